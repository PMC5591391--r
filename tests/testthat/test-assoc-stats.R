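test_that("correlations report estimate, n and both tails with sane edge cases", {
  x <- c(1, 2, 3, 5, 8)
  r <- cor_assoc(x, x * 2 + 1)
  expect_equal(r$estimate, 1)
  expect_equal(r$p_one, 0)
  d <- cor_assoc(c(1, 2, 3), c(6, 4, 2))
  expect_equal(d$estimate, -1)
  expect_error(cor_assoc(c(1, 1, 1), c(1, 2, 3)), class = "cdar_zero_variance")
  expect_error(cor_assoc(1:2, 2:3), class = "cdar_too_few")
  # affine invariance (pearson) and monotone invariance (spearman)
  y <- c(3, 1, 4, 1, 5)
  expect_equal(
    cor_assoc(x, y)$estimate,
    cor_assoc(10 - 2 * x, y)$estimate * -1
  )
  expect_equal(
    cor_assoc(x, y, "spearman")$estimate,
    cor_assoc(exp(x), y, "spearman")$estimate
  )
  expect_equal(r$p_two, min(1, 2 * r$p_one))
})

test_that("the sign test matches brute-force enumeration and the published tail values", {
  expect_equal(sign_test(8, 8)$p_one, 0.5^8)
  expect_equal(sign_test(15, 21)$p_one, 0.0391769, tolerance = 1e-5)
  expect_equal(sign_test(17, 24)$p_one, 0.0319573, tolerance = 1e-5)
  for (n in c(5, 8, 12, 17, 20)) {
    for (k in c(0, floor(n / 3), floor(n / 2), n - 1, n)) {
      expect_equal(sign_test(k, n)$p_one, enum_sign_test_one(k, n))
    }
  }
  expect_error(sign_test(0, 0), class = "cdar_bad_input")
})

test_that("Mann-Whitney exact branch equals full-arrangement enumeration", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p_two, 2 / 6)
  expect_equal(mann_whitney(1, 1)$p_two, 1)
  set.seed(11)
  for (i in 1:8) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    a <- sample(1:6, n1, replace = TRUE) # ties likely
    b <- sample(1:6, n2, replace = TRUE)
    got <- mann_whitney(a, b)
    expect_equal(got$method, "exact_enumeration")
    expect_equal(got$p_two, enum_mann_whitney_p(a, b))
  }
})

test_that("Mann-Whitney approximate branch tracks the exact one and wilcox.test", {
  set.seed(7)
  for (i in 1:6) {
    a <- stats::rnorm(5)
    b <- stats::rnorm(5) + 0.5
    exact <- mann_whitney(a, b)$p_two
    approx <- mann_whitney(a, b, exact_limit = 0)$p_two
    expect_lt(abs(exact - approx), 0.02)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_equal(approx, ref, tolerance = 1e-8)
  }
})

test_that("Fisher exact test equals hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))$p_two, 1 / 3)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_two, 1)
  m <- matrix(c(13, 0, 2, 6), 2, byrow = TRUE)
  expect_equal(fisher_exact(m)$p_two, enum_fisher_p(m))
  expect_equal(fisher_exact(m)$p_two, stats::fisher.test(m)$p.value, tolerance = 1e-9)
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(stats::rpois(4, 4) + c(1, 0, 0, 1), 2)
    expect_equal(fisher_exact(m)$p_two, stats::fisher.test(m)$p.value,
      tolerance = 1e-9
    )
  }
  expect_error(fisher_exact(matrix(c(0, 0, 1, 1), 2)), class = "cdar_bad_input")
})

test_that("one-cell chi-square uses (O-E)^2/E on 1 df without continuity correction", {
  r <- chi_square_one_cell(8, 18)
  expect_equal(r$statistic, 100 / 18)
  expect_equal(r$p, 0.01842, tolerance = 1e-3)
  expect_equal(chi_square_one_cell(5, 5)$p, 1)
  expect_equal(chi_square_one_cell(0, 6.75)$p, 0.009375, tolerance = 1e-3)
})

test_that("group residualization centers within groups and reduces to plain correlation", {
  x <- c(1, 3, 5, 2, 4, 9)
  y <- c(2, 2, 7, 1, 8, 4)
  g <- c("a", "a", "a", "b", "b", "b")
  rx <- x - stats::ave(x, g)
  expect_equal(as.numeric(tapply(rx, g, sum)), c(0, 0))
  res <- residual_partial_assoc(x, y, g)
  expect_equal(res$method, c("pearson_r", "spearman_rs"))
  one_group <- residual_partial_assoc(x, y, rep("a", 6))
  expect_equal(one_group$estimate[1], cor_assoc(x, y)$estimate)
  expect_error(
    residual_partial_assoc(x, y, c("a", "a", "a", "a", "a", "b")),
    class = "cdar_bad_input"
  )
})

test_that("the ranked P adjustment reproduces its worked example and limiting ranks", {
  out <- bh_adjust(c(0.0005, 0.001, 0.002, 0.05), k = 58)
  row <- out[out$p_raw == 0.002, ]
  expect_equal(row$rank, 56)
  expect_equal(row$p_adj, 0.002 * 58 / 56)
  expect_equal(round(row$p_adj, 5), 0.00207)
  # with k = number of rows: smallest P unchanged, largest P Bonferroni
  p <- c(0.04, 0.001, 0.02, 0.3)
  full <- bh_adjust(p)
  expect_equal(full$p_adj[full$rank == 4], min(p))
  expect_equal(full$p_adj[full$rank == 1], max(p) * 4)
  expect_equal(full$p_adj / full$p_raw, full$k / full$rank)
  # the standard step-up variant is a labelled alternative
  su <- bh_adjust(p, method = "step_up")
  expect_equal(sort(su$p_adj), sort(stats::p.adjust(p, "BH")))
  expect_error(bh_adjust(c(0.1, 0.2), k = 1))
})

test_that("code comparison recovers equal strengths when the scale is the class dummy", {
  classes <- synthetase_classes()
  dummy_scale <- tibble::tibble(
    amino_acid = classes$amino_acid,
    value = ifelse(classes$class == "I", 1, 2)
  )
  attr(dummy_scale, "scale_name") <- "class_dummy"
  cc <- code_comparison(scale = dummy_scale)
  expect_equal(cc$r_scale, cc$r_class)
  expect_false(any(cc$above_line))
})

test_that("code comparison spans the 21-code roster with per-origin summaries", {
  cc <- code_comparison()
  expect_equal(nrow(cc), 21)
  expect_true(all(cc$n_amino_acids == 20))
  # scale correlations are negative, class-dummy correlations positive
  expect_true(all(cc$r_scale < 0))
  expect_true(all(cc$r_class > 0))
  g <- glance(cc)
  expect_equal(g$mito_total, 11)
  expect_equal(g$nuclear_total, 8)
  expect_true(g$both_above == 2) # standard and Mycoplasma/Spiroplasma codes
})
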