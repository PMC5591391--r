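test_that("structure classification resolves every rule branch as published", {
  cases <- tibble::tribble(
    ~codon, ~side, ~group,
    "UUU", "none", "zero", # homopolymer palindrome
    "AUA", "none", "zero",
    "AUU", "five_prime", "full", # ZXX across the purine/pyrimidine divide
    "AAU", "three_prime", "full",
    "GAA", "five_prime", "half_a", # ZXX within the purine group
    "UUC", "three_prime", "half_a",
    "AGU", "three_prime", "half_b", # all distinct, middle pairs with 5' end
    "AUC", "five_prime", "half_b", # all distinct, middle pairs with 3' end
    "UAC", "five_prime", "half_c", # middle alone; complement of A is 5' U
    "ACG", "three_prime", "half_c" # middle alone; complement of C is 3' G
  )
  got <- classify_codons(cases$codon)
  expect_equal(got$dominant_side, cases$side)
  expect_equal(got$magnitude_group, cases$group)
})

test_that("a codon is scored zero exactly when it is palindromic", {
  tab <- score_table()
  palindromic <- substr(tab$codon, 1, 1) == substr(tab$codon, 3, 3)
  expect_equal(tab$cda == 0, palindromic)
  expect_equal(tab$dominant_side == "none", palindromic)
})

test_that("base-scheme scores equal the published 64-codon column entry for entry", {
  tab <- score_table()
  pub <- published_scores()
  expect_equal(tab$cda, unname(pub[tab$codon]))
})

test_that("base scheme gives 24 negative, 16 zero, 24 positive and negative stops", {
  tab <- score_table()
  expect_equal(sum(tab$cda < 0), 24)
  expect_equal(sum(tab$cda == 0), 16)
  expect_equal(sum(tab$cda > 0), 24)
  score <- stats::setNames(tab$cda, tab$codon)
  expect_equal(unname(score[c("UAA", "UAG", "UGA")]), c(-1, -0.5, -0.5))
  # score-class partition used downstream by cohort comparisons
  expect_equal(
    as.vector(table(tab$cda)),
    c(8, 16, 16, 16, 8)
  )
})

test_that("the six alternative schemes permute magnitudes but keep every sign", {
  alts <- alternative_schemes()
  expect_length(alts, 6)
  mags <- t(vapply(alts, function(s) unclass(s)[c("half_a", "half_b", "half_c")], numeric(3)))
  expect_equal(nrow(unique(mags)), 6) # pairwise distinct
  expect_true(all(vapply(alts, function(s) unclass(s)[["full"]] == 1, logical(1))))
  base <- score_table()$cda
  for (s in alts) {
    alt <- cda(codons(), s)
    expect_equal(sign(alt), sign(base))
  }
  expect_error(cda_scheme(0, 0.5, 0.5))
})

test_that("scores are antisymmetric under codon reversal in every scheme", {
  cods <- codons()
  rev <- reverse_codon(cods)
  for (s in all_schemes()) {
    expect_equal(cda(rev, s), -cda(cods, s))
  }
})

test_that("scores are invariant under complement and transition exchanges and sum to zero", {
  cods <- codons()
  comp <- apply_transform(cods, "complement")
  trans <- apply_transform(cods, "transition")
  for (s in all_schemes()) {
    sc <- cda(cods, s)
    expect_equal(cda(comp, s), sc)
    expect_equal(cda(trans, s), sc)
    expect_identical(sum(sc), 0)
  }
})

test_that("amino-acid means aggregate codon scores under the standard code", {
  am <- aa_mean_cda()
  means <- stats::setNames(am$mean_cda, am$amino_acid)
  expect_equal(unname(means["Trp"]), -1) # single codon UGG
  expect_equal(unname(means["Asn"]), 1) # AAU, AAC both +1
  expect_equal(unname(means["Gln"]), -0.75) # CAA -1, CAG -0.5
  expect_equal(nrow(am), 20)
  stops <- attr(am, "stops")
  expect_setequal(stops$codon, c("UAA", "UAG", "UGA"))
})

test_that("stop-codon reassignment moves the codon into the residue mean", {
  mt <- aa_mean_cda(genetic_code(2)) # UGA -> Trp, AUA -> Met
  means <- stats::setNames(mt$mean_cda, mt$amino_acid)
  expect_equal(unname(means["Trp"]), mean(c(-1, -0.5))) # UGG, UGA
  expect_equal(unname(means["Met"]), mean(c(-0.5, 0))) # AUG, AUA
  expect_setequal(attr(mt, "stops")$codon, c("UAA", "UAG", "AGA", "AGG"))
})

test_that("usage weighting degenerates correctly and rejects zero-mass residues", {
  w <- tibble::tibble(codon = codons(), count = 0L)
  w$count[w$codon == "CAA"] <- 100L # all Gln mass on CAA
  w$count[w$codon %in% setdiff(codons(), "CAA")] <- 1L
  w$count[w$codon == "CAG"] <- 0L
  am <- aa_mean_cda(weights = w)
  expect_equal(am$mean_cda[am$amino_acid == "Gln"], cda("CAA"))
  w0 <- tibble::tibble(codon = codons(), count = 1L)
  w0$count[w0$codon %in% c("UGG")] <- 0L # Trp family has zero mass
  expect_error(aa_mean_cda(weights = w0), class = "cdar_bad_weights")
})

test_that("codon-level class summary reproduces the published sign counts", {
  cs <- class_sign_summary(level = "codon")
  i <- cs[cs$class == "I", ]
  ii <- cs[cs$class == "II", ]
  expect_equal(i$n_nonzero, 21)
  expect_equal(i$n_negative, 15)
  # the published text says 17 of 24 here; the published score column itself
  # gives 18, which is what the engine reports
  expect_equal(ii$n_nonzero, 24)
  expect_equal(ii$n_positive, 18)
  expect_equal(i$n_zero + ii$n_zero, 16) # zeros excluded and accounted for
})

test_that("amino-acid-level class summary finds 8/10 + 8/10 with the known exceptions", {
  cs <- class_sign_summary()
  i <- cs[cs$class == "I", ]
  ii <- cs[cs$class == "II", ]
  expect_equal(i$n_following, 8)
  expect_equal(ii$n_following, 8)
  expect_setequal(i$exceptions[[1]], c("Cys", "Leu"))
  expect_setequal(ii$exceptions[[1]], c("Ala", "Thr"))
  expect_equal(i$n_following + ii$n_following, 16)
})

test_that("the class-level pattern is identical under all six alternative schemes", {
  for (s in alternative_schemes()) {
    cs <- class_sign_summary(scheme = s)
    expect_equal(cs$n_following, c(8, 8))
    expect_setequal(cs$exceptions[[1]], c("Cys", "Leu"))
    expect_setequal(cs$exceptions[[2]], c("Ala", "Thr"))
  }
})
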