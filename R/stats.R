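#' Correlation with one- and two-tailed P values
#'
#' Product-moment or rank correlation reported in a uniform one-row tibble.
#' Ranks use midranks for ties; P values come from the t approximation on
#' the coefficient (the method tag records this). The one-tailed P is taken
#' in the direction of the observed estimate; the two-tailed P is twice the
#' one-tailed, capped at 1.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite values.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble with `method`, `estimate`, `n`, `p_one`, `p_two`.
#' @examples
#' cor_assoc(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9), method = "spearman")
#' @export
cor_assoc <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    rlang::abort("need at least 3 complete pairs", class = "cdar_too_few")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    rlang::abort("values must be finite", class = "cdar_bad_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("zero variance input", class = "cdar_zero_variance")
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  est <- stats::cor(x, y)
  if (abs(est) >= 1) {
    p_one <- 0
  } else {
    tstat <- est * sqrt((n - 2) / (1 - est^2))
    p_one <- stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(
    method = if (method == "spearman") "spearman_rs" else "pearson_r",
    estimate = est,
    n = n,
    p_one = p_one,
    p_two = min(1, 2 * p_one)
  )
}

#' Exact binomial sign test
#'
#' One-tailed P is the exact binomial tail probability under p = 1/2 in the
#' direction of the majority (`P(X >= k)` for `k >= n/2`, mirrored
#' otherwise); the two-tailed P is twice the one-tailed, capped at 1. Both
#' tails are always reported.
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @return A one-row tibble with `k`, `n`, `p_one`, `p_two`.
#' @examples
#' sign_test(15, 21)
#' @export
sign_test <- function(k, n) {
  stopifnot(length(k) == 1, length(n) == 1, k >= 0, k <= n)
  if (n == 0) rlang::abort("n must be positive", class = "cdar_bad_input")
  p_one <- if (k >= n / 2) {
    sum(stats::dbinom(k:n, n, 0.5))
  } else {
    sum(stats::dbinom(0:k, n, 0.5))
  }
  tibble::tibble(k = k, n = n, p_one = p_one, p_two = min(1, 2 * p_one))
}

#' Mann-Whitney rank-sum test
#'
#' U is computed for the first sample with ties counted half. For combined
#' sample sizes up to `exact_limit` the two-tailed P comes from full
#' enumeration of all group assignments of the pooled values (tie-safe); for
#' larger samples a tie-corrected normal approximation with continuity
#' correction is used. The method tag records which branch ran.
#'
#' @param a,b Numeric samples (both nonempty).
#' @param exact_limit Maximum combined size for the enumeration branch.
#' @return A one-row tibble with `u`, `n1`, `n2`, `p_two`, `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
mann_whitney <- function(a, b, exact_limit = 12) {
  stopifnot(length(a) > 0, length(b) > 0)
  n1 <- length(a)
  n2 <- length(b)
  u_of <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u <- u_of(a, b)
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_limit) {
    pool <- c(a, b)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
    p_two <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact_enumeration"
  } else {
    pool <- c(a, b)
    nn <- n1 + n2
    ties <- table(pool)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p_two <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2) # continuity-corrected
      p_two <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_tie_corrected"
  }
  tibble::tibble(u = u, n1 = n1, n2 = n2, p_two = p_two, method = method)
}

#' Fisher exact test for a 2x2 table
#'
#' Two-tailed P is the sum of hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (within a relative tolerance of 1e-7).
#'
#' @param m A 2x2 matrix of non-negative integer counts.
#' @return A one-row tibble with `p_two`.
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2))
#' @export
fisher_exact <- function(m) {
  m <- matrix(as.numeric(m), 2, 2)
  if (any(m < 0) || any(m != round(m))) {
    rlang::abort("counts must be non-negative integers", class = "cdar_bad_input")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    rlang::abort("empty margin", class = "cdar_bad_input")
  }
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  tibble::tibble(p_two = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' One-cell chi-square test
#'
#' `(O - E)^2 / E` referred to the 1-df chi-square survival function, with
#' no continuity correction.
#'
#' @param observed Observed count.
#' @param expected Expected count (> 0).
#' @return A one-row tibble with `statistic`, `df`, `p`.
#' @examples
#' chi_square_one_cell(8, 18)
#' @export
chi_square_one_cell <- function(observed, expected) {
  stopifnot(expected > 0)
  stat <- (observed - expected)^2 / expected
  tibble::tibble(
    statistic = stat,
    df = 1,
    p = stats::pchisq(stat, df = 1, lower.tail = FALSE)
  )
}

#' Group-residualized partial association
#'
#' Removes group structure from both variables by subtracting each group's
#' mean of x and of y from its members, then correlates the residual pairs.
#' Both Pearson and Spearman results are reported. With a single group this
#' reduces to the plain correlation of centered data.
#'
#' @param x,y Numeric vectors.
#' @param groups Grouping vector (each group needs at least 2 members).
#' @return A two-row tibble, one row per method, as in [cor_assoc()].
#' @examples
#' cls <- synthetase_class(aa_mean_cda()$amino_acid)
#' scale <- aa_scale("antiparallel_beta")
#' residual_partial_assoc(aa_mean_cda()$mean_cda, scale$value, cls)
#' @export
residual_partial_assoc <- function(x, y, groups) {
  stopifnot(length(x) == length(y), length(x) == length(groups))
  sizes <- table(groups)
  if (any(sizes < 2)) {
    rlang::abort(
      paste0("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", ")),
      class = "cdar_bad_input"
    )
  }
  rx <- x - stats::ave(x, groups)
  ry <- y - stats::ave(y, groups)
  dplyr::bind_rows(
    cor_assoc(rx, ry, "pearson"),
    cor_assoc(rx, ry, "spearman")
  )
}

#' Rank-based multiple-testing adjustment
#'
#' The default `"ranked"` convention ranks the k P values from highest
#' (rank 1) to lowest (rank k) and multiplies each P by k divided by its
#' rank: the smallest P is unchanged, the largest follows the Bonferroni
#' adjustment, and no cumulative-minimum step is applied (so adjusted
#' values need not be monotone). `"step_up"` instead applies the standard
#' Benjamini-Hochberg step-up procedure via [stats::p.adjust()]. When `k`
#' exceeds the number of rows supplied, the rows are treated as the k
#' smallest P values of the full family (rank of the smallest = k).
#'
#' @param p Numeric vector of raw P values in \[0, 1\].
#' @param labels Optional labels.
#' @param k Total number of tests in the family (>= `length(p)`).
#' @param method `"ranked"` (default) or `"step_up"`.
#' @return A tibble with `label`, `p_raw`, `rank`, `k`, `p_adj`, sorted by
#'   decreasing `p_raw`; ties in `p_raw` receive distinct consecutive ranks.
#' @examples
#' bh_adjust(c(0.0005, 0.001, 0.002, 0.05), k = 58)
#' @export
bh_adjust <- function(p, labels = NULL, k = length(p),
                      method = c("ranked", "step_up")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0), all(p <= 1), k >= length(p))
  labels <- labels %||% paste0("test_", seq_along(p))
  asc <- rank(p, ties.method = "first")
  rnk <- k - asc + 1L
  p_adj <- if (method == "ranked") {
    p * k / rnk # deliberately uncapped: p_adj / p_raw == k / rank exactly
  } else {
    stats::p.adjust(p, method = "BH", n = k)
  }
  out <- tibble::tibble(
    label = labels, p_raw = p, rank = rnk, k = k,
    p_adj = p_adj, method = method
  )
  dplyr::arrange(out, .data$rank)
}
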