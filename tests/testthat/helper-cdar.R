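# Shared helpers for the suite.

# The published 64-codon base-scheme score column, carried by the bundled
# cohort-usage fixture; used as an external check on the rule engine.
published_scores <- function() {
  u <- longevity_cohort_usage()
  stats::setNames(u$cda, u$codon)
}

all_schemes <- function() {
  c(list(base = base_scheme()), alternative_schemes())
}

# Brute-force sign-test oracle: enumerate all 2^n equally likely sign
# vectors and count outcomes at least as extreme as k in the majority
# direction.
enum_sign_test_one <- function(k, n) {
  ks <- 0:n
  counts <- choose(n, ks)
  if (k >= n / 2) {
    sum(counts[ks >= k]) / 2^n
  } else {
    sum(counts[ks <= k]) / 2^n
  }
}

# Full-arrangement Mann-Whitney oracle for small pooled samples.
enum_mann_whitney_p <- function(a, b) {
  n1 <- length(a)
  pool <- c(a, b)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  mu <- n1 * length(b) / 2
  obs <- u_of(a, b)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Hypergeometric enumeration oracle for 2x2 Fisher tests.
enum_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  sum(probs[probs <= stats::dhyper(m[1, 1], r1, n - r1, c1) * (1 + 1e-7)])
}

write_fasta <- function(seqs, path) {
  writeLines(unlist(purrr::imap(seqs, function(s, id) c(paste0(">", id), s))), path)
  path
}
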