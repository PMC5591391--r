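#' Magnitude schemes for half-strength codons
#'
#' Three distinct rationales each award a codon a half-strength score:
#' group (a), repeated-letter codons `ZXX`/`XXZ` whose two letters share the
#' purine/pyrimidine group; group (b), all-distinct codons whose middle
#' nucleotide shares a group with one extremity; and group (c), all-distinct
#' codons whose middle nucleotide is alone in its group, resolved by
#' canonical complementarity. The base scheme scores all three at 0.5 and
#' cross-group `ZXX`/`XXZ` codons at 1. Because the three half-strength
#' rationales are partly arbitrary, six alternative schemes keep the full
#' magnitude at 1 and permute (0.25, 0.5, 0.75) over groups (a, b, c).
#'
#' @param m_a,m_b,m_c Magnitudes in (0, 1] for groups (a), (b) and (c).
#' @param name Scheme label.
#' @return A `cda_scheme`: a named numeric vector with elements `full`,
#'   `half_a`, `half_b`, `half_c`.
#' @examples
#' base_scheme()
#' names(alternative_schemes())
#' @export
cda_scheme <- function(m_a = 0.5, m_b = 0.5, m_c = 0.5, name = NULL) {
  m <- c(m_a, m_b, m_c)
  stopifnot(is.numeric(m), length(m) == 3, all(m > 0), all(m <= 1))
  out <- c(full = 1, half_a = m_a, half_b = m_b, half_c = m_c)
  attr(out, "scheme_name") <- name %||%
    sprintf("(%.2g, %.2g, %.2g)", m_a, m_b, m_c)
  class(out) <- "cda_scheme"
  out
}

#' @rdname cda_scheme
#' @export
base_scheme <- function() cda_scheme(0.5, 0.5, 0.5, name = "base")

#' @rdname cda_scheme
#' @export
alternative_schemes <- function() {
  perms <- list(
    c(0.50, 0.25, 0.75), c(0.50, 0.75, 0.25),
    c(0.25, 0.50, 0.75), c(0.25, 0.75, 0.50),
    c(0.75, 0.50, 0.25), c(0.75, 0.25, 0.50)
  )
  out <- lapply(perms, function(p) cda_scheme(p[1], p[2], p[3]))
  names(out) <- vapply(out, scheme_name, character(1))
  out
}

#' @export
print.cda_scheme <- function(x, ...) {
  cat("<cda_scheme ", scheme_name(x), "> ", sep = "")
  print(unclass(x)[c("full", "half_a", "half_b", "half_c")])
  invisible(x)
}

scheme_name <- function(scheme) attr(scheme, "scheme_name") %||% "custom"

#' Classify codon structure for directional-asymmetry scoring
#'
#' Assigns each codon a dominant side and a magnitude group. Rule order:
#' palindromic codons (first and third nucleotide identical, including
#' homopolymers) are symmetric; repeated-letter codons `ZXX` (5'-dominant)
#' and `XXZ` (3'-dominant) are full strength across the purine/pyrimidine
#' divide, half strength (group a) within it; among all-distinct codons the
#' extremity left out of the same-group pair is dominant (group b), and when
#' the middle nucleotide is alone in its group the extremity that is its
#' canonical complement is dominant (group c).
#'
#' @param codon Character vector of codons; defaults to all 64.
#' @return A tibble with columns `codon`, `dominant_side` (`"none"`,
#'   `"five_prime"`, `"three_prime"`) and `magnitude_group` (`"zero"`,
#'   `"full"`, `"half_a"`, `"half_b"`, `"half_c"`).
#' @examples
#' classify_codons(c("UUU", "AUU", "UAC", "ACG"))
#' @export
classify_codons <- function(codon = codons()) {
  codon <- normalize_codon(codon)
  cls <- t(vapply(strsplit(codon, "", fixed = TRUE), .classify1, character(2)))
  tibble::tibble(
    codon = codon,
    dominant_side = cls[, 1],
    magnitude_group = cls[, 2]
  )
}

.classify1 <- function(n) {
  if (n[1] == n[3]) {
    return(c("none", "zero"))
  }
  g <- .nt_group[n]
  if (n[2] == n[3]) { # ZXX: 5' extremity differs
    return(c("five_prime", if (g[1] == g[2]) "half_a" else "full"))
  }
  if (n[1] == n[2]) { # XXZ: 3' extremity differs
    return(c("three_prime", if (g[3] == g[2]) "half_a" else "full"))
  }
  # all three distinct
  if (g[2] == g[3]) {
    return(c("five_prime", "half_b")) # middle pairs with 3' end, 5' left out
  }
  if (g[1] == g[2]) {
    return(c("three_prime", "half_b"))
  }
  # middle alone in its group: canonical complementarity breaks the tie
  if (.nt_complement[n[2]] == n[1]) {
    return(c("five_prime", "half_c"))
  }
  c("three_prime", "half_c")
}

#' Codon directional asymmetry score
#'
#' Signed score for each codon: negative when the 5' extremity carries the
#' most different nucleotide, positive when the 3' extremity does, zero for
#' palindromic codons. Magnitudes come from the scheme (quarters, exact in
#' double precision).
#'
#' @param codon Character vector of codons.
#' @param scheme A [cda_scheme()]; defaults to the base scheme.
#' @return Numeric vector of signed scores.
#' @examples
#' cda(c("AUU", "UUC", "UUU"))
#' @export
cda <- function(codon, scheme = base_scheme()) {
  cls <- classify_codons(codon)
  sgn <- c(none = 0, five_prime = -1, three_prime = 1)[cls$dominant_side]
  mag <- c(zero = 0, unclass(scheme))[cls$magnitude_group]
  unname(sgn * mag)
}

#' Full 64-codon score table
#'
#' @param scheme A [cda_scheme()].
#' @return A tibble (class `cda_score_table`) with columns `codon`,
#'   `structure_class`, `dominant_side`, `cda`, carrying the scheme name as
#'   an attribute. Scores sum to zero under every scheme, and the base
#'   scheme yields 24 negative, 16 zero and 24 positive codons.
#' @examples
#' score_table()
#' @export
score_table <- function(scheme = base_scheme()) {
  cls <- classify_codons(codons())
  out <- tibble::tibble(
    codon = cls$codon,
    structure_class = cls$magnitude_group,
    dominant_side = cls$dominant_side,
    cda = cda(cls$codon, scheme)
  )
  attr(out, "scheme") <- scheme_name(scheme)
  class(out) <- c("cda_score_table", class(out))
  out
}

#' @export
tidy.cda_score_table <- function(x, ...) tibble::as_tibble(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL
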