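#' Six-bit binary codon representation
#'
#' Each codon position contributes two indicator bits: `Rk = 1` when
#' position k carries a purine, and `Sk = 1` when it carries a nucleotide
#' pairing through three hydrogen bonds (`G` or `C`). The 64 codons map
#' bijectively onto the 64 six-bit vectors. With `pairing = "keto"` the
#' first bit of each pair instead marks the keto nucleotides (`G`, `U`).
#'
#' @param codon Character vector of codons; defaults to all 64.
#' @param pairing `"purine"` (default) or `"keto"` for the first bit of
#'   each pair.
#' @return A tibble with columns `codon`, `R1`, `S1`, `R2`, `S2`, `R3`, `S3`
#'   (0/1 integers).
#' @examples
#' binary_vectors(c("AAA", "GCG", "CCC"))
#' @export
binary_vectors <- function(codon = codons(), pairing = c("purine", "keto")) {
  pairing <- match.arg(pairing)
  codon <- normalize_codon(codon)
  chars <- strsplit(codon, "", fixed = TRUE)
  first_bit <- if (pairing == "purine") {
    function(n) as.integer(.nt_group[n] == "purine")
  } else {
    function(n) as.integer(.nt_keto[n])
  }
  bits <- t(vapply(chars, function(n) {
    c(
      first_bit(n[1]), as.integer(.nt_strong[n[1]]),
      first_bit(n[2]), as.integer(.nt_strong[n[2]]),
      first_bit(n[3]), as.integer(.nt_strong[n[3]])
    )
  }, integer(6)))
  colnames(bits) <- c("R1", "S1", "R2", "S2", "R3", "S3")
  dplyr::bind_cols(tibble::tibble(codon = codon), tibble::as_tibble(bits))
}

#' Independence of CDA from the binary codon dimensions
#'
#' Pearson correlation of the codon scores against each of the six binary
#' codon bits, and against the sums and differences of every bit pair. All
#' of these are exactly zero: the score table is invariant under the
#' complement exchange (which flips every purine bit) and under the
#' transition exchange (which flips every strong bit), and its scores sum
#' to zero, which forces every such covariance to vanish. The same holds
#' under the keto/amino regrouping.
#'
#' @param table A [score_table()].
#' @param pairing Passed to [binary_vectors()].
#' @return A tibble with columns `term` (e.g. `"R1"`, `"R1+S2"`,
#'   `"R1-S2"`), `r`.
#' @examples
#' all(cda_bit_independence()$r == 0)
#' @export
cda_bit_independence <- function(table = score_table(),
                                 pairing = c("purine", "keto")) {
  bv <- binary_vectors(table$codon, pairing = match.arg(pairing))
  bits <- as.matrix(bv[, c("R1", "S1", "R2", "S2", "R3", "S3")])
  single <- tibble::tibble(
    term = colnames(bits),
    r = apply(bits, 2, function(b) stats::cor(table$cda, b))
  )
  pairs <- utils::combn(colnames(bits), 2, simplify = FALSE)
  combos <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(
      term = c(paste0(p[1], "+", p[2]), paste0(p[1], "-", p[2])),
      r = c(
        stats::cor(table$cda, bits[, p[1]] + bits[, p[2]]),
        stats::cor(table$cda, bits[, p[1]] - bits[, p[2]])
      )
    )
  })
  dplyr::bind_rows(single, combos)
}

#' Nucleotide exchanges (swinger transformations)
#'
#' `nucleotide_permutations()` enumerates all 23 non-identity bijections of
#' the RNA alphabet, named where a conventional name exists: `rumer`
#' (A-C, G-U), `complement` (A-U, G-C), `transition` (A-G, C-U).
#' `position_transform()` builds a per-codon-position transform from one
#' permutation per position; `apply_transform()` applies it to codons or to
#' longer in-frame sequences.
#'
#' @return A named list of named character vectors, each a bijection on
#'   `A, C, G, U`.
#' @examples
#' nucleotide_permutations()[["rumer"]]
#' @export
nucleotide_permutations <- function() {
  bases <- c("A", "C", "G", "U")
  perms <- list()
  idx <- 0
  for (p in .permutations4()) {
    img <- bases[p]
    if (identical(img, bases)) next
    map <- stats::setNames(img, bases)
    idx <- idx + 1
    perms[[idx]] <- map
  }
  nm <- vapply(perms, function(m) {
    if (identical(m, c(A = "C", C = "A", G = "U", U = "G"))) return("rumer")
    if (identical(m, c(A = "U", C = "G", G = "C", U = "A"))) return("complement")
    if (identical(m, c(A = "G", C = "U", G = "A", U = "C"))) return("transition")
    paste0(m, collapse = "")
  }, character(1))
  stats::setNames(perms, nm)
}

.permutations4 <- function() {
  out <- list()
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4) {
    p <- c(a, b, cc, d)
    if (length(unique(p)) == 4) out[[length(out) + 1]] <- p
  }
  out
}

#' @rdname nucleotide_permutations
#' @param p1,p2,p3 Either a named character vector (a bijection on the
#'   alphabet), the name of one (`"rumer"`, `"complement"`, `"transition"`,
#'   `"identity"`), or `NULL` for identity at that position.
#' @param name Optional transform label.
#' @export
position_transform <- function(p1 = NULL, p2 = NULL, p3 = NULL, name = NULL) {
  resolve <- function(p) {
    if (is.null(p) || identical(p, "identity")) {
      return(stats::setNames(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
    }
    if (is.character(p) && length(p) == 1) {
      perms <- nucleotide_permutations()
      if (!p %in% names(perms)) {
        rlang::abort(paste0("unknown permutation name: ", p), class = "cdar_bad_transform")
      }
      return(perms[[p]])
    }
    stopifnot(setequal(names(p), c("A", "C", "G", "U")), setequal(p, c("A", "C", "G", "U")))
    p[c("A", "C", "G", "U")]
  }
  out <- list(p1 = resolve(p1), p2 = resolve(p2), p3 = resolve(p3))
  attr(out, "transform_name") <- name %||% "custom"
  class(out) <- "position_transform"
  out
}

#' The genetic-code symmetry transform associated with synthetase classes
#'
#' Exchanges nucleotides at the first and third codon positions by the
#' Rumer rule (A-C, G-U) and at the second position by the transition rule
#' (A-G, C-U). The `third_position = "complement"` variant applies A-U, C-G
#' at the third position instead; both variants map most sense codons onto
#' codons of the opposite synthetase class.
#'
#' @param third_position `"rumer"` (default) or `"complement"`.
#' @return A [position_transform()].
#' @examples
#' apply_transform("UUA", class_symmetry_transform()) # Leu -> Ala
#' @export
class_symmetry_transform <- function(third_position = c("rumer", "complement")) {
  third_position <- match.arg(third_position)
  position_transform(
    "rumer", "transition", third_position,
    name = paste0("class_symmetry_", third_position, "3")
  )
}

#' @rdname nucleotide_permutations
#' @param x Character vector of codons or in-frame sequences over
#'   `A, C, G, U/T` (length a multiple of 3).
#' @param transform A [position_transform()], or a single permutation
#'   applied uniformly at all three positions.
#' @export
apply_transform <- function(x, transform) {
  if (!inherits(transform, "position_transform")) {
    transform <- position_transform(transform, transform, transform)
  }
  x <- toupper(chartr("T", "U", as.character(x)))
  bad <- grepl("[^ACGU]", x) | nchar(x) %% 3 != 0
  if (any(bad)) {
    rlang::abort("sequences must be in-frame over A, C, G, U/T", class = "cdar_bad_codon")
  }
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    pos <- (seq_along(ch) - 1L) %% 3L + 1L
    ch[pos == 1L] <- transform$p1[ch[pos == 1L]]
    ch[pos == 2L] <- transform$p2[ch[pos == 2L]]
    ch[pos == 3L] <- transform$p3[ch[pos == 3L]]
    paste(ch, collapse = "")
  }, character(1))
}

#' Synthetase-class swap under a nucleotide-exchange transform
#'
#' Maps every sense codon of a genetic code through a transform and asks
#' whether the image codon's amino acid belongs to the opposite synthetase
#' class. Images that are stop codons (or pre-images that are stops) are
#' flagged and excluded from the swap fraction.
#'
#' @param code A [genetic_code()].
#' @param transform A [position_transform()].
#' @param classes A synthetase class map.
#' @return A tibble (class `cda_class_swap`) with one row per codon:
#'   `codon`, `amino_acid`, `class`, `image`, `image_amino_acid`,
#'   `image_class`, `swapped` (NA when either side is a stop). Use
#'   [glance()] for the summary fraction.
#' @examples
#' glance(class_swap_report())
#' @export
class_swap_report <- function(code = genetic_code(1),
                              transform = class_symmetry_transform(),
                              classes = synthetase_classes()) {
  aa_of <- stats::setNames(code$amino_acid, code$codon)
  cls_of <- stats::setNames(classes$class, classes$amino_acid)
  img <- apply_transform(code$codon, transform)
  out <- tibble::tibble(
    codon = code$codon,
    amino_acid = unname(aa_of[code$codon]),
    class = unname(cls_of[.data$amino_acid]),
    image = img,
    image_amino_acid = unname(aa_of[img]),
    image_class = unname(cls_of[.data$image_amino_acid]),
    swapped = ifelse(
      is.na(.data$class) | is.na(.data$image_class),
      NA,
      .data$class != .data$image_class
    )
  )
  attr(out, "transform") <- attr(transform, "transform_name")
  class(out) <- c("cda_class_swap", class(out))
  out
}

#' @export
glance.cda_class_swap <- function(x, ...) {
  tibble::tibble(
    transform = attr(x, "transform"),
    n_counted = sum(!is.na(x$swapped)),
    n_flagged = sum(is.na(x$swapped)),
    swap_fraction = mean(x$swapped, na.rm = TRUE)
  )
}

#' Absolute CDA inside versus outside a circular code
#'
#' Compares absolute codon scores between codons belonging to a circular
#' code (by default the natural circular code X0) and the remaining codons:
#' group means plus a two-tailed Mann-Whitney test. Both group means and
#' the signed difference are reported; no direction is asserted.
#'
#' @param table A [score_table()].
#' @param code_set Character vector of member codons.
#' @return A two-row tibble (`group`, `n`, `mean_abs_cda`) with attributes
#'   `u`, `p_two`, `method`, `difference` (inside minus outside). When one
#'   group is empty the test attributes are `NA` and a warning is raised.
#' @examples
#' circular_abs_cda()
#' @export
circular_abs_cda <- function(table = score_table(), code_set = circular_code_x0()) {
  code_set <- normalize_codon(code_set)
  inside <- abs(table$cda[table$codon %in% code_set])
  outside <- abs(table$cda[!table$codon %in% code_set])
  out <- tibble::tibble(
    group = c("inside", "outside"),
    n = c(length(inside), length(outside)),
    mean_abs_cda = c(mean(inside), mean(outside))
  )
  if (length(inside) == 0 || length(outside) == 0) {
    rlang::warn("one group is empty; no test possible")
    attr(out, "u") <- NA_real_
    attr(out, "p_two") <- NA_real_
    attr(out, "method") <- "none"
  } else {
    mw <- mann_whitney(inside, outside)
    attr(out, "u") <- mw$u
    attr(out, "p_two") <- mw$p_two
    attr(out, "method") <- mw$method
  }
  attr(out, "difference") <- out$mean_abs_cda[1] - out$mean_abs_cda[2]
  out
}
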