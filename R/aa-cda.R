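#' Per-amino-acid mean codon directional asymmetry
#'
#' Averages codon scores over each amino acid's codons under a genetic
#' code. Stop codons never enter residue means; their scores are carried
#' separately in the `stops` attribute. Codes that reassign a stop codon to
#' a residue (e.g. `UGA` to Trp in most mitochondrial tables) include the
#' reassigned codon in that residue's mean. With `weights` (a codon usage
#' table, see [codon_usage()]) the mean is count-weighted within each
#' synonymous family.
#'
#' @param code A [genetic_code()].
#' @param scheme A [cda_scheme()].
#' @param weights Optional tibble with columns `codon` and `count` (or
#'   `promil`) covering the code's sense codons.
#' @return A tibble (class `aa_cda`) with columns `amino_acid`, `mean_cda`,
#'   `n_codons`; attributes `stops` (tibble of stop-codon scores),
#'   `table_id`, `scheme`, `weighted`.
#' @examples
#' aa_mean_cda()
#' attr(aa_mean_cda(), "stops")
#' @export
aa_mean_cda <- function(code = genetic_code(1), scheme = base_scheme(),
                        weights = NULL) {
  scores <- cda(code$codon, scheme)
  df <- tibble::tibble(
    codon = code$codon,
    amino_acid = code$amino_acid,
    cda = scores
  )
  if (!is.null(weights)) {
    wcol <- if ("count" %in% names(weights)) "count" else "promil"
    stopifnot(wcol %in% names(weights))
    df$w <- weights[[wcol]][match(df$codon, weights$codon)]
    sense <- df$amino_acid != "STOP"
    if (anyNA(df$w[sense])) {
      rlang::abort("weights must cover the code's sense codons", class = "cdar_bad_weights")
    }
  } else {
    df$w <- 1
  }
  stops <- df[df$amino_acid == "STOP", c("codon", "cda")]
  sense <- df[df$amino_acid != "STOP", ]
  zero_mass <- tapply(sense$w, sense$amino_acid, sum) == 0
  if (any(zero_mass)) {
    rlang::abort(
      paste0(
        "all-zero weight mass for: ",
        paste(names(zero_mass)[zero_mass], collapse = ", ")
      ),
      class = "cdar_bad_weights"
    )
  }
  out <- sense |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::summarise(
      mean_cda = sum(.data$cda * .data$w) / sum(.data$w),
      n_codons = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "stops") <- stops
  attr(out, "table_id") <- attr(code, "table_id")
  attr(out, "scheme") <- scheme_name(scheme)
  attr(out, "weighted") <- !is.null(weights)
  class(out) <- c("aa_cda", class(out))
  out
}

#' Synthetase-class sign summary of CDA
#'
#' Counts how codon or amino-acid scores split by sign within each
#' aminoacyl-tRNA synthetase class. At the codon level, zero-scored sense
#' codons are excluded from the negative/positive counts and reported in
#' `n_zero`. At the amino-acid level, residues with strictly negative or
#' strictly positive mean CDA are counted, and the residues breaking the
#' expected pattern (class I negative, class II positive) are listed.
#'
#' @param code A [genetic_code()].
#' @param scheme A [cda_scheme()].
#' @param level `"amino_acid"` (default) or `"codon"`.
#' @param classes Synthetase class map, a tibble like [synthetase_classes()].
#' @return A two-row tibble (one per class) with sign counts; at the
#'   amino-acid level also `n_following` (residues matching the expected
#'   direction) and an `exceptions` list-column.
#' @examples
#' class_sign_summary(level = "codon")
#' class_sign_summary()
#' @export
class_sign_summary <- function(code = genetic_code(1), scheme = base_scheme(),
                               level = c("amino_acid", "codon"),
                               classes = synthetase_classes()) {
  level <- match.arg(level)
  if (level == "codon") {
    df <- tibble::tibble(
      codon = code$codon,
      amino_acid = code$amino_acid,
      cda = cda(code$codon, scheme)
    ) |>
      dplyr::filter(.data$amino_acid != "STOP") |>
      dplyr::inner_join(classes, by = "amino_acid")
    out <- df |>
      dplyr::group_by(class) |>
      dplyr::summarise(
        n_codons = dplyr::n(),
        n_zero = sum(.data$cda == 0),
        n_nonzero = sum(.data$cda != 0),
        n_negative = sum(.data$cda < 0),
        n_positive = sum(.data$cda > 0),
        .groups = "drop"
      )
    return(out)
  }
  am <- aa_mean_cda(code, scheme)
  df <- dplyr::inner_join(am, classes, by = "amino_acid")
  df |>
    dplyr::group_by(class) |>
    dplyr::summarise(
      n_amino_acids = dplyr::n(),
      n_negative = sum(.data$mean_cda < 0),
      n_positive = sum(.data$mean_cda > 0),
      n_following = sum(
        if (class[1] == "I") .data$mean_cda < 0 else .data$mean_cda > 0
      ),
      exceptions = list(
        .data$amino_acid[
          if (class[1] == "I") .data$mean_cda >= 0 else .data$mean_cda <= 0
        ]
      ),
      .groups = "drop"
    )
}
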