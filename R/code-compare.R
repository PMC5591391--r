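#' Scale versus synthetase-class correlation strength across genetic codes
#'
#' For each genetic code, recomputes amino-acid mean CDA under that code's
#' codon assignments (reassigned stop codons enter residue means; stop
#' codons never do) and forms two Pearson coefficients: `r_scale`, the
#' correlation of mean CDA with a conformational scale, and `r_class`, the
#' correlation of mean CDA with the synthetase-class dummy (class I coded
#' 1, class II coded 2). The two are compared as correlation strengths
#' against the equal-strength line y = x: `above_line` compares absolute
#' values, `above_line_raw` the signed coefficients (the two differ because
#' `r_scale` is typically negative while `r_class` is positive). Use
#' [glance()] for the origin contrast: an exact sign test over
#' mitochondrial-only codes and a Fisher exact test of origin against side.
#'
#' @param codes Tibble of codes to compare, as from [genetic_codes()]
#'   (needs `table_id` and `origin` columns).
#' @param scale An [aa_scale()].
#' @param scheme A [cda_scheme()].
#' @param classes A synthetase class map.
#' @return A tibble (class `cda_code_comparison`) with one row per code:
#'   `table_id`, `name`, `origin`, `n_amino_acids`, `r_scale`, `r_class`,
#'   `above_line`, `above_line_raw`.
#' @examples
#' cc <- code_comparison()
#' glance(cc)
#' @export
code_comparison <- function(codes = genetic_codes(),
                            scale = aa_scale("antiparallel_beta"),
                            scheme = base_scheme(),
                            classes = synthetase_classes()) {
  scale_val <- stats::setNames(scale$value, scale$amino_acid)
  cls_dummy <- stats::setNames(
    ifelse(classes$class == "I", 1, 2),
    classes$amino_acid
  )
  out <- purrr::map_dfr(codes$table_id, function(id) {
    code <- genetic_code(id)
    am <- aa_mean_cda(code, scheme)
    if (anyNA(scale_val[am$amino_acid]) || anyNA(cls_dummy[am$amino_acid])) {
      rlang::abort(
        paste0("scale or class map does not cover code ", id),
        class = "cdar_bad_input"
      )
    }
    r_scale <- stats::cor(am$mean_cda, scale_val[am$amino_acid])
    r_class <- stats::cor(am$mean_cda, cls_dummy[am$amino_acid])
    tibble::tibble(
      table_id = attr(code, "table_id"),
      name = attr(code, "code_name"),
      origin = attr(code, "origin"),
      n_amino_acids = nrow(am),
      r_scale = r_scale,
      r_class = r_class,
      above_line = abs(r_scale) > abs(r_class),
      above_line_raw = r_scale > r_class
    )
  })
  attr(out, "scale_name") <- attr(scale, "scale_name")
  attr(out, "scheme") <- scheme_name(scheme)
  class(out) <- c("cda_code_comparison", class(out))
  out
}

#' @export
glance.cda_code_comparison <- function(x, ...) {
  mito <- x[x$origin == "mitochondrial", ]
  nuc <- x[x$origin == "nuclear", ]
  st <- sign_test(sum(mito$above_line), nrow(mito))
  fis <- fisher_exact(matrix(
    c(
      sum(mito$above_line), sum(!mito$above_line),
      sum(nuc$above_line), sum(!nuc$above_line)
    ),
    nrow = 2, byrow = TRUE
  ))
  tibble::tibble(
    n_codes = nrow(x),
    mito_above = sum(mito$above_line),
    mito_total = nrow(mito),
    nuclear_below = sum(!nuc$above_line),
    nuclear_total = nrow(nuc),
    both_above = sum(x$above_line[x$origin == "both"]),
    sign_p_one = st$p_one,
    sign_p_two = st$p_two,
    fisher_p_two = fis$p_two
  )
}
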