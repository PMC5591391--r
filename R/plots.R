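#' Plot a codon score table
#'
#' Tiles the 64 codons on a first-position by second/third-position grid,
#' filled by signed score, with the conventional U, C, A, G ordering.
#'
#' @param object A [score_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(score_table())
#' @export
autoplot.cda_score_table <- function(object, ...) {
  ucag <- c("U", "C", "A", "G")
  df <- tibble::tibble(
    codon = object$codon,
    p1 = factor(substr(object$codon, 1, 1), levels = rev(ucag)),
    p2 = factor(substr(object$codon, 2, 2), levels = ucag),
    p3 = factor(substr(object$codon, 3, 3), levels = ucag),
    cda = object$cda
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p3, y = .data$p1, fill = .data$cda)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$codon), size = 2.6) +
    ggplot2::facet_wrap(~p2, nrow = 1, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(
      low = "#b2182b", mid = "white", high = "#2166ac",
      limits = c(-1, 1), name = "CDA"
    ) +
    ggplot2::labs(
      x = "third position", y = "first position",
      title = paste0("Codon directional asymmetry (", attr(object, "scheme"), " scheme)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-amino-acid mean CDA against a propensity scale
#'
#' Scatter of a conformational scale against mean codon score, points
#' labelled by residue and shaped by synthetase class.
#'
#' @param object An [aa_mean_cda()] result.
#' @param scale An [aa_scale()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(aa_mean_cda(), aa_scale("antiparallel_beta"))
#' @export
autoplot.aa_cda <- function(object, scale = aa_scale("antiparallel_beta"), ...) {
  df <- dplyr::inner_join(object, scale, by = "amino_acid") |>
    dplyr::mutate(class = synthetase_class(.data$amino_acid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_cda, y = .data$value)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$class), size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$amino_acid), vjust = -0.8, size = 2.8) +
    ggplot2::scale_shape_manual(values = c(I = 1, II = 16), name = "synthetase class") +
    ggplot2::labs(
      x = "mean codon directional asymmetry",
      y = attr(scale, "scale_name")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a genetic-code comparison
#'
#' Correlation strength with the conformational scale against correlation
#' strength with the synthetase-class dummy, one point per genetic code,
#' with the equal-strength line y = x.
#'
#' @param object A [code_comparison()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(code_comparison())
#' @export
autoplot.cda_code_comparison <- function(object, ...) {
  df <- dplyr::mutate(object,
    x = abs(.data$r_class), y = abs(.data$r_scale)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$origin), size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$table_id), vjust = -0.8, size = 2.8) +
    ggplot2::scale_shape_manual(
      values = c(mitochondrial = 1, nuclear = 16, both = 13),
      name = "code origin"
    ) +
    ggplot2::labs(
      x = "|r| mean CDA vs synthetase-class dummy",
      y = paste0("|r| mean CDA vs ", attr(object, "scale_name"))
    ) +
    ggplot2::theme_minimal()
}
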