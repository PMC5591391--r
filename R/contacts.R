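#' Tetrahedral contact layouts
#'
#' A contact layout places the 64 codons on the cells of a tetrahedral
#' genetic-code representation (four triangular faces of 16 small triangles
#' each) and lists which cell pairs touch within a face and which touch
#' across faces. Published layouts exist only as figures, so layouts are
#' data, not code: `contact_layout()` builds one from R objects and
#' `read_contact_layout()` reads the JSON interchange format
#' (`{cells: [{codon, face, index}], within_pairs: [[i,j],...],
#' between_pairs: [[i,j],...]}`, pairs referring to 1-based rows of
#' `cells`).
#'
#' @param cells A data frame with columns `codon`, `face`, `index`.
#' @param within_pairs,between_pairs Two-column matrices (or lists of
#'   integer pairs) of cell row indices.
#' @return A `contact_layout` object.
#' @examples
#' cells <- data.frame(codon = c("AUU", "AAU"), face = "A", index = 1:2)
#' layout <- contact_layout(cells, within_pairs = rbind(c(1, 2)))
#' contact_analysis(layout)
#' @export
contact_layout <- function(cells, within_pairs = NULL, between_pairs = NULL) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("codon", "face", "index") %in% names(cells)))
  cells$codon <- normalize_codon(cells$codon)
  if (anyDuplicated(cells$codon)) {
    rlang::abort("each codon may be placed only once", class = "cdar_bad_layout")
  }
  as_pairs <- function(p) {
    if (is.null(p)) return(matrix(integer(0), ncol = 2))
    if (is.list(p)) p <- do.call(rbind, lapply(p, as.integer))
    p <- matrix(as.integer(p), ncol = 2)
    if (any(p < 1 | p > nrow(cells))) {
      rlang::abort("pair references an unplaced cell", class = "cdar_bad_layout")
    }
    p
  }
  out <- list(
    cells = cells,
    within_pairs = as_pairs(within_pairs),
    between_pairs = as_pairs(between_pairs)
  )
  class(out) <- "contact_layout"
  out
}

#' @rdname contact_layout
#' @param path Path to a layout JSON file.
#' @export
read_contact_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  contact_layout(
    cells = x$cells,
    within_pairs = x$within_pairs,
    between_pairs = x$between_pairs
  )
}

#' Opposite-sign contacts on a tetrahedral layout
#'
#' Counts the listed cell contacts joining codons of strictly opposite
#' score sign (zero-scored codons are never "opposite"), within faces (with
#' a per-face breakdown) and between faces. The result is symmetric in pair
#' order and invariant to a global sign flip of the score table.
#'
#' @param layout A [contact_layout()].
#' @param table A [score_table()].
#' @return A tibble with columns `scope` (`"within"`, per-face `"within:X"`
#'   rows, and `"between"`), `n_pairs`, `n_opposite`.
#' @export
contact_analysis <- function(layout, table = score_table()) {
  stopifnot(inherits(layout, "contact_layout"))
  score <- stats::setNames(table$cda, table$codon)
  s <- score[layout$cells$codon]
  opp <- function(pairs) {
    if (nrow(pairs) == 0) return(c(n = 0L, opp = 0L))
    a <- s[pairs[, 1]]
    b <- s[pairs[, 2]]
    c(n = nrow(pairs), opp = sum(a * b < 0))
  }
  w <- opp(layout$within_pairs)
  b <- opp(layout$between_pairs)
  per_face <- NULL
  if (nrow(layout$within_pairs) > 0) {
    face_of <- layout$cells$face[layout$within_pairs[, 1]]
    per_face <- purrr::map_dfr(sort(unique(face_of)), function(f) {
      sel <- layout$within_pairs[face_of == f, , drop = FALSE]
      o <- opp(sel)
      tibble::tibble(
        scope = paste0("within:", f),
        n_pairs = o[["n"]], n_opposite = o[["opp"]]
      )
    })
  }
  dplyr::bind_rows(
    tibble::tibble(scope = "within", n_pairs = w[["n"]], n_opposite = w[["opp"]]),
    per_face,
    tibble::tibble(scope = "between", n_pairs = b[["n"]], n_opposite = b[["opp"]])
  )
}

#' Expected opposite-sign contacts under random placement
#'
#' For `n_pairs` contacts and marginal sign fractions `f_neg`, `f_pos`,
#' the expected number of opposite-sign contacts is
#' `n_pairs * 2 * f_neg * f_pos`. With the base score table's 24/16/24 sign
#' split this gives 6.75 for 24 pairs and 18 for 64 pairs.
#'
#' @param n_pairs Number of contacts.
#' @param f_neg,f_pos Fractions of negative- and positive-scored codons,
#'   each in \[0, 1\].
#' @return Expected count (numeric).
#' @examples
#' expected_opposite(24, 24 / 64, 24 / 64)
#' @export
expected_opposite <- function(n_pairs, f_neg, f_pos) {
  stopifnot(f_neg >= 0, f_neg <= 1, f_pos >= 0, f_pos <= 1, n_pairs >= 0)
  n_pairs * 2 * f_neg * f_pos
}
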