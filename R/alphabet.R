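#' The RNA alphabet used throughout
#'
#' All codon arithmetic in cdar is carried out over the RNA alphabet
#' `A, C, G, U`; `T` is accepted everywhere on input as an alias of `U`.
#' Each nucleotide carries three attributes that the scoring rules use:
#' its chemical group (purine `A, G` versus pyrimidine `C, U`), whether it
#' pairs through three hydrogen bonds ("strong", `G` and `C`), and its
#' canonical Watson-Crick complement.
#'
#' @return A tibble with columns `symbol`, `group` (`"purine"` or
#'   `"pyrimidine"`), `strong` (logical) and `complement`.
#' @examples
#' nucleotides()
#' @export
nucleotides <- function() {
  tibble::tibble(
    symbol = c("A", "C", "G", "U"),
    group = c("purine", "pyrimidine", "purine", "pyrimidine"),
    strong = c(FALSE, TRUE, TRUE, FALSE),
    complement = c("U", "G", "C", "A")
  )
}

# internal lookup vectors (fast paths used by the scoring engine)
.nt_group <- c(A = "purine", G = "purine", C = "pyrimidine", U = "pyrimidine")
.nt_strong <- c(A = FALSE, G = TRUE, C = TRUE, U = FALSE)
.nt_complement <- c(A = "U", U = "A", G = "C", C = "G")
.nt_keto <- c(G = TRUE, U = TRUE, A = FALSE, C = FALSE) # keto vs amino divide

#' Normalize raw codon text
#'
#' Uppercases, maps `T` to `U`, and validates a vector of 3-letter codon
#' strings. Ambiguity codes (`N`, `R`, `Y`, ...) are rejected with an error
#' of class `cdar_ambiguous_base` so callers can distinguish them from
#' malformed input (class `cdar_bad_codon`).
#'
#' @param x Character vector of raw codons (e.g. `"att"`, `"AUU"`).
#' @return Character vector of canonical RNA codons.
#' @examples
#' normalize_codon(c("att", "AUU", "tga"))
#' @export
normalize_codon <- function(x) {
  x <- toupper(trimws(as.character(x)))
  bad_len <- nchar(x) != 3L
  if (any(bad_len)) {
    rlang::abort(
      paste0("codons must have exactly 3 letters: ", paste(x[bad_len], collapse = ", ")),
      class = "cdar_bad_codon"
    )
  }
  x <- chartr("T", "U", x)
  chars <- strsplit(x, "", fixed = TRUE)
  ok <- vapply(chars, function(ch) all(ch %in% c("A", "C", "G", "U")), logical(1))
  if (!all(ok)) {
    offending <- unique(unlist(lapply(chars[!ok], setdiff, y = c("A", "C", "G", "U"))))
    cls <- if (any(offending %in% c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V"))) {
      "cdar_ambiguous_base"
    } else {
      "cdar_bad_codon"
    }
    rlang::abort(
      paste0("invalid bases in codons: ", paste(x[!ok], collapse = ", ")),
      class = cls
    )
  }
  x
}

#' All 64 codons
#'
#' @param order `"alphabetical"` (default, A < C < G < U) or `"ucag"` for the
#'   conventional genetic-code table order (U, C, A, G at every position).
#' @return Character vector of 64 distinct codons.
#' @examples
#' head(codons())
#' @export
codons <- function(order = c("alphabetical", "ucag")) {
  order <- match.arg(order)
  b <- if (order == "ucag") c("U", "C", "A", "G") else c("A", "C", "G", "U")
  grid <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(grid$p1, grid$p2, grid$p3)
}

#' Reverse a codon (positions 3-2-1, no complementation)
#'
#' @param codon Character vector of codons.
#' @return Character vector of reversed codons.
#' @examples
#' reverse_codon("AUG")
#' @export
reverse_codon <- function(codon) {
  codon <- normalize_codon(codon)
  vapply(
    strsplit(codon, "", fixed = TRUE),
    function(ch) paste0(ch[3], ch[2], ch[1]),
    character(1)
  )
}
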