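.cdar_env <- new.env(parent = emptyenv())

.load_code_fixture <- function() {
  if (is.null(.cdar_env$codes)) {
    path <- system.file("extdata", "genetic_codes.json", package = "cdar")
    raw <- jsonlite::read_json(path)
    codes <- lapply(raw, function(x) {
      list(
        table_id = as.integer(x$table_id),
        name = x$name,
        origin = x$origin,
        assignment = unlist(x$assignment)
      )
    })
    names(codes) <- vapply(codes, function(x) as.character(x$table_id), character(1))
    .cdar_env$codes <- codes
  }
  .cdar_env$codes
}

#' Bundled genetic codes
#'
#' `genetic_codes()` lists the 21 bundled NCBI translation tables with their
#' origin tags (11 mitochondrial-only, 8 nuclear-only, 2 used in both
#' nuclear and mitochondrial genomes). `genetic_code(table_id)` returns one
#' code as a 64-row codon/amino-acid tibble. The roster is a reconstruction
#' of the NCBI compilation and ships as an editable JSON fixture
#' (`inst/extdata/genetic_codes.json`), so it can be corrected without code
#' changes.
#'
#' @param table_id NCBI translation-table number (e.g. 1 standard,
#'   2 vertebrate mitochondrial).
#' @return `genetic_codes()`: a tibble with `table_id`, `name`, `origin`.
#'   `genetic_code()`: a tibble (class `genetic_code`) with columns `codon`
#'   and `amino_acid` (three-letter residue codes or `"STOP"`), with the id,
#'   name and origin as attributes.
#' @examples
#' genetic_codes()
#' genetic_code(2)
#' @export
genetic_codes <- function() {
  codes <- .load_code_fixture()
  tibble::tibble(
    table_id = vapply(codes, function(x) x$table_id, integer(1)),
    name = vapply(codes, function(x) x$name, character(1)),
    origin = vapply(codes, function(x) x$origin, character(1))
  )
}

#' @rdname genetic_codes
#' @export
genetic_code <- function(table_id = 1) {
  codes <- .load_code_fixture()
  key <- as.character(as.integer(table_id))
  if (!key %in% names(codes)) {
    rlang::abort(
      paste0("unknown translation table id: ", table_id),
      class = "cdar_unknown_code"
    )
  }
  x <- codes[[key]]
  out <- tibble::tibble(
    codon = names(x$assignment),
    amino_acid = unname(x$assignment)
  )
  attr(out, "table_id") <- x$table_id
  attr(out, "code_name") <- x$name
  attr(out, "origin") <- x$origin
  class(out) <- c("genetic_code", class(out))
  out
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(
    "<genetic_code ", attr(x, "table_id"), ": ", attr(x, "code_name"),
    " (", attr(x, "origin"), ")>\n",
    sep = ""
  )
  NextMethod()
}

#' Aminoacyl-tRNA synthetase classes
#'
#' The twenty standard amino acids split 10/10 between the two structural
#' families of aminoacyl-tRNA synthetases: class I enzymes aminoacylate the
#' 2' hydroxyl of the tRNA's terminal ribose, class II the 3' hydroxyl.
#'
#' @return `synthetase_classes()`: a 20-row tibble with `amino_acid` and
#'   `class` (`"I"` or `"II"`).
#' @examples
#' synthetase_class(c("Leu", "Ala"))
#' @export
synthetase_classes <- function() {
  tibble::tibble(
    amino_acid = c(
      "Arg", "Cys", "Gln", "Glu", "Ile", "Leu", "Met", "Trp", "Tyr", "Val",
      "Ala", "Asn", "Asp", "Gly", "His", "Lys", "Phe", "Pro", "Ser", "Thr"
    ),
    class = rep(c("I", "II"), each = 10)
  )
}

#' @rdname synthetase_classes
#' @param amino_acid Character vector of three-letter residue codes.
#' @export
synthetase_class <- function(amino_acid) {
  map <- synthetase_classes()
  idx <- match(amino_acid, map$amino_acid)
  if (anyNA(idx)) {
    rlang::abort(
      paste0(
        "unknown residue(s): ",
        paste(unique(amino_acid[is.na(idx)]), collapse = ", ")
      ),
      class = "cdar_unknown_residue"
    )
  }
  map$class[idx]
}

.scale_registry <- c(
  antiparallel_beta = "scale_antiparallel_beta.tsv",
  parallel_beta = "scale_parallel_beta.tsv",
  all_beta = "scale_all_beta.tsv",
  alpha_helix = "scale_alpha_helix.tsv",
  beta_turn = "scale_beta_turn.tsv"
)

#' Amino-acid conformational propensity scales
#'
#' Loads one of the bundled secondary-structure propensity scales
#' (`"antiparallel_beta"`, `"parallel_beta"`, `"all_beta"` from the
#' Lifson-Sander beta-strand preference statistics; `"alpha_helix"` and
#' `"beta_turn"` from the Chou-Fasman conformational parameters) or a user
#' TSV with columns `residue` and `value` covering all 20 standard residues.
#' The provenance string recorded in the file header travels with the
#' result, so substituting a different transcription of a scale stays
#' auditable.
#'
#' @param name Registry name or path to a TSV file.
#' @return A 20-row tibble (class `aa_scale`) with columns `amino_acid` and
#'   `value`, with `scale_name` and `provenance` attributes.
#' @examples
#' aa_scale("antiparallel_beta")
#' @export
aa_scale <- function(name) {
  if (name %in% names(.scale_registry)) {
    path <- system.file("extdata", .scale_registry[[name]], package = "cdar")
    scale_name <- name
  } else {
    path <- name
    scale_name <- basename(name)
    if (!file.exists(path)) {
      rlang::abort(paste0("no such scale or file: ", name), class = "cdar_unknown_scale")
    }
  }
  header <- readLines(path, n = 10)
  prov <- sub("^#\\s*provenance:\\s*", "", grep("^#\\s*provenance:", header, value = TRUE))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(df))) {
    rlang::abort("scale file must have columns 'residue' and 'value'", class = "cdar_bad_scale")
  }
  aa20 <- sort(synthetase_classes()$amino_acid)
  if (!setequal(df$residue, aa20) || nrow(df) != 20) {
    rlang::abort("scale must cover exactly the 20 standard residues", class = "cdar_bad_scale")
  }
  if (!is.numeric(df$value) || anyNA(df$value) || any(!is.finite(df$value))) {
    rlang::abort("scale values must be finite numbers", class = "cdar_bad_scale")
  }
  out <- tibble::tibble(amino_acid = df$residue, value = df$value)
  attr(out, "scale_name") <- scale_name
  attr(out, "provenance") <- if (length(prov)) prov[[1]] else NA_character_
  class(out) <- c("aa_scale", class(out))
  out
}

#' The natural circular code X0
#'
#' The 20-trinucleotide set, conserved across genes, whose usage in coding
#' frames permits reading-frame retrieval. Bundled as a plain-text fixture.
#'
#' @return Character vector of 20 codons (RNA form).
#' @examples
#' circular_code_x0()
#' @export
circular_code_x0 <- function() {
  path <- system.file("extdata", "circular_code_x0.txt", package = "cdar")
  x <- readLines(path)
  normalize_codon(x[!startsWith(x, "#")])
}
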