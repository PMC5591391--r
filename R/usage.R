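#' Read coding sequences into codon records
#'
#' Reads CDS nucleotide sequences from a FASTA file (plain CDS, assumed
#' coding-strand) or from a GenBank flat file (CDS features are extracted
#' with their location, `complement(...)` and `join(...)` honoured, so the
#' returned codons are already in coding orientation). Sequences are split
#' into codons from position 1 in the first frame only. Lengths not
#' divisible by 3 are an error under `frame_policy = "error"` or trimmed at
#' the 3' end under `"trim"`; codons containing ambiguity codes are dropped
#' and counted.
#'
#' @param path Path to the sequence file.
#' @param format `"auto"` (by extension/content), `"fasta"` or `"genbank"`.
#' @param code_id Translation table id recorded on each record.
#' @param frame_policy `"error"` or `"trim"`.
#' @return A tibble with one row per CDS: `id`, `codons` (list-column of
#'   codon vectors), `n_codons`, `n_ambiguous_dropped`, `n_trimmed_bases`,
#'   `code_id`, `source`.
#' @export
read_cds <- function(path, format = c("auto", "fasta", "genbank"),
                     code_id = 1, frame_policy = c("error", "trim")) {
  format <- match.arg(format)
  frame_policy <- match.arg(frame_policy)
  if (!file.exists(path)) {
    rlang::abort(paste0("cannot read: ", path), class = "cdar_bad_input")
  }
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, ">")) "fasta" else "genbank"
  }
  seqs <- if (format == "fasta") .read_fasta(path) else .read_genbank_cds(path)
  if (length(seqs) == 0) {
    rlang::abort("no CDS found", class = "cdar_bad_input")
  }
  recs <- purrr::imap(seqs, function(s, id) {
    s <- toupper(chartr("t", "u", chartr("T", "U", s)))
    n_trim <- nchar(s) %% 3
    if (n_trim != 0) {
      if (frame_policy == "error") {
        rlang::abort(
          paste0("CDS length of ", id, " not divisible by 3"),
          class = "cdar_bad_frame"
        )
      }
      s <- substr(s, 1, nchar(s) - n_trim)
    }
    cods <- substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
    ok <- !grepl("[^ACGU]", cods)
    tibble::tibble(
      id = id,
      codons = list(cods[ok]),
      n_codons = sum(ok),
      n_ambiguous_dropped = sum(!ok),
      n_trimmed_bases = n_trim
    )
  })
  out <- dplyr::bind_rows(recs)
  out$code_id <- code_id
  out$source <- path
  out
}

.read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(path)
    return(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))))
  }
  # fallback plain-text reader
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  body <- tapply(lines[!hdr], grp[!hdr], paste, collapse = "")
  stats::setNames(as.character(body), id)
}

# Minimal GenBank flat-file CDS extractor: parses ORIGIN sequence blocks and
# CDS feature locations with complement()/join(); spans crossing record ends
# or with external references are rejected.
.read_genbank_cds <- function(path) {
  lines <- readLines(path)
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0) {
    rlang::abort("not a GenBank flat file", class = "cdar_bad_input")
  }
  rec_ends <- c(rec_starts[-1] - 1, length(lines))
  out <- list()
  for (r in seq_along(rec_starts)) {
    block <- lines[rec_starts[r]:rec_ends[r]]
    locus <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    ori <- grep("^ORIGIN", block)
    if (length(ori) == 0) next
    seq_lines <- block[(ori[1] + 1):length(block)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seqchr <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    feat_idx <- grep("^\\s{5}CDS\\s", block)
    for (i in seq_along(feat_idx)) {
      j <- feat_idx[i]
      loc <- trimws(sub("^\\s{5}CDS\\s+", "", block[j]))
      jj <- j + 1
      while (jj <= length(block) && grepl("^\\s{6,}", block[jj]) &&
        !startsWith(trimws(block[jj]), "/") &&
        !grepl("^\\s{5}\\S", block[jj])) {
        loc <- paste0(loc, trimws(block[jj]))
        jj <- jj + 1
      }
      gene <- NA_character_
      while (jj <= length(block) && grepl("^\\s{10,}/", block[jj])) {
        m <- regmatches(block[jj], regexec("/(gene|locus_tag)=\"([^\"]+)\"", block[jj]))[[1]]
        if (length(m) == 3 && is.na(gene)) gene <- m[3]
        jj <- jj + 1
      }
      s <- .extract_location(seqchr, loc)
      id <- if (is.na(gene)) paste0(locus, "_CDS", i) else paste0(locus, "_", gene)
      out[[id]] <- s
    }
  }
  unlist(out)
}

.extract_location <- function(seqchr, loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  comp <- FALSE
  if (grepl("^complement\\(", loc)) {
    comp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("[A-Za-z]", gsub("complement", "", loc))) {
    rlang::abort("unsupported CDS location (external reference?)", class = "cdar_bad_input")
  }
  spans <- strsplit(loc, ",", fixed = TRUE)[[1]]
  pieces <- vapply(spans, function(sp) {
    ends <- as.integer(strsplit(sp, "..", fixed = TRUE)[[1]])
    if (length(ends) == 1) ends <- c(ends, ends)
    substr(seqchr, ends[1], ends[2])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (comp) {
    s <- chartr("ACGTU", "TGCAA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  s
}

#' Codon usage table
#'
#' Pools codon counts over a set of CDS records (or a plain codon vector)
#' and reports per-mil frequencies over all 64 codons.
#'
#' @param records A tibble from [read_cds()], a list of codon vectors, or a
#'   character vector of codons.
#' @param scope Label recorded on the table.
#' @return A 64-row tibble with `codon`, `count`, `promil`
#'   (`count / total * 1000`).
#' @examples
#' codon_usage(c("AUG", "AAU"))
#' @export
codon_usage <- function(records, scope = "pooled") {
  cods <- if (is.data.frame(records)) {
    unlist(records$codons)
  } else if (is.list(records)) {
    unlist(records)
  } else {
    records
  }
  cods <- normalize_codon(cods)
  if (length(cods) == 0) {
    rlang::abort("no codons to count", class = "cdar_bad_input")
  }
  counts <- table(factor(cods, levels = codons()))
  out <- tibble::tibble(
    codon = codons(),
    count = as.integer(counts),
    promil = as.numeric(counts) / length(cods) * 1000
  )
  attr(out, "scope") <- scope
  out
}

#' Usage-weighted mean CDA
#'
#' Count-weighted mean codon score of a usage table. With
#' `include_stops = FALSE` a genetic code must be supplied and its stop
#' codons are excluded from the average.
#'
#' @param usage A [codon_usage()] table (or any tibble with `codon` plus
#'   `count` or `promil`).
#' @param table A [score_table()].
#' @param include_stops Include stop codons (default `TRUE`).
#' @param code A [genetic_code()], required when `include_stops = FALSE`.
#' @return A single numeric value.
#' @examples
#' mean_cda_of_usage(codon_usage(c("AUG", "AAU")))
#' @export
mean_cda_of_usage <- function(usage, table = score_table(),
                              include_stops = TRUE, code = NULL) {
  wcol <- if ("count" %in% names(usage)) "count" else "promil"
  w <- usage[[wcol]]
  s <- table$cda[match(usage$codon, table$codon)]
  if (!include_stops) {
    if (is.null(code)) {
      rlang::abort("supply a genetic code to exclude stops", class = "cdar_bad_input")
    }
    stops <- code$codon[code$amino_acid == "STOP"]
    keep <- !usage$codon %in% stops
    w <- w[keep]
    s <- s[keep]
  }
  if (sum(w) == 0) {
    rlang::abort("usage table has zero mass", class = "cdar_bad_input")
  }
  sum(w * s) / sum(w)
}

#' GC content of a usage table
#'
#' Fraction of G and C bases among all bases implied by the codon counts.
#'
#' @param usage A [codon_usage()] table.
#' @return Fraction in \[0, 1\].
#' @examples
#' gc_content(codon_usage(c("GCG", "AUA")))
#' @export
gc_content <- function(usage) {
  wcol <- if ("count" %in% names(usage)) "count" else "promil"
  w <- usage[[wcol]]
  gc_per_codon <- vapply(
    strsplit(usage$codon, "", fixed = TRUE),
    function(ch) sum(ch %in% c("G", "C")),
    numeric(1)
  )
  sum(w * gc_per_codon) / (3 * sum(w))
}

#' Bundled longevity-cohort codon usage
#'
#' Mean codon frequencies (per mil) in the 13 mitogenome-encoded protein
#' genes of three cohorts of Japanese males: 97 healthy controls, 112
#' semi-supercentenarians and 96 centenarians, as published (two-decimal
#' precision). The `cda` column carries the published base-scheme score for
#' each codon and serves as a transcription fixture.
#'
#' @return A 64-row tibble with `codon`, `cda`, `control`,
#'   `supercentenarian`, `centenarian`.
#' @examples
#' head(longevity_cohort_usage())
#' @export
longevity_cohort_usage <- function() {
  path <- system.file("extdata", "longevity_codon_usage.tsv", package = "cdar")
  tibble::as_tibble(utils::read.delim(path, comment.char = "#"))
}

#' Per-score-class cohort comparison of codon frequencies
#'
#' For each CDA value of the score table, counts how many codons are more
#' frequent in group A than in group B, fewer, or tied, at a declared
#' comparison precision (published tables are typically rounded, which
#' creates ties that full-precision data would not), plus an exact sign
#' test over the non-tied codons of each class.
#'
#' @param usage_a,usage_b Usage tables covering all 64 codons (columns
#'   `codon` and `promil` or `count`).
#' @param table A [score_table()].
#' @param precision Decimal places at which frequencies are compared.
#' @return A tibble with one row per CDA value: `cda`, `n_codons`,
#'   `higher`, `lower`, `tied`, `p_one`, `p_two` (NA when all tied).
#' @examples
#' u <- longevity_cohort_usage()
#' cohort_compare(
#'   dplyr::transmute(u, codon, promil = supercentenarian),
#'   dplyr::transmute(u, codon, promil = control)
#' )
#' @export
cohort_compare <- function(usage_a, usage_b, table = score_table(),
                           precision = 2) {
  wcol <- function(u) if ("promil" %in% names(u)) "promil" else "count"
  fa <- round(usage_a[[wcol(usage_a)]][match(table$codon, usage_a$codon)], precision)
  fb <- round(usage_b[[wcol(usage_b)]][match(table$codon, usage_b$codon)], precision)
  if (anyNA(fa) || anyNA(fb)) {
    rlang::abort("usage tables must cover all 64 codons", class = "cdar_bad_input")
  }
  df <- tibble::tibble(cda = table$cda, a = fa, b = fb)
  df |>
    dplyr::group_by(.data$cda) |>
    dplyr::summarise(
      n_codons = dplyr::n(),
      higher = sum(.data$a > .data$b),
      lower = sum(.data$a < .data$b),
      tied = sum(.data$a == .data$b),
      .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      p_one = if (.data$higher + .data$lower > 0) {
        sign_test(.data$higher, .data$higher + .data$lower)$p_one
      } else {
        NA_real_
      },
      p_two = if (!is.na(.data$p_one)) min(1, 2 * .data$p_one) else NA_real_
    ) |>
    dplyr::ungroup()
}
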