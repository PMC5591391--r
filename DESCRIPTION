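Package: cdar
Title: Codon Directional Asymmetry and Genetic Code Symmetry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the 64 codons by directional asymmetry in nucleotide
    content (CDA): palindromic codons score zero, codons whose 5' or 3'
    extremity carries the nucleotide most different from the other two score
    negative or positive, with magnitudes set by purine/pyrimidine grouping
    and canonical complementarity. Provides the base and six alternative
    magnitude schemes, per-amino-acid aggregation under 21 bundled NCBI
    translation tables, aminoacyl-tRNA synthetase class summaries,
    genetic-code symmetry machinery (six-bit codon representation, Rumer and
    other systematic nucleotide exchanges, circular-code and tetrahedral
    contact analyses), the statistical toolbox used around these scores
    (exact sign tests, Mann-Whitney, Fisher exact, group-residualized
    partial correlation, a rank-based multiple-testing adjustment), a codon
    usage pipeline from coding sequences, and seeded synthetic-data
    generators for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
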