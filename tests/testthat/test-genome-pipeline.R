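test_that("FASTA CDS records split into codons with frame and ambiguity policies", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(g1 = "ATGAAT"), f)
  recs <- read_cds(f)
  expect_equal(recs$codons[[1]], c("AUG", "AAU"))
  write_fasta(list(g1 = "ATGAA"), f)
  expect_error(read_cds(f, frame_policy = "error"), class = "cdar_bad_frame")
  trimmed <- read_cds(f, frame_policy = "trim")
  expect_equal(trimmed$codons[[1]], "AUG")
  expect_equal(trimmed$n_trimmed_bases, 2)
  write_fasta(list(g1 = "ATGNNT"), f)
  amb <- read_cds(f)
  expect_equal(amb$codons[[1]], "AUG")
  expect_equal(amb$n_ambiguous_dropped, 1)
  expect_error(read_cds(tempfile()), class = "cdar_bad_input")
})

test_that("GenBank CDS features are extracted with join and complement locations", {
  f <- withr::local_tempfile(fileext = ".gb")
  # 30-base record; one forward CDS 1..6, one complement(join(7..9,13..15))
  seqraw <- "atgaatcccgggtttaaacccgggtttaaa"
  writeLines(c(
    "LOCUS       TEST0001                30 bp    DNA     linear   UNA 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..6",
    '                     /gene="fwd"',
    "     CDS             complement(join(7..9,13..15))",
    '                     /gene="rev"',
    "ORIGIN",
    paste0("        1 ", seqraw),
    "//"
  ), f)
  recs <- read_cds(f, format = "genbank")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$codons[[which(recs$id == "TEST0001_fwd")]], c("AUG", "AAU"))
  # complement of join: ccc (7..9) + ttt (13..15) = "cccttt", revcomp = "aaaggg"
  expect_equal(recs$codons[[which(recs$id == "TEST0001_rev")]], c("AAA", "GGG"))
})

test_that("codon usage pools counts into per-mil frequencies", {
  u <- codon_usage(c("AUG", "AAU"))
  expect_equal(u$count[u$codon == "AUG"], 1L)
  expect_equal(u$promil[u$codon == "AAU"], 500)
  expect_equal(sum(u$promil), 1000)
  expect_equal(sum(u$count), 2L)
  expect_error(codon_usage(character(0)), class = "cdar_bad_input")
})

test_that("usage-derived mean CDA is count-weighted and respects the zero-sum table", {
  expect_equal(mean_cda_of_usage(codon_usage("GCC")), cda("GCC"))
  expect_equal(mean_cda_of_usage(codon_usage(c("AUG", "AAU"))), 0.25)
  uniform <- tibble::tibble(codon = codons(), count = 5L)
  expect_equal(mean_cda_of_usage(uniform), 0)
  # stop exclusion needs a code
  u <- codon_usage(c("AUG", "UAA"))
  expect_error(mean_cda_of_usage(u, include_stops = FALSE), class = "cdar_bad_input")
  expect_equal(
    mean_cda_of_usage(u, include_stops = FALSE, code = genetic_code(1)),
    cda("AUG")
  )
})

test_that("the usage pipeline is linear in counts and scale-invariant in promil", {
  a <- codon_usage(c("AUG", "AAU", "AAU"))
  b <- codon_usage(c("GCC", "UUU"))
  pooled <- tibble::tibble(codon = codons(), count = a$count + b$count)
  na <- sum(a$count)
  nb <- sum(b$count)
  expect_equal(
    mean_cda_of_usage(pooled),
    (na * mean_cda_of_usage(a) + nb * mean_cda_of_usage(b)) / (na + nb)
  )
  scaled <- tibble::tibble(codon = a$codon, count = a$count * 7L)
  expect_equal(mean_cda_of_usage(scaled), mean_cda_of_usage(a))
  expect_equal(
    codon_usage(rep(c("AUG", "AAU"), 3))$promil,
    codon_usage(c("AUG", "AAU"))$promil
  )
})

test_that("GC content counts bases, not codons", {
  expect_equal(gc_content(codon_usage("GCG")), 1)
  expect_equal(gc_content(codon_usage("AUA")), 0)
  expect_equal(gc_content(codon_usage(c("AUA", "GCG"))), 0.5)
})

test_that("the bundled cohort usage fixture is complete and consistent", {
  u <- longevity_cohort_usage()
  expect_equal(nrow(u), 64)
  expect_setequal(u$codon, codons())
  # published score column agrees with the rule engine
  tab <- score_table()
  expect_equal(u$cda, tab$cda[match(u$codon, tab$codon)])
  # per-mil columns sum to 1000 within two-decimal rounding of 64 entries
  for (col in c("control", "supercentenarian", "centenarian")) {
    expect_lt(abs(sum(u[[col]]) - 1000), 64 * 0.005)
  }
})

test_that("cohort comparison ties everything for identical tables and splits by score class", {
  u <- longevity_cohort_usage()
  ua <- tibble::tibble(codon = u$codon, promil = u$supercentenarian)
  ub <- tibble::tibble(codon = u$codon, promil = u$control)
  same <- cohort_compare(ua, ua)
  expect_true(all(same$tied == same$n_codons))
  expect_true(all(is.na(same$p_one)))
  cc <- cohort_compare(ua, ub, precision = 2)
  expect_equal(cc$n_codons, c(8, 16, 16, 16, 8))
  plus1 <- cc[cc$cda == 1, ]
  expect_equal(c(plus1$higher, plus1$lower, plus1$tied), c(3, 3, 2))
  expect_equal(plus1$higher + plus1$lower + plus1$tied, plus1$n_codons)
})

test_that("grouped trait association recovers a noiseless negative slope", {
  panel <- simulate_trait_panel(n_species = 16, n_groups = 4, beta = -30, sigma = 0, seed = 5)
  ga <- grouped_trait_assoc(panel)
  expect_true(all(ga$sign[!is.na(ga$sign)] < 0))
  g <- glance(ga)
  expect_equal(g$estimate, -1)
  expect_equal(g$n_negative_groups, g$n_groups)
  # a group of two species contributes a sign but no correlation
  mixed <- tibble::tibble(
    mean_cda = c(-0.1, 0.2, -0.3, 0, 0.3),
    trait = c(5, 1, 9, 6, 3),
    group = c("pair", "pair", "trio", "trio", "trio")
  )
  ga2 <- grouped_trait_assoc(mixed)
  pair <- ga2[ga2$group == "pair", ]
  expect_equal(pair$sign, -1L)
  expect_true(is.na(pair$estimate))
  expect_false(is.na(ga2$estimate[ga2$group == "trio"]))
})

test_that("bilateral stability is the left-right correlation per species", {
  d <- data.frame(
    species = rep(c("a", "b"), each = 4),
    left = c(10, 12, 11, 13, 5, 6, 7, 8),
    right = c(10, 12, 11, 13, 8, 5, 7, 6)
  )
  st <- bilateral_stability(d)
  expect_equal(st$stability[st$species == "a"], 1)
  expect_lt(st$stability[st$species == "b"], 1)
  dd <- data.frame(species = "c", left = c(1, 1, 1), right = c(2, 3, 4))
  expect_warning(st2 <- bilateral_stability(dd), "constant")
  expect_true(is.na(st2$stability))
  # too few individuals: NA without warning
  st3 <- bilateral_stability(data.frame(species = "d", left = 1:2, right = 2:1))
  expect_true(is.na(st3$stability))
})

test_that("positional controls rank-correlate gene mean CDA with exposure", {
  genes <- data.frame(gene = c("a", "b", "c"), mean_cda = c(-0.2, 0, 0.3))
  expect_equal(
    positional_control_assoc(genes, data.frame(gene = genes$gene, exposure = c(1, 2, 3)))$estimate,
    1
  )
  expect_equal(
    positional_control_assoc(genes, data.frame(gene = genes$gene, exposure = c(3, 2, 1)))$estimate,
    -1
  )
  expect_error(
    positional_control_assoc(genes, data.frame(gene = c("a", "b", "x"), exposure = 1:3)),
    class = "cdar_bad_input"
  )
})
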