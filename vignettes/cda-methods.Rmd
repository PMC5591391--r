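---
title: "Codon directional asymmetry: model, scoring rules and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon directional asymmetry: model, scoring rules and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdar)
```

## The score and its rules

Codon directional asymmetry (CDA) asks, for each codon, which extremity —
5′ or 3′ — carries the nucleotide most different from the codon's other two
nucleotides, and by how much. The sign convention is arbitrary but fixed:
5′-dominant codons score negative, 3′-dominant codons positive.

The classification proceeds in a strict rule order (`classify_codons()`):

1. **Palindromic codons** (`XZX`, first and third nucleotide identical,
   homopolymers included) are symmetric: score 0. There are 16 of them.
2. **Repeated-letter codons** `ZXX` / `XXZ`: the lone extremity dominates
   (5′ for `ZXX`, 3′ for `XXZ`). The magnitude is 1 when `Z` and `X` sit on
   opposite sides of the purine/pyrimidine divide, and enters half-strength
   group (a) when they share a side — purine–purine and
   pyrimidine–pyrimidine contrasts are chemically smaller.
3. **All-distinct codons** `XZW` where the middle nucleotide shares a
   purine/pyrimidine group with one extremity: the *other* extremity is the
   most different (group b).
4. **All-distinct codons whose middle nucleotide is alone in its group**:
   both extremities then sit in the other group, and canonical Watson–Crick
   complementarity breaks the tie — the extremity complementary to the
   middle nucleotide is "most different" and dominates (group c).

Under the base scheme all half-strength groups score 0.5 and the full
group 1, giving the five-valued score set {−1, −0.5, 0, +0.5, +1} with a
24/16/24 negative/zero/positive split. Because the three half-strength
rationales are partly arbitrary, six alternative schemes
(`alternative_schemes()`) keep the full magnitude at 1 and permute
(0.25, 0.5, 0.75) across groups (a, b, c). All magnitudes are quarters, so
scores and their sums are exact in double precision; equality tests in the
suite are exact, not approximate.

Three structural invariances follow from the rules and are enforced as
properties: reversal antisymmetry (reversing a codon flips the sign),
invariance under the complement exchange A↔U, G↔C at every position, and
invariance under the transition exchange A↔G, C↔U. The last two are what
make CDA *exactly* uncorrelated (r = 0, not merely small) with each of the
six binary codon bits — purine and strong-pairing indicators per position
(`cda_bit_independence()`): each exchange flips one family of bits while
permuting codons without changing scores, and scores sum to zero.

## Aggregation and the synthetase-class contrast

`aa_mean_cda()` averages codon scores within each amino acid's codon
family under any of the 21 bundled translation tables. Stop codons never
enter residue means (they are reported separately); codes that reassign a
stop to a residue include the reassigned codon in that residue's mean.
Usage weights, when supplied, weight the mean within each synonymous
family by observed counts.

The aminoacyl-tRNA synthetase contrast (`class_sign_summary()`) is run at
two levels. At the codon level, zero-scored codons carry no directional
information for a sign test, so they are excluded from the
negative/positive counts and reported separately. At the amino-acid level
the package counts residues whose mean score matches the expected
direction (class I negative, class II positive): 8 of 10 in each class
under the standard code, exceptions Cys and Leu (class I) and Ala and Thr
(class II), a pattern that is identical under all six alternative
schemes. One published codon-level count disagrees with the published
score table itself (17 versus 18 positive codons among the 24 nonzero
class-II codons); the package reports the value implied by the score
table, 18.

## Statistical conventions

- **Sign tests** are exact binomial; both tails are always reported. The
  published one-tailed values (0.039 for 15/21, 0.032 for 17/24) reproduce
  exactly; several published values labelled two-tailed match only the
  one-tailed computation, so the reporting here is explicit rather than
  relabelled.
- **Mann–Whitney** uses full enumeration of group assignments up to a
  combined n of 12 (tie-safe by construction) and a tie-corrected,
  continuity-corrected normal approximation beyond; the result records
  which branch ran.
- **Fisher's exact test** enumerates the hypergeometric distribution of
  the 2×2 table.
- **The one-cell chi-square** `(O − E)²/E` on 1 df, without continuity
  correction, reproduces the published contact-analysis P values (0.018
  for 8 observed versus 18 expected).
- **The ranked multiple-testing adjustment** (`bh_adjust()`) multiplies
  each P by k divided by its rank, with rank 1 assigned to the *largest* P
  — the convention under which the published adjustment table reproduces
  (0.002 with k = 58 and rank 56 adjusts to 0.00207). Unlike the standard
  Benjamini–Hochberg step-up there is no cumulative-minimum step, and
  adjusted values are deliberately left uncapped so that
  `p_adj / p_raw = k / rank` holds exactly. The standard step-up is
  available as a labelled alternative (`method = "step_up"`), never
  silently substituted.
- **Group-residualized partial association** subtracts class means of both
  variables before correlating, the device used to show the
  score–betasheet association is not an artifact of synthetase classes.

## Scales and their provenance

The conformational scale fixtures are transcribed from the AAindex
compilation: the beta-strand preference statistics of Lifson and Sander
(antiparallel, parallel, and pooled variants) and the Chou–Fasman
conformational parameters (alpha helix, beta turn). Provenance strings are
carried in the TSV headers and on every loaded scale object. With the
antiparallel transcription bundled here, the standard-code correlation
between per-amino-acid mean CDA and antiparallel betasheet preference is
r = −0.637 (published: −0.642) and the class-residualized partial
correlation is −0.429 (published: −0.435); the parallel-betasheet control
reproduces exactly at the published precision (−0.28). The residual
differences are consistent with a slightly different transcription of the
same scale having been used originally; exact agreement is therefore
scale-provenance-dependent, which is why the package treats scales as
auditable data rather than constants.

## The genetic-code roster and the code comparison

The published comparison across genetic codes uses 21 translation tables
(11 mitochondrial-only, 8 nuclear-only, 2 used in both compartments) but
never prints the roster. The bundled reconstruction takes the NCBI
compilation: mitochondrial-only tables 2, 3, 5, 9, 13, 14, 16, 21, 22,
23, 24; nuclear-only 6, 10, 11, 12, 15, 25, 26, 27; and tables 1
(standard) and 4 (Mycoplasma/Spiroplasma) as "both". The roster ships as
editable JSON so it can be corrected without touching code.

`code_comparison()` computes, per code, the Pearson correlation of
per-amino-acid mean CDA with the antiparallel scale (`r_scale`) and with
the synthetase-class dummy variable coded 1/2 (`r_class`), per the
published definition of both axes. Since `r_scale` is negative and
`r_class` positive throughout, "stronger" is compared as absolute values
(`above_line`), with the raw signed comparison also reported. With the
bundled scale and roster, 10 of the 11 mitochondrial-only codes fall above
the equal-strength line; the eleventh (table 9) misses it by
|r_scale| − |r_class| = −0.0026, an order of magnitude less than the
scale-transcription uncertainty described above, so the published 11/11 is
within provenance noise but not exactly reproduced here. The companion
published claim that six of eight nuclear-only codes fall *below* the line
is not reproducible under any 20-value scale consistent with the rest of
the analysis: two nuclear tables (6 and 11) have amino-acid mean CDA
identical to the standard code — which is itself above the line — and the
other nuclear variants perturb at most one residue mean, leaving all eight
on the standard code's side. Both facts are reported by the package rather
than forced.

Similarly, the direction claim for the natural circular code is reported,
not asserted: with the bundled X0 membership and the base scores, mean
|CDA| is *higher* inside the code (0.65) than outside (0.43);
`circular_abs_cda()` returns both group means, the signed difference and
the rank test, leaving interpretation to the caller.

Tetrahedral layouts of the genetic code are published only as figures, so
layout geometry is data: `contact_layout()` objects carry explicit cell
placements and contact lists, the analysis counts strictly-opposite-sign
contacts (zeros are never "opposite"), and the null expectation
`n_pairs · 2 f₋ f₊` reproduces the published 6.75 (24 pairs) and 18 (64
pairs) reference values.

## Synthetic data: what it emulates and what it does not

The generators exist so that every pipeline stage is testable without
sequence downloads; their defaults are the study conditions, not tuning
knobs.

- `simulate_usage()` draws codon counts from a multinomial tilted *within
  synonymous families*: probabilities proportional to
  `base × exp(−λ · CDA)`, renormalized per family, so amino-acid
  composition is held fixed and only synonymous choice responds to the
  tilt — matching the premise that CDA-related selection acts on
  synonymous codon choice. λ = 0 recovers the base usage exactly.
- `simulate_trait_panel()` emulates a reptile-like species panel: 30
  species in 8 phylogenetic groups, per-species tilt drawn uniformly from
  (−1, 1), about 3800 codons of mitogenome-encoded protein per species
  (the size of a vertebrate mitochondrial proteome), and a trait
  `β · meanCDA + N(0, σ)` on a body-temperature-like scale. The defaults
  β = −30 and σ = 2 give a signal-to-noise ratio near one (the realized
  spread of species mean CDA under these tilts is ≈ 0.08).
- `simulate_cohorts()` emulates the cohort contrast: group B from a base
  codon composition (by default the bundled control-cohort table), group A
  with the probability mass of score-−1 codons multiplied by δ and
  renormalized; δ = 1 gives exchangeable cohorts.

What the generators do *not* emulate: phylogenetic covariance between
species (groups are independent by construction, which is exactly the
assumption the grouped sign test makes), sequence-level mutation
processes, gene-to-gene heterogeneity within a species, and linkage
between synonymous sites. Passing calibration and power checks therefore
demonstrates that the analysis code recovers known composition-level
structure, not that real mitogenomes behave this way.

`recovery_report()` runs the calibration suite consumed by the tests: with
400 null panels, the overall-correlation test holds its nominal 5% level;
the cross-group sign test over 8 groups is necessarily conservative
because its attainable size is discrete (P(X ≥ 7 | 8, ½) = 0.035), and is
checked against that attainable size rather than against a level it cannot
reach. Power rises monotonically in β, δ and λ, and the δ = 1.05 cohort
scenario at 10⁶ codons recovers the enriched class in ≳ 90% of
replicates. Problem sizes (replicate counts, codon totals) are set so the
whole suite runs comfortably on a single CPU.

## Numerical choices and degenerate inputs

- Scores are quarters; all invariance tests use exact equality.
- Codons are validated strictly: ambiguity codes raise a distinct error
  class (`cdar_ambiguous_base`); in the sequence pipeline ambiguous codons
  are dropped and counted per record instead.
- Out-of-frame CDS lengths are an error by default, or trimmed at the 3′
  end under an explicit policy; trimmed bases are counted.
- Cohort comparisons take an explicit `precision` because published
  frequency tables are rounded: at two decimals the bundled cohort table
  yields ties that full-precision data would not, which is why the
  published 7-of-8 claim for the −1 class is documented as irreproducible
  from the printed table rather than asserted (the printed two-decimal
  data give 3 higher / 1 lower / 4 tied).
- Zero-variance inputs to correlations raise an error rather than
  returning NaN; singleton groups are rejected in the residualized
  association.
- Weighted residue means reject weight vectors that give a residue's
  entire family zero mass.

## Known limitations

- The 21-code roster and origin tags are a reconstruction constrained only
  by the published 11/8/2 split.
- Scale transcriptions are auditable but not guaranteed identical to the
  originally used values; correlation-level results shift in the second
  decimal across transcriptions.
- The GenBank reader handles single-file flat records with
  `join`/`complement` locations only; external references are rejected.
- Species trait compilations (body temperatures, bilateral counts) are
  user-supplied inputs; none are bundled.
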