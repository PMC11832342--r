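---
title: "Detecting pseudouridine in small RNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pseudouridine in small RNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pseudouridine (Ψ), the C5-glycoside isomer of uridine, is the most abundant
internal RNA modification, but in small RNAs (miRNAs, siRNAs, piRNAs,
tRNA fragments) it is hard to map: the classical CMC/reverse-transcription
stop assay truncates an already short molecule into fragments too short to
align. `psifinder` implements the computational readout of three
complementary sequencing assays that work at small RNA scale, together with
a molecule-level simulator so that the entire analysis chain can be
validated as a parameter-recovery problem with known ground truth:

* **Ψ-IP** — immunoprecipitation with an anti-Ψ antibody; modified species
  are *enriched* in the bound fraction relative to the unbound fraction.
* **CMC depletion** — the carbodiimide CMC forms a bulky adduct at Ψ that
  blocks reverse transcriptase under standard conditions, so modified
  molecules drop out of the library; modified species are *depleted* in
  CMC⁺ relative to mock.
* **CMC/Mn²⁺ mutational readout** — reverse transcription in manganese
  buffer reads through the adduct, leaving a 1-nt deletion or a mismatch at
  the Ψ position; modified positions carry an excess of *altered* reads in
  the treated library.

A feature supported by all three readouts forms the high-confidence set.

# The generative model

`simulate_libraries()` samples each library at the molecule level:

1. Per-feature molecule shares are log-normal (`expression_meanlog`,
   `expression_sdlog`; defaults 0 and 1, a realistic dynamic range of
   roughly two orders of magnitude for small RNA loci). Features at most
   35 nt long yield full-length molecules with optional 3′ jitter;
   longer loci (rRNA, TE, genes) yield uniform fragments of 18–30 nt.
2. Each planted site carries a stoichiometry *s* ∈ (0, 1]: every molecule
   covering the site is modified independently with probability *s*.
3. Assay chemistry, per molecule:
   * IP: capture probability 1 − (1 − *e*)^*k* for a molecule carrying *k*
     Ψ (capture efficiency *e* = 0.8) and background 0.05 for unmodified
     molecules; the input pool is partitioned exactly into bound and
     unbound, so molecule counts are conserved.
   * CMC⁺: each Ψ is adducted with probability *a* (default 0.9); any
     adducted molecule is dropped (RT stop, unsequenceable). The expected
     surviving fraction of a single-site species is therefore 1 − *s·a*,
     which the tests verify against Monte-Carlo error.
   * Mn²⁺: an adduct converts to a 1-nt deletion with `p_del`, to a random
     non-cognate base with `p_mis` (defaults 0.3 / 0.3), and reads through
     cleanly otherwise.
4. Uniform per-base sequencing error (default 10⁻³) is applied last.
   Correct bases are written at Q37; miscalled bases at Q10, so
   base-quality-aware consumers can distinguish sequencing noise from
   chemistry deterministically.

Two design points deserve emphasis. First, the treated and mock arms of the
CMC and Mn²⁺ assays are **independent molecule pools** drawn from the same
expression vector, which is what physically dividing one sample into two
aliquots produces. Re-using the identical molecule list for both arms would
make the null contrast degenerate (treated ≡ mock byte for byte), and no
calibration statement about the test would be meaningful. The IP assay, by
contrast, splits a single pool into bound and unbound, because those two
libraries really are complementary fractions of the same material. Second,
RT-stop products under standard RT are dropped entirely rather than emitted
as truncations: truncated small RNA fragments would be too short to map, so
emitting them would only model unusable reads.

Mock and "untreated" arms are computationally indistinguishable, so only
mock is emitted. The order of adapter ligation relative to CMC treatment
does not change any simulated quantity; it is recorded as a metadata flag
(`protocol_order`) only. All randomness flows from one master seed through
named substreams (`substream_seed()`), so any stage can be re-run in
isolation and the whole pipeline is byte-reproducible.

# Preprocessing and alignment

Reads are trimmed (3′ adapter, ≥ 5-nt terminal overlap, ≤ 1 substitution,
optional NextFlex-style random ends), filtered (length bounds; optional
Q20-over-90% rule; reads containing N removed), and collapsed to unique
sequences with per-library counts. Untrimmed reads are discarded: a small
RNA insert is shorter than the read, so a missing adapter indicates a
failed read. Discards are logged by reason and reconcile with input totals.

Alignment is a deliberately small, fully verifiable scanner rather than a
general-purpose aligner: every offset on both strands is examined
(end-to-end, ungapped, ≤ `max_mismatch` ∈ 0–3), and a second mode admits
exactly one 1-nt internal reference deletion — the Mn²⁺ signature. The best
stratum is by total edits; on ties a gapless placement beats a deletion
placement (substitution is the more parsimonious explanation), and
ambiguous deletion placement within a homopolymer is normalized to the
leftmost position so pileups are deterministic. Policies: `all_best`
(report all best-stratum hits), `unique_only` (drop multimappers), and
`single_hit` (one deterministic placement per read, used for metagene
profiles). A hit cap (default 50) flags pathological repeats. The contract
is tested against an exhaustive pure-R Hamming-scan oracle.

# Enrichment testing

Counts are per unique sequence (the sequence, not the locus, is the tested
feature; locus and family assignment happen downstream). Features must
exceed a mean of 10 raw reads per library (strict `>`; a flag gives `≥`).
Normalization is median-of-ratios: per library, the median over
everywhere-nonzero features of count / geometric mean. Factors are reported
raw, without re-centering; note that scaling one library by *c* scales its
factor *ratio* to the others by exactly *c*, while the factor itself scales
by *c*^(1−1/n) because the geometric-mean reference absorbs *c*^(1/n).

Dispersion is a method-of-moments negative-binomial estimate,
α = (s² − μ)/μ² on normalized counts within each condition, averaged over
conditions, then shrunk 50% toward the mean of similarly expressed features
(20 expression bins). The floor (10⁻⁸) is applied **after** shrinkage, and
the trend is computed from un-floored values: flooring each raw value first
keeps only the positive half of the sampling noise and biases the estimate
upward under near-Poisson data, which makes the Wald test visibly
conservative. With the floor applied last, an all-constant matrix still
returns exactly the floor, and null calibration is preserved. With a single
replicate per condition the estimator falls back to a fixed prior (0.1)
with a warning.

The test is a per-feature two-condition Wald test on the log2 ratio of
normalized condition means with pseudocount 0.5; the standard error comes
from the NB variance function μ + αμ², and the statistic is referred to the
standard normal. Technical replicates of a biological replicate are
averaged before testing. p-values are Benjamini–Hochberg adjusted. The
default contrast is two-group (the pairing enters through technical-replicate
averaging); a strict paired design — per-pair log2 ratios tested against
zero — is available with `paired = TRUE`. We default to the two-group form
because it is well defined for unequal replicate numbers and its null
behavior is directly checkable; both forms are exported and tested. No
shrinkage is applied to the fold change itself (the MLE is reported).

Known limitation: with ~3 replicates the moments estimator is noisy, and
under strongly overdispersed data (true α ≳ 0.2) the normal-reference Wald
test does not control tail error the way a full GLM with trended priors
would. Under the package's own simulation null (counts Poisson around
log-normal means) the raw p < 0.05 fraction sits near nominal and BH false
discoveries stay controlled; both properties are asserted in the test
suite.

# Site-level calling

`build_pileup()` accumulates, per reference position: coverage, altered
reads (1-nt deletions at their reference position plus mismatches), and
5′/3′ terminal counts. A mismatch counts as altered only if its base
quality is at least `min_base_quality` (default Q20) — the base-quality
filter of standard readcount tools. Because the simulator writes sequencing
errors at reduced quality, this cleanly separates chemistry from noise;
on real data it plays the same role it plays in any variant-counting
pipeline.

A position is called when:

* treated read support ≥ `min_reads` (default 5),
* the treated/mock ratio of altered fractions ≥ `min_fold` (default 1.5),
* altered treated reads ≥ `min_altered` (default 3),
* mock coverage ≥ `min_mock_cov` (default 5; positions below it are
  "untestable").

The fold change uses a common add-half pseudo-ratio ε = 0.5 / treated
coverage added to both fractions. Two numerical choices matter here. A
*common* ε guarantees that a position with zero altered reads in both arms
has fold exactly 1: if each arm used its own coverage, a mere ≥ 1.5×
coverage imbalance between mock and treated would manufacture a positive
"fold change" at completely clean positions. And the `min_altered` floor is
required because a single spuriously realigned multi-error read at high
coverage yields a fold of about 3 under any additive correction; no
ratio-only rule can keep the empty-truth null at zero calls while
sequencing error is nonzero. Three altered reads is the conventional
variant-support floor; at the edge of the tested regime (coverage 20,
*s·a* = 0.4) the expected altered count is ≈ 4.8, so recovery is
essentially unaffected. `use_pseudo = FALSE` reproduces the plain ratio
(zero-mock positions then give an infinite fold), for users who prefer to
exclude those positions instead.

Per-feature calls take the position with the maximum fold change inside the
feature, with read support counted as treated reads whose 5′ end lies in
the feature — the per-miRNA phrasing of the rule. Calling is monotone in
all thresholds (raising any of them never adds a call), which is tested as
a property.

`rrna_site_validation()` normalizes per-position coverage to total locus
coverage per library, averages log2 paired ratios over replicate pairs, and
reports the mean over a ±2 nt window around each known site (the window is
configurable; ±2 covers placement ambiguity of deletion signatures without
diluting the site signal). Depletion at a genuine site is negative under
the CMC contrast and, in the tests, known sites rank in the lowest decile
of the locus track at ~100× coverage.

`consensus_calls()` classifies features by assay support — IP: adjusted
p < α and log2FC > 0; CMC: adjusted p < α and log2FC < 0; MnCMC: called —
with α = 0.01 by default, and reports Venn class sizes. The intersection of
all three is the high-confidence set.

# Rollups and profiles

* **TE families:** per family × size class (defaults 20–22 and 23–25 nt,
  configurable — size classes are analysis parameters, not constants), the
  mean of member log2 fold changes; a sequence multimapping across families
  contributes once per matched family (a fractional-weight mode divides by
  the number of families). Aggregation is over unique sequences by default;
  the copy-level alternative is reachable by aggregating the annotation
  table first.
* **AGO preference:** per family × size class, the Argonaute-IP library
  with maximum enrichment; exact ties are "ambiguous".
* **Terminal bias:** 5′/3′ base frequencies per group after removing
  structural classes (tRNA/snoRNA/snRNA/rRNA).
* **tRFs:** reads inside tRNA features classified 3′-tRF (ends at the CCA
  end), 5′-tRF (starts at the tRNA start) or internal; flagged for the
  UNUAR motif (U-N-U-A-purine) and for spanning the canonical position-55
  uridine.
* **Metagene profiles:** single-placement alignments, coverage normalized
  per library to total genomic coverage and merged within treatment; flanks
  binned at the window size (default 25 nt), gene bodies rescaled to 60
  bins (a fixed resolution chosen so typical gene lengths map a few
  nucleotides per bin), minus-strand genes reversed, then a centered moving
  average (default width 6 bins, partial at the edges so totals are
  preserved). Flanks running off a contig are truncated with a warning and
  padded so bins stay aligned across genes.

# Problem sizes and runtime

The package's standard study conditions — used by the acceptance checks and
`pipeline_preset("toy")` — are 200 miRNA-sized loci, 30 modified at
stoichiometry 0.5–1, 5×10⁴ molecules per library, three replicate pairs,
capture efficiency 0.8 over background 0.05, adduct probability 0.9,
`p_del = p_mis = 0.3`, sequencing error 10⁻³. At these sizes a full
simulate–preprocess–align–test cycle takes a few seconds on one CPU; the
complete test suite, including twenty null seeds of the mutational
readout, runs in minutes. Site-level checks use 60 loci at ~500× mean
coverage; the rRNA analogue uses a 2-kb locus at ~240×.

# What the simulation does and does not show

The generator reproduces the *chemistry* of the three assays — capture,
adduction, dropout, read-through mutation, sequencing error — with known
per-site stoichiometry, so passing tests demonstrate that the estimators
recover planted parameters under the stated noise model. It deliberately
omits PCR duplication, ligation bias, 2′-O-methylation effects,
cell-sorting artifacts and sequence-specific antibody affinity. Results on
real libraries therefore depend on upstream normalization assumptions in
ways the simulation cannot certify; the per-sequence testing unit and the
median-of-ratios normalization are, however, the field-standard responses
to exactly those biases.
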