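# psifinder

Pseudouridine (Ψ) detection in small RNA sequencing libraries.

Ψ is the most abundant internal RNA modification, but mapping it in small
RNAs (miRNAs, siRNAs, piRNAs, tRNA fragments) is hard: the classical
CMC/RT-stop readout truncates an already short molecule into unmappable
fragments. `psifinder` implements the computational readout of three
complementary assays that do work at small RNA scale, and a molecule-level
simulator with known ground truth so the whole chain is testable as a
parameter-recovery problem:

| Assay | Signal | Statistic |
|---|---|---|
| Ψ-IP | modified species enriched in bound vs unbound | NB Wald test, log2FC > 0 |
| CMC depletion | adducted molecules drop out of CMC⁺ vs mock | NB Wald test, log2FC < 0 |
| CMC/Mn²⁺ readout | 1-nt deletions / mismatches at Ψ positions | altered-ratio fold change |

For the enrichment assays, counts of unique collapsed sequences are
normalized by median-of-ratios size factors, per-feature NB dispersions are
estimated by method of moments with trend shrinkage, and each contrast
(IP/unbound, CMC⁺/mock) is tested with a Wald statistic
z = log2FC / SE referred to the standard normal, with Benjamini–Hochberg
adjustment. For the mutational readout, a position is called when it has at
least 5 treated reads, at least 3 altered treated reads, and

```
(altered_ratio_treated + eps) / (altered_ratio_mock + eps) >= 1.5,
eps = 0.5 / treated coverage
```

Features significant in all three assays (adjusted p < 0.01 for IP and
CMC) form the high-confidence set.

## Worked example

Simulate a toy study (80 miRNA-sized loci, 12 of them modified at
stoichiometry 0.6–1, three replicate pairs per assay), run every stage, and
compare the calls with the planted truth:

```r
library(psifinder)

cfg <- list(preset = "toy", master_seed = 42,
            reference = list(n_mirna = 80L, n_te_families = 0L,
                             rrna_len = 0L, n_trna = 0L),
            truth = list(n_modified = 12L, stoich_range = c(0.6, 1)),
            sim = list(molecules_per_library = 10000L, replicates = 3L))
res <- run_pipeline(cfg, "toy_run")
str(res$report$recovery)
#> List of 8
#>  $ ip_sensitivity             : num 0.75
#>  $ ip_fdr                     : num 0
#>  $ cmc_sensitivity            : num 0.833
#>  $ cmc_fdr                    : num 0
#>  $ mn_sensitivity             : num 0.917
#>  $ mn_fdr                     : num 0
#>  $ high_confidence_sensitivity: num 0.75
#>  $ high_confidence_fdr        : num 0
```

At these modest library sizes each assay recovers 75–92% of the planted
features with no false discoveries; the consensus of all three (at
adjusted p < 0.01) recovers 75%. The strongest CMC depletions are the
modified sequences:

```r
cmc <- res$enrichment$cmc
head(cmc[order(cmc$pvalue),
         c("feature_id", "baseMean", "log2FC", "stat", "padj")], 4)
#>               feature_id  baseMean    log2FC       stat         padj
#> 41 TATATGTTAATTCGTATGGGG 217.02431 -2.124709 -20.725101 2.098088e-93
#> 79 TGGCTGTGAAACCCCAAAAGG 124.17619 -1.157263 -10.142897 1.817496e-22
#> 1  AAGAAGGTTTCTGTCACAGGT  54.90923 -1.871976  -9.712601 9.059308e-21
#> 62 TCTGCCCTGACGTCCCTCCGT  38.90924 -2.172205  -8.925366 1.132784e-17
```

A negative `log2FC` means the sequence was depleted after CMC treatment —
the expected direction for a pseudouridylated species. The Mn²⁺ readout
pins sites to single nucleotides:

```r
subset(res$mn_feature_calls, called)[1:3, ]
#>    feature_id  pos fold_change called
#> 2      mir002  173    133.0000   TRUE
#> 9      mir009  753     39.0000   TRUE
#> 16     mir016 1332    125.7581   TRUE
```

`pos` is the 0-based reference coordinate of the best altered position
inside each feature; a fold change of 133 means the altered-read fraction
at that position is two orders of magnitude above mock background.

The run directory contains all tables (`ip_results.tsv`,
`cmc_results.tsv`, `mn_site_calls.tsv`, `consensus.tsv`), the reference
(FASTA/BED), the ground truth, a YAML manifest and a JSON report.
Re-running the same config reproduces every file byte for byte.

An optional command-line wrapper for the pipeline lives at
`inst/scripts/psifinder` (`psifinder run --config cfg.yaml --outdir DIR`).

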