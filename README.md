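# tssmeth

Integrative epigenomics in R: where around the transcription start site
(TSS) is DNA methylation coupled to gene expression, and does that
coupling shift position between tumor and normal cohorts?

`tssmeth` is for computational biologists analyzing paired DNA
methylation and expression cohorts — MBD-seq/MACS-style peak calls or
Infinium-style beta values alongside RSEM-style normalized expression —
who want a tested, reproducible implementation of the TSS-centric
correlation-mapping analysis rather than a pile of one-off scripts.

## What it computes

Methylation is reduced to a binary call per 100-bp genomic segment per
sample (presence/absence of a peak). For each gene, the 20 non-overlapping
500-bp windows tiling TSS ± 5 kb get a score in 0–5 (sum of their five
segment binaries, strand-aware). For each cohort arm, every (gene, window)
pair is tested by Spearman rank correlation between window score and
expression across samples, with Benjamini–Hochberg FDR control. The
TSS-relative midpoints of significant windows are profiled by a Gaussian
KDE *f̂* normalized to integrate to 1 over [−5000, 5000], and the headline
statistic is the AUC ratio

    R = ∫[−500,500] f̂_tumor dx  /  ∫[−500,500] f̂_normal dx

tested one-sided against a permutation null (expression shuffled against
methylation within each arm, the full chain recomputed per permutation,
add-one p-value). Around this core the package provides expression-quartile
methylation and ChIP meta-profiles with randomized gene-list background
bands, Ward/Euclidean methylation-subtype clustering on the most strongly
anticorrelated genes, Fisher-exact mutation–subtype association with
protein-domain effect classification, an array-mode probe-density-weighted
methylation summary, and a synthetic cohort generator that plants all of
the above with known ground truth.

## Worked example

Simulate a cohort under the package's default study conditions — 300
genes, 40 tumor + 40 normal samples, methylation–expression coupling
centered 1 kb upstream of the TSS in normal and directly at the TSS in
tumor (Spearman ρ ≈ 0.5 at the planted window) — then test for the
tumorward shift:

```r
library(tssmeth)

co <- simulate_cohort(cohort_config(seed = 11))
w  <- window_scores(co$segments, co$genes, co$chrom_sizes)
st <- tss_shift_test(w, co$expr, co$samples, n_perm = 200, seed = 11)
st
#> TSS shift permutation test (AUC ratio, tumor/normal)
#>   region: [-500, 500] bp; selection: p < 0.05 (any correlation, all genes)
#>   AUC tumor = 0.2405, AUC normal = 0.1412
#>   observed ratio = 1.703, p = 0.004975 (200 permutations, 0 degenerate)
```

Tumor density mass within TSS ± 500 bp is 1.7-fold the normal arm's and no
permutation reached the observed ratio (p = 1/201): the planted shift onto
the TSS is recovered. `autoplot(st)` draws the null-ratio histogram with
the observed ratio marked; `tidy(st)` and `glance(st)` return the
permutation draws and the one-row summary. `run_tss_pipeline()` chains all
stages (scoring → correlation maps → densities → shift test → gene
selection → subtypes → quartile profiles) and `write_pipeline()`
serializes every output as TSV/JSON.

Against real data, replace the simulated pieces with
`read_gene_bed()`, `read_cgi_bed()`, `binarize_segments()` over per-sample
peak BEDs, your expression matrix, and a sample manifest — or
`probe_weighted_methylation()` for array cohorts.

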