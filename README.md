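# temdyn

Transposable elements (TEs) are silenced in plants by RNA-directed DNA
methylation (RdDM): 24-nt small interfering RNAs guide de novo cytosine
methylation, most visibly in the CHH context. During Arabidopsis
embryogenesis two TE populations behave very differently — euchromatic TEs
whose 24-nt siRNAs rise sharply at embryo maturation and stay high in
post-embryonic tissues, and long heterochromatic TEs that produce an
early-embryonic siRNA burst which collapses at maturity, apparently
because chromatin compaction later restricts Pol IV access.

`temdyn` implements the computational side of this analysis as a tested R
package running entirely on synthetic data with known ground truth:

* a **synthetic-data generator**: a miniature genome with planted TE
  classes, stage-resolved small RNA libraries, replicate-pooled
  methylomes with planted DMRs, and nucleosome-occupancy tracks with
  three archetypes;
* **siRNA quantification**: "rich-get-richer" fractional reassignment of
  multi-mapping reads (candidate weight ∝ local assigned coverage,
  iterated to a fixed point with exact mass conservation), RPM
  normalization against all genome-matching reads, per-TE sums by
  alignment start, and deepTools-style scale-regions matrices
  (5 bp bins, 4 kb body, 2 kb flanks → 1600 columns);
* **temporal TE classification**: a hand-written EM for Gaussian mixtures
  with the VEV covariance family Σ_k = λ_k·D_k·A·D_kᵀ (variable volume,
  shared det-1 shape, variable orientation), BIC selection over
  G = 2,4,…,20, a 2-RPM detection rule, and template-correlation
  assignment of clusters to class A / class B / depleted, plus PCA,
  complete-linkage sample clustering and the ≤723 / 724–2114 / >2114 bp
  length partition;
* **methylome analysis**: weighted methylation (Σmc/Σcov), trinucleotide
  context classification (CG/CHG/CHH and the CWA subcontext),
  conversion-rate estimation, differentially methylated sites by a
  root-mean-square goodness-of-fit test with a Monte-Carlo null and BH
  FDR ≤ 0.01, 100-bp DMS chaining, and the ≥4-DMS / ≥20-percentage-point
  DMR filters with pairwise merging;
* **chromatin association**: restarted k-means on nucleosome profile
  matrices (group 1 = densest), length-normalized
  heterochromatic/euchromatic siRNA enrichment, TE-family O/E enrichment
  with Fisher's exact test, percentile overlays, exact small-sample
  Mann-Whitney tests, z-score series and Pearson correlation tables.

## Worked example

The default configuration simulates 300 TEs (120 class A, 120 class B, 60
siRNA-depleted) on two 500-kb chromosomes, with ten samples × three
replicates of 100,000 reads. The full run below takes a few minutes on one
core.

```r
library(temdyn)

cfg    <- sim_config(seed = 11)
genome <- generate_genome(cfg)

# simulate + reassign + normalize + quantify all 30 libraries,
# then select the mixture size by BIC and label the classes
quant <- quantify_experiment(genome)
res   <- classify_tes(quant, seed = 7)
res$model$G
#> [1] 8
table(truth = genome$truth$te_class, called = res$labels$class)
#>           called
#> truth        A   B depleted
#>   A        120   0        0
#>   B          0 120        0
#>   depleted  17   1       42

# DMR calling between preglobular and mature green methylomes
dmrs <- call_dmrs(list(pg = simulate_methylome(genome, "pg"),
                       mg = simulate_methylome(genome, "mg")), seed = 5)
dmr_recovery_stats(dmrs, genome$truth$dmr_truth)[c("precision", "recall")]
#> $precision
#> [1] 1
#>
#> $recall
#> [1] 1
```

Every true class-A and class-B TE is recovered (the BIC-selected
8-component mixture splits them into sub-clusters that the template rule
re-merges); a handful of truly depleted TEs catch stray reads and cross
the 2-RPM line, a granularity effect of desk-scale libraries (one read =
10 RPM). All 40 planted DMRs are recovered with no false calls.

## Layout

```
R/                  implementation
tests/testthat/     unit, property and end-to-end recovery tests
scripts/acceptance.R
vignettes/temdyn-methods.Rmd   models, parameters, design choices
```
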