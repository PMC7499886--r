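---
title: "Models and methods behind temdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind temdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

temdyn implements, on fully synthetic data with known ground truth, the
computational pipeline used to study how chromatin state shapes 24-nt
siRNA production and RNA-directed DNA methylation (RdDM) over transposable
elements (TEs) across plant embryogenesis: quantification of 24-nt siRNAs
with fractional reassignment of multi-mapping reads, model-based temporal
classification of TEs, weighted-methylation and DMR calling from
per-cytosine count tables, and the statistics relating siRNA output to
chromatin features. Every downstream stage is testable against the
generator's ground truth without any external download.

# The synthetic study system

`sim_config()` fixes the study conditions. The defaults describe a
miniature diploid-agnostic genome of two 500-kb chromosomes carrying three
latent TE populations (120 class-A, 120 class-B, 60 siRNA-depleted TEs),
ten samples (floral bud; preglobular through mature green embryos; leaf)
with three replicates of 100,000 genome-matching reads each. These sizes
were chosen so the whole pipeline — including the mixture-model grid and
genome-wide DMS testing — runs in a few minutes on one core; they are the
package's default problem sizes, stated here once, and all tests and the
acceptance script use them or documented reductions of them.

## TE placement

Class-B (heterochromatic) TEs are drawn from a longer log-normal length
distribution (median 1.8 kb vs 0.5 kb) and placed with 85% probability
inside a pericentromeric window of ±75 kb around each chromosome midpoint,
reproducing the heterochromatic/euchromatic length and position asymmetry
that the bipartite classification rests on. Placement is sequential
rejection sampling of non-overlapping intervals; an impossible packing is
an explicit error, not a silent truncation.

## Stage templates

No numeric siRNA profile is printed anywhere for the real classes, so the
generator's stage templates (`sirna_templates()`) are piecewise
idealizations of the described dynamics, in units of expected reads per kb
of TE per library:

* class A — low at preglobular, moderate through mid-embryogenesis, a
  sharp rise at the mature green stage, high in leaves and floral buds;
* class B — already high at preglobular, peaking in mid-embryogenesis
  (early torpedo), collapsing at maturity and in post-embryonic tissues;
* depleted — 0.05 reads/kb throughout, which keeps expected levels far
  below the 2-RPM detection line.

Amplitudes are generator conventions, not estimates. Per-TE expected
counts scale with TE length; realized counts are negative binomial with
dispersion 0.2 (`size = 1/0.2`), the simplest overdispersed count model.
Read lengths are 18–30 nt with a 24-nt mode for TE reads, and 24-nt reads
start with adenosine with elevated probability, mirroring the first-base
bias of genuine Pol IV products. Each library is filled to exactly
`reads_per_library` with background reads placed outside TEs, so RPM
denominators are exact by construction.

At this scale one read corresponds to 10 RPM, so the 2-RPM detection rule
effectively asks "was any read seen"; occasional stray reads can push a
truly depleted TE over the line in a single sample. This is a granularity
artifact of desk-scale libraries; it does not affect class A/B recovery,
which is scored among truly non-depleted TEs.

## Multi-mapping families

A configured fraction (30%) of TE reads report `multimap_family_size`
candidate loci. Decoy loci are drawn from TEs of the same family *and*
class — the simulated analogue of a repeat family whose copies share
near-identical flanks. The true origin of every read is recorded, which is
what makes reassignment testable.

## Methylomes

`simulate_methylome()` emits a replicate-pooled per-stage methylome:
binomial counts at every cytosine of both strands, with Poisson coverage
at `n_replicates * coverage_per_cytosine` (pooling replicates before DMS
testing is exactly what the DMR-calling procedure does with real
replicates, and per-site power at genome-wide FDR control requires the
pooled depth). Baselines are 24% CG / 9% CHG / 2% CHH. Planted DMR
intervals (40 intervals of 200 bp inside non-depleted TEs) ramp their CHH
level from the baseline at preglobular up to baseline + `dmr_effect`
(default +40 percentage points) at mature green, dropping again in leaves
and floral buds. A bisulfite non-conversion rate (0.5%) adds false
methylation everywhere, and an unmethylated `ctrl` contig plays the role
of the chloroplast/Lambda conversion control.

What the generator does *not* model: sequence-specific methylation
(contexts come from a random sequence), extra-binomial dispersion between
replicates, m-bias, or TE-body versus flank methylation gradients. Passing
recovery tests therefore demonstrates correctness of the pipeline's
statistics and bookkeeping, not robustness to every property of real
bisulfite data.

## Nucleosome tracks

Long (>2114 bp) class-B TEs receive one of three occupancy archetypes with
probabilities 0.567/0.331/0.102 (the group proportions observed in the
real k-means analysis): (1) high occupancy throughout, (2) low edges/high
body, (3) low throughout. The per-base track adds smoothed Gaussian noise;
`noise_sd = 0` gives the noiseless archetypes used for the exactness
check.

# Quantification

## Rich-get-richer reassignment

`reassign_multimappers()` computes a fixed point of preferential
assignment. Each read's candidate weight is proportional to the total
currently assigned read mass (unique reads plus the fractional mass of
other multimappers) in a window spanning the candidate footprint ±25 bp,
renormalized per read each iteration (tolerance 1e-6, at most 100
iterations). Unique reads anchor the solution; total mass is conserved
exactly at every step. If all of a read's candidates see zero coverage its
weights fall back to uniform. The published pipeline cites an external
script for this step without restating its update rule; the fixed-point
rule here is therefore this package's own declared operationalization,
validated against a hand-iterated oracle (the 9:1 unique-coverage toy
converges to weights 0.9/0.1).

## RPM and per-TE sums

Normalization divides by all genome-matching reads of any length (18–30
nt). A read contributes its normalized mass at its alignment start
position; a TE's quantification is the sum of masses starting inside its
half-open interval, which attributes each read to exactly one position and
avoids double counting at TE borders (a read starting inside two
overlapping TEs counts for both, matching interval-sum semantics). The
24-nt class uses lengths (24,24); precursor-length reads use (25,30).

## Scale-regions matrices

`metaplot_matrix()` reproduces the deepTools scale-regions geometry: 5-bp
bins, 4000-bp rescaled body, 2000-bp flanks — 400 + 800 + 400 = 1600
columns. Bodies shorter than the bin count are stretched by midpoint
sampling rather than erroring; minus-strand rows are reversed so all
profiles read 5'→3'; flank positions beyond a chromosome end contribute
zero.

# Temporal classification

## The VEV mixture

TE × sample matrices of replicate-mean 24-nt RPM are clustered with a
Gaussian mixture whose covariances follow the VEV parameterization
Σ_k = λ_k D_k A D_kᵀ — variable volume λ_k, a shared diagonal shape A with
det(A) = 1, variable orientation D_k. The M-step eigendecomposes each
component scatter matrix and alternates closed-form updates of (λ_k, A)
until convergence; the shared-shape pairing is by eigenvalue rank.
Numerical choices: k-means++ initialization with 10 seeded restarts (best
final log-likelihood kept), eigenvalue floor at 1e-8 times the mean column
variance, and re-seeding of components whose responsibility mass starves
(re-seeds are logged; log-likelihood monotonicity holds between re-seeds).
Model size is chosen by BIC (2·loglik − m·log n, larger is better) over
G = 2, 4, …, 20, taking the smallest G attaining the maximum. The free
parameter count is m = (G−1) + Gd + G + (d−1) + Gd(d−1)/2. The fit agrees
with the independent mclust implementation to numerical precision on test
data; mclust is used only as a cross-check, never as the engine.

## From clusters to classes

How the original eight mixture clusters were merged into two classes was
a manual step in the source analysis; this package makes it explicit.
TEs whose replicate-mean RPM never reaches 2 in any sample are labeled
`depleted` ("at least 2 RPM" is evaluated as the maximum across samples of
the replicate mean — the printed rule does not say which, and this reading
is the most permissive one that still excludes never-detected TEs). Every
remaining cluster is labeled A or B by which of two fixed stage templates
its mean profile (over detected members) correlates with more strongly;
a cluster whose correlations differ by less than 1e-6 is reported
`unclassified` rather than silently assigned. Members inherit their
cluster's label. Length classes use the printed cutoffs: short ≤ 723 bp,
medium 724–2114 bp, long > 2114 bp.

# Methylome analysis

Weighted methylation is Σmc/Σcov over qualifying sites — coverage-weighted,
never a mean of ratios, hence invariant to pooling or splitting count
tables. Contexts derive from the strand-oriented trinucleotide (CG; CHG;
CHH with CWA = C-(A|T)-A vs non-CWA), with minus-strand cytosines read
from their own strand. Cytosine tables are 1-based (allc convention); all
interval output is 0-based half-open (BED convention).

## DMS testing

Each CHH site covered by ≥4 reads in every sample (≥3 for preglobular) is
tested for homogeneity across samples with a root-mean-square
goodness-of-fit statistic on the 2 × S count table,
sqrt(mean(((O−E)/N)²)), with expectations from the pooled proportion. The
null is Monte-Carlo: coverages fixed, methylated counts resampled
binomially at the pooled proportion, p = (b+1)/(n+1). Sampling is batched
with two early stops: a site whose 99% CI for p lies above the FDR
boundary stops (it can never be called, so the decision is unaffected),
and a site with enough exceedances stops because its p is already well
estimated. Sites that remain unresolved at the 3000-resample baseline
escalate up to 40,000 resamples — necessary because with ~2.5 × 10^5
tested sites the Benjamini–Hochberg threshold sits far below 1/3001, and a
p-value stuck at its Monte-Carlo floor could never be ranked finely
enough. q-values are BH; DMSs are sites with q ≤ 0.01. Null p-values are
conservative (super-uniform) at small counts, which the test suite checks
by simulation.

## DMRs

DMSs within 100 bp chain transitively into regions; regions need ≥4 DMSs
and a maximum pairwise weighted-methylation difference ≥20 percentage
points between the compared samples (read as percentage points of weighted
mCHH, comparing the samples of the pairwise test). Pairwise DMR sets across
the five embryonic stages (10 combinations) merge by interval union with
bookended merging. Recovery of the 40 planted DMRs is scored by interval
overlap: precision and recall are both 1.0 at the default effect and depth
under seed 11, and the acceptance script recomputes them from scratch for
any requested seed. The acceptance run uses the maximum-contrast
preglobular-vs-mature-green comparison; the 10-way enumeration and merge
are exercised on small inputs where exhaustive checking is possible.

# Chromatin association

Nucleosome profile matrices over long heterochromatic TEs are clustered
with restarted k-means (best of 10 starts by within-cluster sum of
squares); groups are renumbered by descending mean occupancy so group 1 is
always the dense one. The heterochromatic/euchromatic enrichment is the
ratio of per-bp siRNA densities (ΣRPM/Σbp over class B divided by class
A), which cancels TE length and read-length-fraction conventions and is
invariant to uniform RPM rescaling. Family enrichment is log2 of the
observed over expected fraction of DMR-overlapping TEs per family, with a
two-sided Fisher's exact test; a family with zero overlap reports an NA
sentinel rather than −Inf. The Mann-Whitney U test enumerates all
arrangements exactly for n+m ≤ 12 (valid under ties) and otherwise uses
the tie-corrected normal approximation; group comparisons of
replicate-level enrichment values use Welch's t (the equal-variance
assumption is never made). Percentile overlays rank TEs by mutant siRNA
level into equal-count bins (sizes differ by ≤1), breaking ties by stable
TE id.

# Known limitations

* Amplitude-level claims (absolute RPM, absolute methylation differences)
  are generator conventions; only shapes, rankings, and recovery rates are
  meaningful.
* The 2-RPM detection rule is grainy at 10^5-read libraries (one read =
  10 RPM); depleted-TE detection counts at this scale overestimate what
  deeper libraries would show.
* The rich-get-richer window/update rule is a declared stand-in for an
  uncited external implementation; its fixed point is validated against
  its own oracle, not against that script.
* Monte-Carlo DMS p-values are floor-limited; the escalation ceiling
  (40,000) bounds how small a q-value can get and therefore how many tests
  the FDR step can support at a given number of truly changed sites.
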