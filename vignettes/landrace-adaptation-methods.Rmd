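---
title: "Methods: environmental GWAS on structured landrace panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environmental GWAS on structured landrace panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Crop landraces are farmer-developed varieties shaped by generations of
selection for local conditions. A panel of landraces genotyped by
reduced-representation sequencing, with passport records of where each
accession was collected, supports two complementary association designs:
a conventional GWAS on phenotypes measured in common gardens (here,
flowering time at two locations), and a "reverse ecology" GWAS that
treats bioclimatic variables of the collection sites — temperature
annual range (TAR), annual precipitation (AP) and the maximum day length
between sowing and harvest (MDL) — as quantitative traits. Loci that
respond to both designs, and that show strong frequency shifts between
wild relatives and landraces or among landrace subpopulations, are
candidates for adaptive variation usable in breeding.

`ecogwas` implements that full analysis path: genotype calling from
per-site allele read depths, the quality-filter cascade, population
structure, differentiation/diversity/LD statistics, photoperiod
modelling, association scanning, effect and variance-explained
quantification, and selection-signal classification — together with a
seeded synthetic-panel generator that reproduces the statistical
structure the analyses assume, so every stage is testable end to end
without any external download.

## Genotype calling from allele depths

Reduced-representation data yield shallow, variable coverage (the
emulated panel averages 13 reads per site and sample), so the caller is
rule-based rather than likelihood-based. Per cell, with `a` reads of one
allele, `b` of the other and a total `t` including other bases:

* homozygous for the allele with more reads if that allele has ≥ 2 reads
  and ≥ 90% of `t`;
* heterozygous if both alleles have ≥ 1 read, each ≥ 20% of `t`, and the
  two together have ≥ 5 reads making up ≥ 90% of `t`;
* missing otherwise.

The homozygous rule is evaluated first; a read-count tie can only
satisfy the heterozygous rule. The two rules are mutually exclusive for
any total ≥ 2, a fact the test suite asserts by exhaustive enumeration
of all read-count triples up to 20. The percentage denominators use the
full cell total (including other-base reads): that is the literal
reading of "total reads" and the conservative choice at noisy cells.

The filter cascade is fixed: site discovery (pooled bi-allelic fraction
≥ 80% over cells with ≥ 5 reads) → calling → site filters
(MAF ≥ 1% on called alleles, heterozygosity ≤ 20%, missingness ≤ 70%)
→ sample filter (missingness < 80%) → imputation → post-imputation
filter (MAF/het re-applied plus ≥ 20 homozygous-minor carriers).
MAF always uses called alleles only, since a missing genotype
contributes no allele observations. All filters are idempotent.

Imputation offers a marginal mode fill and a local-window k-nearest
neighbour fill (allele-sharing distance over a window of flanking
sites). The kNN variant exploits LD and is measurably more accurate on
masked-entry experiments; neither attempts to reproduce a full
haplotype-cluster model, because downstream matrix statistics need
completeness, not genotype posteriors.

## The synthetic panel

The generator's defaults are the study conditions of the emulated
panel: four groups (wild outgroup plus NR/HR/SR landrace
subpopulations with 97/385/346/1007 accessions), group latitude bands
spanning 18.2–51.4°N, pairwise differentiation targets 0.077 (NR–HR),
0.136 (NR–SR), 0.164 (HR–SR) and 0.15 against the wild group, mean
depth 13, flowering-time heritability 0.704 with 20 causal loci, and a
between-location phenotype correlation near 0.9.

**Differentiation.** Per site, an ancestral frequency `p` is uniform on
(0.05, 0.95) and each group's frequency is Balding–Nichols,
`Beta(p(1−F)/F, (1−p)(1−F)/F)`. Because the expected pairwise
Weir–Cockerham Fst between groups `i` and `j` is `(F_i + F_j)/2`,
group-level `F` values are solved from the pairwise targets by least
squares; an infeasible target set (negative or ≥ 1 solution) is an
error naming the offending pairs.

**Linkage disequilibrium.** Haplotypes are generated by thresholding a
latent Gaussian AR(1) along each chromosome, with latent correlation
`exp(−d/δ)` between adjacent sites at distance `d` (`δ =
ld_copy_decay_bp`, default 170 kb; the wild group uses 21% of that,
mirroring the faster decay of wild panels). We chose this
marginal-preserving construction over a literal "copy the previous
allele with probability `exp(−d/δ)`" chain deliberately: allele copying
blends adjacent sites' group frequencies, which shrinks realized
between-group variance by a factor `(1−c)/(1+c)` at copy rate `c` and
silently deflates Fst below target. Thresholding a copula leaves every
site's marginal exactly Balding–Nichols — the Fst calibration is exact
by construction — while genotype r² still decays monotonically with
distance.

**Inbreeding.** Landraces of a selfing crop are nearly homozygous, and
the calling cascade's heterozygosity filter (≤ 20% per site) only makes
sense against that background. The generator therefore makes a
configurable fraction of accessions fully autozygous (both haplotypes
identical; default 0.95), which yields median site heterozygosity
around 1–2% — realistic for selfing panels — while leaving
Balding–Nichols frequencies, and hence the Fst calibration, untouched
(the Weir–Cockerham estimator's heterozygosity terms absorb the
departure from Hardy–Weinberg, which the tests verify empirically).

**Phenotypes.** Flowering time at each location is
`intercept + location offset + Σ effect × dosage + residual`, with the
genetic value shared across locations (no G×E, consistent with the
small G×E reported for soya bean flowering). Residual variance is set
so the additive heritability equals `h2_target`. Residuals at the two
locations are correlated `resid_cor` (default 0.7), representing
shared non-genetic plasticity; the expected between-location phenotype
correlation is then `h² + (1 − h²)·resid_cor ≈ 0.9` at the default
heritability, matching the panel this generator emulates.

**Read depths.** Depth per cell is Poisson(13) with a configurable
zero-coverage fraction; reads are allocated binomially with a per-read
error toward the other allele only (no third-allele noise).

All draws flow from one master seed via per-operation sub-streams
(seeds derived from the operation name), so rerunning one stage never
perturbs another, and identical configurations are bit-reproducible.

What the generator does *not* emulate: coalescent genealogies,
recombination-map heterogeneity, allele-frequency clines within groups,
raster-derived climate surfaces (climate is a latitude trend plus
Gaussian noise), or sequence-level artefacts (no FASTQ). Tests passing
on this generator therefore establish the statistical machinery, not
robustness to every pathology of real GBS data.

## Population structure and differentiation

The relationship matrix standardizes each site's dosages by `2p` and
`sqrt(2p(1−p))` and averages the cross-product over polymorphic sites;
PCA is its eigendecomposition with coordinates scaled by the root
eigenvalue and a fixed sign convention (largest-magnitude loading
positive) for reproducibility. Subpopulation assignment is k-means on
the top components (20 restarts, fixed seed) with inverse-distance
membership proportions; a sample is labelled `MIXED` when its top
proportion falls below 0.55. This deliberately replaces model-based
admixture inference: downstream stages consume only hard labels plus an
admixed class, and a full MCMC treatment is out of proportion at desk
scale. Trees come from classic neighbour joining on allele-sharing
distances, with negative branch lengths clamped to zero and the deficit
moved to the sister branch so path lengths are preserved.

Weir–Cockerham Fst is the 1984 variance-components estimator with the
heterozygosity terms, reported per SNP, as 30-kb window means, and
genome-wide as the ratio of summed components (the ratio-of-sums form is
the standard way to combine loci without weighting artefacts). Sites
need two called individuals per group to contribute. Watterson's θw is
`S/(a_{n−1} L)` per 1-Mb window — a per-bp quantity comparable across
windows — plus the genome mean and central 95% range. Pst uses one-way
ANOVA components with the `(c/h²)σ²B / ((c/h²)σ²B + 2σ²W)` scaling;
`c = h² = 1` by default since no scaling was printed for the panel we
mirror, and both are exposed. Its bootstrap resamples individuals
within groups (1000 draws, percentile 95% interval).

LD is composite genotype r² (squared dosage correlation) — the correct
choice for unphased calls — restricted to intra-chromosome pairs within
1 Mb. The decay profile averages r² in 1-kb bins; the reported decay
distance is where the profile halves relative to its maximum observed
value. Raw first crossings are noisy, so the profile is isotonically
smoothed (monotone non-increasing) before locating the smallest bin
midpoint at or below half-maximum; the smoothing flag is recorded, and
a flat profile reports "not reached" rather than a number. TAS LD
blocks are bounded by the farthest context SNP within ±1 Mb at
r² ≥ 0.8 on each side, collapsing to the focal position on empty sides.

## Association scanning

The baseline scan is single-marker least squares with covariates
(default: top three principal components), computed by residualizing
trait and dosages on the covariate space once and using the exact
residual degrees of freedom — identical to per-SNP `lm()` fits at a
fraction of the cost.

The iterative scan alternates a fixed-effect model (current pseudo-QTNs
as covariates) with a random-effect model used only for model
selection: candidate pseudo-QTNs are the best SNP per physical bin
(bins swept over 100 kb/500 kb/1 Mb), ranked by p, pruned at mutual
r² ≥ 0.7, capped at 20, and the accepted set is the candidate prefix
maximizing the restricted likelihood when kinship is built from the
pseudo-QTN dosages alone (computed through a low-rank Woodbury
identity, so each evaluation costs `O(n·q)` rather than `O(n³)`).
Pseudo-QTNs are never tested against themselves; they report the
p-value from the iteration in which they were selected. One guard is
ours: candidates must first pass a nomination threshold (default
`0.01/m`). Adding a variance component can only improve the restricted
likelihood, so an ungated candidate pool would accrete markers even for
a heritability-zero trait; the gate keeps null scans empty, and the
test suite verifies both the null behaviour and family-wise error
within twice nominal at the Bonferroni threshold. Ties are broken by
genome order; the scan has no internal randomness.

Significance uses `alpha/n_tests` with the one-significant-figure
convention reported alongside (0.01/99 085 ≈ 1e-7); a lower-density
panel convention of 1e-6 is a parameter away. QQ diagnostics report
`λ_GC` as the median observed χ² quantile over 0.4549.

## Quantification and selection signals

Per-TAS variance explained follows the full/reduced scheme: `R²` of the
joint linear model of all TASs minus `R²` with that TAS removed; the
joint PVE is the full-model `R²`. These are ordinary least-squares
quantities by design. Heritability is GRM-REML for a single random
effect: eigendecomposition of the relationship matrix followed by
one-dimensional optimization of the restricted likelihood over the
variance ratio, with boundary fits flagged and a warning for degenerate
(near-duplicate) kinship. Allele effects at a TAS are homozygote
contrasts (Welch t; heterozygotes excluded, matching the two-homozygote
design of the emulated study); the "early" allele is the homozygote
class with the smaller mean flowering time in the discovery location,
stored explicitly so reports are reproducible. Early-allele stacking
counts early homozygotes per sample (heterozygotes 0.5 by default).

Selection classification is a two-axis flag. Domestication: wild-vs-
landrace per-SNP Fst above the genome-wide 0.95 quantile *and* an
allele-frequency change of at least 0.1. Diversification: any pairwise
subpopulation Fst above that pair's genome-wide 0.95 quantile, with
groups where the minor allele is rare (MAF < 0.05) listed as carrying
subpopulation-constrained variation. The numeric criteria are explicit
stand-ins — the emulated study printed no cutoffs — so both are
configurable and echoed in the report; under neutral simulations the
flag rate calibrates to one minus the quantile, which the tests check.

## Photoperiod model

Day length uses the CBM approximation: revolution angle
`θ = 0.2163108 + 2 atan(0.9671396 tan(0.00860(J − 186)))`, declination
`δ = asin(0.39795 cos θ)`, and
`D = 24 − (24/π) acos[(sin(pπ/180) + sin(Lπ/180) sin δ)/(cos(Lπ/180) cos δ)]`
with the day-length coefficient `p = 0.8333°` (apparent sunrise/sunset)
by default. The arccos argument is clamped to [−1, 1] with clamp events
counted — relevant only poleward of the polar circles. The calendar is
365 days with no leap handling; MDL maximizes `D` over the sowing–
harvest window, wrapping past day 365 for autumn-sown material. At the
panel's latitude extremes this model reproduces the printed photoperiod
range (annual maximum 16.6 h at 51.4°N).

## Numerical choices and problem sizes

Tolerances in the oracle tests are 1e-10 against naive second
implementations of Fst, r², θw and the relationship matrix, and 1e-8
against per-SNP `lm()`. The REML ratio is optimized on
`log λ ∈ [−12, 12]`; hitting that boundary flags non-convergence.
Mode-imputation ties break toward the smaller genotype code; candidate
pseudo-QTN ties break by genome order.

Simulation-backed checks run at sizes chosen to keep the full suite
under a minute on one core while leaving estimator noise well inside
the asserted tolerances: differentiation recovery at 2 000–3 000 SNPs
with 150–300 samples per group, heritability recovery at 400–1 000
samples and 1 500–5 000 SNPs (3–20 replicates), null calibration of
the iterative scan at 100–150 replicates of 1 000 SNPs, and the LD
half-decay oracle at 150 000–200 000 synthetic pairs. The acceptance
script uses the larger end of those ranges.

## Known limitations

The admixture model behind `MIXED` labels is geometric, not
probabilistic; membership proportions are inverse-distance heuristics.
The iterative scan is a faithful but simplified relative of its
published namesake (fixed bin sweep, single pruning pass, REML prefix
selection) and inherits the usual caveat that pseudo-QTN p-values are
conditional on the selection path. Pst inference assumes balanced-ish
one-way designs; strongly unbalanced groups widen its bootstrap
interval. The generator's LD is first-order Markov on the latent scale,
so long-range haplotype structure (e.g. inversions) is absent. And the
selection-signal cutoffs, while calibrated under neutrality, are
empirical quantile rules, not likelihood-based sweep tests.
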