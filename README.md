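# ecogwas

Environmental and phenotypic GWAS for structured crop landrace panels.

Landraces — farmer-developed varieties predating modern breeding — carry
locally adaptive alleles that modern cultivars have lost. Given a panel
genotyped by reduced-representation sequencing together with passport
records (collection latitude/longitude/altitude, sowing and harvest
dates), `ecogwas` runs the complete analysis path from raw per-site
allele read depths to classified selection signals:

* **Genotype calling** from allele depths with threshold rules
  (homozygote: ≥ 2 reads and ≥ 90% of the cell total; heterozygote:
  both alleles ≥ 1 read, each ≥ 20%, jointly ≥ 5 reads and ≥ 90%),
  followed by the standard filter cascade (site MAF ≥ 1%,
  heterozygosity ≤ 20%, missingness ≤ 70%; sample missingness < 80%;
  imputation; ≥ 20 homozygous-minor carriers).
* **Population structure**: variance-standardized relationship matrix
  `K = (1/m) Σ (x − 2p)(x − 2p)ᵀ / 2p(1−p)`, PCA, allele-sharing
  distances, neighbour-joining trees, and k-means subpopulation
  assignment with an admixed (`MIXED`) class.
* **Population genetics**: per-SNP/windowed/genome-wide Weir–Cockerham
  F<sub>ST</sub>, Watterson's θ<sub>w</sub> = S/(a<sub>n−1</sub>·L) per
  window, composite genotype r² with decay profiles and the
  half-maximum LD distance, r² ≥ 0.8 LD-block delimitation, and
  P<sub>ST</sub> = (c/h²)σ²<sub>B</sub> / ((c/h²)σ²<sub>B</sub> +
  2σ²<sub>W</sub>) with bootstrap intervals.
* **Bioclimatic traits**: the CBM photoperiod model
  D(L, J) = 24 − (24/π)·arccos[(sin pπ/180 + sin Lπ/180 · sin δ)/(cos
  Lπ/180 · cos δ)] and the maximum day length over the sowing–harvest
  window (MDL), plus tabular temperature-annual-range (TAR) and annual
  precipitation (AP) handling.
* **Association scanning**: a covariate-adjusted single-marker scan and
  an iterative fixed/random-model (FarmCPU-style) scan with pseudo-QTN
  binning, LD pruning and REML model selection; Bonferroni thresholds
  and QQ/λ<sub>GC</sub> diagnostics.
* **Quantification**: per-TAS phenotypic variance explained by
  full/reduced linear models (PVE<sub>j</sub> = R²<sub>full</sub> −
  R²<sub>j</sub>), GRM-REML heritability h² = σ²<sub>a</sub> /
  (σ²<sub>a</sub> + σ²<sub>e</sub>), homozygote-contrast allele
  effects, early-allele stacking scores, and LD-block/candidate-gene
  interval overlap.
* **Selection signals**: domestication (wild-vs-landrace F<sub>ST</sub>
  outlier + frequency shift) and diversification (among-subpopulation
  F<sub>ST</sub> outlier, subpopulation-restricted alleles) scans with
  a four-way classification.

A seeded synthetic-panel generator (Balding–Nichols differentiation,
distance-decaying LD, latitude-driven climate, additive flowering-time
genetics, Poisson read depths, selfing-level homozygosity) reproduces
the statistical structure these analyses assume, so the whole pipeline
is testable offline. See the methods vignette
(`vignettes/landrace-adaptation-methods.Rmd`) for models, assumptions
and design decisions.

## Worked example

Simulate a small four-group panel, call genotypes from read depths,
filter, and run the analysis:

```r
library(ecogwas)

cfg <- sim_config(seed = 42,
                  n_per_group = c(WILD = 30, NR = 60, HR = 60, SR = 80),
                  n_snps = 1500, n_chromosomes = 5, chrom_length_bp = 2e6,
                  n_causal = 10, effect_sd = 3)
panel <- simulate_panel(cfg)

geno <- call_genotypes(panel$depths[discover_sites(panel$depths), ]) |>
  filter_sites_pre() |> filter_samples() |>
  impute_genotypes() |> filter_sites_post(min_homozygous_minor = 5)
geno
#> <geno_matrix> 1476 sites x 230 samples, 0.0% missing

glance(wc_fst(geno, panel$samples$group, labels = c("HR", "SR")))
#> # A tibble: 1 × 3
#>   comparison   fst n_snps
#>   <chr>      <dbl>  <int>
#> 1 HR-SR      0.127   1467

ld_decay_profile(ld_r2(geno))
#> <ld_profile> 1000 bins; half-max distance: 45.5 kb

k <- relationship_matrix(geno)
heritability(k, panel$phenotypes$FT_loc1)
#> <variance_components> h2 = 0.650 (sigma_a2 = 63.5, sigma_e2 = 34.3)

pcs <- pca(k, k = 5)
scan <- scan_farmcpu(geno, panel$phenotypes$FT_loc1,
                     covariates = as.matrix(pcs$coords[, 2:4]))
thr <- bonferroni_threshold(0.01, nrow(geno$geno))
dplyr::filter(scan, p < thr$threshold)
#> # A tibble: 4 × 7
#>   chrom     pos   maf  beta    se        p not_estimable
#>   <chr>   <int> <dbl> <dbl> <dbl>    <dbl> <lgl>
#> 1 Chr02   25089 0.328  4.57 0.889 6.05e- 7 FALSE
#> 2 Chr04  605584 0.126  5.96 0.930 8.60e-10 FALSE
#> 3 Chr04 1691586 0.196  3.79 0.784 2.46e- 6 FALSE
#> 4 Chr05 1147411 0.148 -5.81 0.836 4.04e-11 FALSE
```

The panel was simulated with 10 causal loci at heritability 0.704; the
scan recovers four of the larger effects genome-wide-significantly at
this panel size, with effects in days per minor-allele copy. The
between-group F<sub>ST</sub>, LD half-decay distance and heritability
estimates reflect the configured differentiation targets, LD scale and
trait architecture. `run_pipeline(cfg, out_dir)` chains every stage
(structure, LD, bioclimatic and flowering-time scans, PVE,
heritability, selection classification) and writes TSV/CSV/Newick/BED
outputs plus a seeded manifest.

Photoperiod utilities work standalone:

```r
round(max(daylength(51.4, 1:365)), 1)   # annual max photoperiod, 51.4°N
#> [1] 16.6
mdl(40.1, 121, 274)                     # max day length, May–Oct window
```

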