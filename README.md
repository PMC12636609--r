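# rg4llps

Quantitative analysis of RNA G-quadruplex (rG4) control of FUS
liquid–liquid phase separation (LLPS).

Short G-rich RNAs that fold into G-quadruplexes can block the recruitment
of the ALS/FTD-linked protein FUS into liquid condensates, dissolve
pre-formed droplets, or — at high G4 repeat number — nucleate FUS
assembly instead. Studying this quantitatively takes a heterogeneous
toolchain: motif prediction on oligo panels, genomic-interval statistics on
rG4-seq and phase-specific interactome data, biophysical curve fitting,
plate-reader kinetics, and condensate image analysis. `rg4llps` implements
that toolchain as one tidyverse-style R package — data frames in, tibbles
out, `tidy()`/`glance()`/`autoplot()` on every fitted object — with a
synthetic-data generator providing ground truth for every stage.

## What it computes

- **rG4 motif scanning** (`find_candidates`, `classify_panel`): exhaustive
  QGRS-style enumeration of four G-runs (`g >= 2` tetrads) separated by
  three loops of 0–36 nt within a 30 nt span, with a surrogate G-score
  `10 (g - g_min) + (L_max - L) - (max loop - min loop)`.
- **Interval enrichment** (`count_overlaps`, `stratify_by_probability`,
  `phase_enrichment`, `select_candidates`, `permutation_test`): tertile
  stratification of rG4 regions by G4 probability; per-region enrichment
  `E = occurrences(soluble interactome) / occurrences(droplet interactome)`;
  permutation nulls via genome-wide interval shuffling with empirical
  `p = (1 + #[null >= obs]) / (N + 1)`.
- **Binding isotherms** (`binding_model`, `fit_binding`): the exact
  ligand-depletion solution
  `y = a0 + dAmax * [(x + Lt + Kd) - sqrt((x + Lt + Kd)^2 - 4 x Lt)] / (2 Lt)`
  fitted to anisotropy titrations (`Lt` = 8 nM by default).
- **CD melts** (`means_movement_smooth`, `subtract_blank`, `melt_model`,
  `fit_melt`, `is_parallel_g4`): means-movement smoothing, buffer
  subtraction, and the two-state van't Hoff fit
  `Y = [(m_f X + b_f) + (m_u X + b_u) Q] / (1 + Q)` with
  `Q = exp((dH/R)(1/Tm - 1/X))`, `X` in Kelvin.
- **Turbidity kinetics** (`preprocess_inhibition`, `preprocess_reversal`,
  `trace_auc`, `sedimentation_fractions`): buffer subtraction, control/
  pre-RNA normalization, trapezoidal AUC, sedimentation fractions.
- **Imaging** (`segment_droplets`, `enrichment_scores`, `phase_diagram`,
  `enhance_speckles`, `cytoplasmic_foci_mask`, `pearson_colocalization`,
  `count_assemblies`): droplet segmentation and partition (enrichment)
  scores, phase diagrams, and the stress-granule colocalization pipeline
  (speckle top-hat, nuclear shrink-and-invert masking, Pearson r).
- **Synthetic data** (`simulate_*`, `make_sequence_panel`): seeded
  generators for every input above, with planted ground truth.

## Worked example

Scan an RNA panel, run the planted enrichment pipeline, and fit curves:

```r
library(rg4llps)
library(dplyr)

classify_panel(make_sequence_panel()) |> select(name, has_rg4, g, score)
#> # A tibble: 6 × 4
#>   name         has_rg4     g score
#> 1 GGU8         TRUE        2    19
#> 2 G4C2x4       TRUE        4    28
#> 3 TERRA4       TRUE        3    19
#> 4 polyA30      FALSE      NA    NA
#> 5 GGU8_G4neg   FALSE      NA    NA
#> 6 G4C2x4_G4neg FALSE      NA    NA
```

The `(GGGGCC)4` hexanucleotide repeat scores highest (four tetrads, equal
loops); the G4-ablated and poly-A controls are negative.

```r
sim <- simulate_enrichment_dataset(seed = 1)      # 300 planted rG4 regions
pe  <- phase_enrichment(sim$regions, sim$soluble, sim$droplet)
high <- filter(pe, stratum == "high")
permutation_test(high, sim$soluble, sim$genome,
                 n_shuffles = 100, direction = "a", seed = 1)
#> Interval-overlap permutation test
#>   observed overlapping intervals: 84 of 100 in set A
#>   null: 100 shuffles of set A, mean 1.14, max 4
#>   empirical p (enrichment tail): 0.009901
```

84 of the 100 high-probability rG4 regions overlap the soluble
interactome, against a shuffle null of about one — the planted
soluble-phase enrichment, recovered at the smallest p-value 100 shuffles
can give (1/101).

```r
fit_binding(simulate_titration(delta_a_max = 0.1, k_d = 50,
                               sigma = 0.002, seed = 1), l_t = 8)
#> Ligand-depletion binding isotherm fit
#>   Kd      = 50.58 nM
#>   dAmax   = 0.1013
#>   a0      = 0.04997
#>   Lt      = 8 nM (fixed)
#>   status  = ok (residual norm 0.00507)

fit_melt(simulate_melt(tm_celsius = 50.64, delta_h = 180e3,
                       sigma = 0.1, seed = 1))
#> Two-state van't Hoff melt fit
#>   Tm  = 50.59 C
#>   dH  = 173.1 kJ/mol
#>   status = ok (sigma 0.0939 mdeg)
```

Both fitters recover their generating parameters from noisy data: the
dissociation constant within ~1% and the melting temperature within
0.05 °C here (the estimator's seed-to-seed sd is ≈ 0.4 °C at this noise
level).

```r
img <- simulate_droplet_image(n_droplets = 7, seed = 1)
seg <- segment_droplets(img$image)
#> Droplet segmentation: 7 droplets (threshold 151)
summary(enrichment_scores(img$image, seg)$enrichment)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   1.999   2.000   2.000   2.001   2.003   2.004
```

All seven planted droplets are found, and their FUS enrichment score
(mean intensity inside / mean background) recovers the planted 200:100
partition ratio.

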