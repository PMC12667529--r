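# aggrefinger

Single-particle fingerprinting of protein aggregates from single-molecule
pulldown (SiMPull) and dSTORM data.

## The problem

SiMPull captures protein assemblies from solution on an
antibody-functionalised coverslip and reads them out as diffraction-limited
fluorescent puncta under TIRF illumination; using the same monoclonal
antibody for capture and detection selects multimers over monomers. The
assay yields, per sample: puncta counts and intensities, two-channel
colabelling proportions, and — via dSTORM super-resolution — per-aggregate
nanoscale morphology. Studies of neurodegenerative disease use these
readouts to compare aggregate populations between donor cohorts (e.g.
motor-neuron-disease donors with TDP-43 pathology versus neurologically
normal controls) and to build per-donor "aggregate fingerprints" that
separate cohorts and tissues.

`aggrefinger` implements the full analysis chain for researchers running
such assays:

* **Diffraction-limited quantification** — mean projection of the trailing
  frames of a stack, background-relative punctum detection
  (median + k·MAD threshold after Gaussian smoothing), sub-pixel
  centroids, intensity measurement, count scaling by sample load.
* **Colocalization** — one-to-one nearest-neighbour matching within a
  4 px radius, plus a chance-colocalization estimate obtained by mirroring
  one channel's x-coordinates.
* **Super-resolved morphometrics** — precision filtering (< 30 nm after
  discarding the first 300 frames), block-correlation drift correction,
  DBSCAN clustering (eps 0.5 px, min 5), morphological regionization on a
  10.7 nm grid, and per-aggregate area, perimeter, eccentricity, axes,
  skeleton ("smoothed") length, localization count and density.
* **Subpopulations** — threshold classification (long ≥ 100 nm, fibrillar
  ≥ 0.9, dense ≥ 0.01 loc/nm², bright ≥ 0.9 A.U.), the 8-cell Sankey
  table, and per-donor profiles over technical replicates.
* **Cohort statistics** — 101-point nearest-interpolated cumulative
  distributions, matched-n subsampled Kolmogorov–Smirnov comparisons with
  Holm/Bonferroni families, Welch's t, one-sample relative-proportion
  tests.
* **Disease signature** — linear discriminant analysis over the 15-feature
  donor profiles with region–cohort classes, explained variance per
  discriminant, pseudo-eigenvector feature rankings, and leave-one-out
  nearest-centroid separation.
* **Aggregate-fraction proteomics** — quantification filtering (≥ 2
  peptides, ≥ 1 unique, contaminants removed), reference-sum
  normalization, per-case abundance ratios corrected by the total-proteome
  ratio of the same protein, one-sample t against no change, and volcano
  calls at |log₂| > 1, −log₁₀ p > 1.3.
* **Synthetic data** — a generator for every input (TIRF stacks,
  localization tables from parametric rod/globule shapes, donor cohorts
  with disease-direction effects, two-fraction TMT-style tables) with
  exported ground truth, so the whole pipeline is testable without tissue
  data.

The core morphometric quantities per aggregate are the mask area
`A = n_bins · Δ²` (render pixel Δ = 10.7 nm), eccentricity
`e = sqrt(1 − λ₂/λ₁)` from the second central moments, localization
density `ρ = n_loc / A`, and skeleton length `L = Σ` Euclidean steps along
the thinned mask's branches (Guo–Hall thinning, sub-resolution spurs
pruned). The proteomics correction is
`corrected ratio = (agg_case / mean agg_ctrl) / (tot_case / mean tot_ctrl)`.

## Worked example

Detect puncta in a simulated TIRF field, then measure a simulated 220 nm
rod-shaped aggregate end to end:

```r
library(aggrefinger)

sim <- simulate_tirf_stack(n_spots = 12, width = 64, height = 64, seed = 7)
proj <- mean_projection(sim$stack)          # mean of the last 40 frames
spots <- detect_puncta(proj)                # median + 5*MAD threshold
nrow(spots)
#> [1] 12
head(spots, 3)
#>    x_px  y_px  peak fov channel
#> 8 58.21 7.783 59.88   1     ch1
#> 7 10.22 7.911 60.71   1     ch1
#> 6 28.95 8.803 60.74   1     ch1

agg <- aggregate_truth(kind = "rod", length_nm = 220, x_nm = 2000,
                       y_nm = 2000, theta = 0.6, n_loc = 290, sigma_nm = 12)
lsim <- simulate_localization_table(agg, background_rate = 1, fov_px = 64,
                                    seed = 7)
res <- analyze_localizations(lsim$locs)     # filter -> DBSCAN -> measure
res$records
#>   id area_nm2 perimeter_nm eccentricity major_axis_nm minor_axis_nm
#> 1  1    15342          835        0.955           274          81.2
#>   skeleton_length_nm n_localizations density_loc_per_nm2
#> 1                267             275              0.0179

classify_aggregates(res$records)[, c("long", "fibrillar", "dense")]
#>   long fibrillar dense
#> 1 TRUE      TRUE  TRUE
```

The detector recovers all 12 rendered spots with sub-pixel centroids
(`x_px`, `y_px`; `peak` is the smoothed height above background). The
220 nm rod is measured at 267 nm skeleton length with eccentricity 0.955
and density 0.018 loc/nm², so it classifies as long, fibrillar and dense.

A full synthetic cohort run — simulation, measurement, donor profiles,
cohort statistics, LDA signature and a proteomics volcano, with CSV
outputs and a JSON manifest — is one call:

```r
res <- run_profile(pipeline_config(seed = 11L), cohort_spec(),
                   out_dir = "outputs")
```

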