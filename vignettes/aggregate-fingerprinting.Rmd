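---
title: "Fingerprinting nanoscopic protein aggregates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting nanoscopic protein aggregates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggrefinger)
```

# The measurement problem

Single-molecule pulldown (SiMPull) captures protein assemblies on an
antibody-functionalised coverslip and reads them out as diffraction-limited
fluorescent puncta under TIRF illumination. Because the same monoclonal
antibody is used for capture and detection, only particles presenting at
least two copies of the epitope — multimers, not monomers — produce a
punctum. Counting puncta quantifies aggregate load; adding a second
detection channel reports composition (what fraction of aggregates carry a
second target such as phospho-serine-modified TDP-43); and switching to
dSTORM super-resolution turns each captured aggregate into a cloud of
localizations from which nanoscale morphology (length, eccentricity,
localization density) can be measured. This package implements that entire
analysis chain, together with cohort statistics, a linear-discriminant
disease signature over per-donor feature profiles, and the
total-proteome-corrected enrichment analysis used for aggregate-fraction
proteomics.

Post-mortem tissue data are not distributable with a package, so every
input is emulated by a synthetic-data generator that exports its ground
truth. All recovery and calibration claims in the test suite are claims
about this synthetic emulation; what that does and does not imply for real
data is discussed at the end.

# Diffraction-limited quantification

A field of view is a 512 x 512 px EMCCD frame at 107 nm/px (so a field
spans 54.784 µm on a side); 50 frames are acquired and the trailing 40 are
averaged (`mean_projection()`) to suppress noise — early frames carry the
highest background. Detection (`detect_puncta()`) is deliberately simple
and background-relative:

1. Gaussian smoothing (sigma = 1 px, about the PSF scale);
2. a robust threshold, median + k x MAD with k = 5 by default — both knobs
   mirror the practice of tuning detection on positive and negative
   control wells;
3. local maxima above threshold, merged within 3 px (the brightest
   candidate wins);
4. sub-pixel centroids by intensity-weighted means in a 5 x 5 window.

Because the threshold is relative to the image median, adding a constant
offset changes nothing, and raising k can only reduce the count — both are
asserted as properties in the test suite. Spot intensities are measured in
a square window; spots whose window crosses the image border are excluded
rather than measured on a clipped window, to keep intensities unbiased.
Counts can be normalised to material loaded via
`scale_count(count, weight_mg, conc_mg_per_ml)`, which divides by the
product of the two factors — both inflate the amount of material assayed,
so both divide.

# Two-channel colocalization and the chance estimate

`match_spots()` matches centroids across channels within a 4 px radius,
accepting candidate pairs in order of ascending distance so that each spot
is matched at most once and always to its nearest available partner; exact
distance ties break by the lower spot index. The colabelled proportion is
matched spots over the reference-channel total.

The chance estimate mirrors channel B about the image's vertical axis
(x to width - 1 - x) and repeats the matching. Mirroring preserves the
spot density and the y-structure of the channel while destroying true
correspondence, which is exactly what a chance estimate needs. (An axis
swap x <-> y would be an alternative reading; the mirror is the default
and the choice is config-exposed as `chance_transpose`.) For independent
uniform channels the chance proportion approaches the Poisson-field
expectation 1 - exp(-rho pi r^2); the acceptance suite verifies this
calibration by simulation.

# Super-resolved morphometrics

The localization table (frame, x, y, photons, PSF widths, background,
per-axis precision; pixel units, 0-based, origin at the centre of pixel
(0,0)) is processed as follows.

**Filtering.** The first 300 frames are discarded and localizations must
have pooled precision (mean of the per-axis values) strictly below 30 nm.
The filter is idempotent.

**Drift correction** (`estimate_and_correct_drift()`). The acquisition is
split into equal temporal blocks (10 by default); each block is rendered
as a 2-D histogram and FFT-cross-correlated against the first block, with
parabolic sub-bin peak refinement; block shifts are interpolated
piecewise-linearly over frames (linearly extrapolated beyond the first and
last block centres) and subtracted. This is a single-reference
simplification of redundant (all-pairs) cross-correlation: it estimates
each block against one anchor rather than averaging all pairwise
estimates, trading some noise robustness for simplicity. On synthetic
fields it recovers a linear 0.002 px/frame drift over 5000 frames to
within a few percent of the terminal displacement.

**Clustering.** DBSCAN with eps = 0.5 px and a minimum neighbourhood of 5
localizations (the point itself included) separates aggregates from random
background. The implementation buckets points on an eps-sized grid for
neighbour search. One detail is pinned down deterministically: a border
point reachable from two clusters joins the cluster of its lowest-index
core neighbour. The test suite checks label-for-label identity against a
brute-force density-reachability oracle on random instances.

**Regionization.** Cluster localizations are binned onto a 10.7 nm grid —
one tenth of the camera pixel, chosen to be of the order of the ~12 nm
localization precision, the standard oversampling for rendering — then
dilated (disc radius 1 bin), closed (radius 2) and eroded (radius 1) to
bridge jitter gaps without inflating 100 nm-scale features, and the
largest 8-connected component is kept. With all radii zero the mask is
exactly the occupied bins; a degenerate cluster of identical localizations
yields a single-bin mask.

**Measurement** (`measure_aggregate()`). Area is the bin count times the
squared render pixel; perimeter is the boundary crack length (exposed bin
edges); eccentricity and axes come from the ellipse with the region's
second central moments, with the 1/12 bin-extent term added so that a
single-bin-wide region has eccentricity strictly below 1; localization
density is count over area, so density x area reproduces the count
exactly.

Skeleton length — the "smoothed length" entering the donor profiles — is
measured by topological thinning followed by summing Euclidean steps along
all skeleton branches. Two numerical choices deserve record:

* *Thinning algorithm.* Textbook parallel Zhang-Suen deletes
  simultaneously within each sub-iteration and is known to collapse
  diagonal strokes and 2 x 2 blocks; on diagonal rod masks it shortened
  skeletons catastrophically. The package instead implements Guo-Hall
  two-subiteration thinning driven by the standard G123/G123' deletion
  lookup tables, which preserves connectivity, endpoints and diagonal
  strokes.
* *Branch summing and spur pruning.* The summed branch distance is the
  total edge length of the minimum spanning tree of the skeleton's
  8-adjacency graph (which drops the redundant diagonals of
  orthogonal-diagonal triangles, as walking the branches would). Because
  Guo-Hall preserves endpoints, thinning a jitter-ragged outline leaves
  short terminal spurs; leaf-to-junction branches shorter than 5 render
  bins (~55 nm, the typical mask half-width — a side branch shorter than
  the local width cannot be a resolved real branch) are pruned before
  summing. Leaf-to-leaf paths, i.e. the backbone of a fibril, are never
  pruned.

On simulated rods the chain recovers skeleton length within +-20% of
ground truth for 150-500 nm rods and recovers length ordering with
Spearman rho above 0.95 across 50-500 nm. Below ~150 nm the estimator is
biased high (the object's length approaches its blurred width, and the
skeleton of a roundish blob no longer tracks the rod axis), and at exactly
100 nm the mask's eccentricity falls just short of the 0.9 fibrillar
threshold (about 0.87 on average for a 20 nm-wide rod jittered by 12 nm
precision). Both shortfalls are measured and asserted openly in the
acceptance tests — the corresponding expectations are left failing rather
than loosened — and they delimit the size range over which per-aggregate
morphometrics should be trusted: robust above ~150 nm, order-preserving
but biased below.

# Subpopulations and donor profiles

Aggregates are classified against cumulative thresholds: long (skeleton
length >= 100 nm), fibrillar (eccentricity >= 0.9), dense (>= 0.01
localizations/nm^2, sparse otherwise) and bright (scaled intensity >= 0.9
A.U.). Inclusive (>=) boundaries are used — the source material prints
both ">" and ">=" variants, and the inclusive reading is adopted and
config-exposed (`threshold_boundary`). `tabulate_subpopulations()` returns
the 8-cell (long x fibrillar x dense) table whose proportions a Sankey
diagram visualises; cells always sum to the record count.

`build_donor_profiles()` reduces replicate-level measurements to one row
per donor and region: continuous features are averaged within each
technical replicate and then across replicates; proportion features are
computed over all of the donor's aggregates; spot intensities are min-max
scaled to [0, 1] by the per-region batch maximum (so the 0.9 "bright" cut
is meaningful — per-batch rather than per-replicate scaling was chosen so
that brightness is comparable across a panel); and the count feature is
the donor's mean count as a proportion of the maximum donor count within
the same region, so exactly one donor per region scores 1.

# Cohort statistics

**Interpolated CDFs.** To average cumulative distributions across donors
with different sample sizes, each sample's empirical CDF is evaluated at
101 fixed proportions (0, 0.01, ..., 1) by nearest-neighbour inversion:
the value at proportion p is the sample value whose empirical proportion
is closest to p (lower rank on ties). The result is non-decreasing and
invariant to input order.

**Subsampled KS comparisons.** Populations of very different sizes
confound KS tests, so `bootstrap_ks()` draws matched-n subsamples (1000 by
default) without replacement from each population, applies the two-sample
asymptotic KS test per draw, and reports the median statistic and median
p-value over `n_boot` draws (100 by default; how repeats should be
combined is not pinned down by any convention, so the median — stable at
desk scale — is the default and the raw vectors are returned for any other
summary). One calibration fact matters: when the populations are exactly
the matched size, the subsample is the population and the procedure is an
exactly calibrated single KS test; when populations are much larger than
the subsample, overlapping subsamples correlate the repeats and the
median-p summary becomes conservative (it under-rejects, never
over-rejects). The type-I calibration in the acceptance suite is therefore
run at matched size, where the claim is exact.

Multiplicity corrections are applied over explicitly declared families
(`correct_family()`): Holm for per-cohort families, plain Bonferroni for
per-population families. Family membership is always an argument — it is
never inferred from data. Donor-level mean comparisons use Welch's
unequal-variance t-test; relative proportions against a no-difference
value of 1 use a one-sample t with Bonferroni correction for the number of
targets.

# The discriminant disease signature

Each donor x region observation carries 15 features: mean assembly count
(normalised), area, eccentricity, perimeter, minor and major axis lengths,
localization count, smoothed (skeleton) length, localization density and
scaled intensity, plus the proportions of assemblies classed bright,
pSER-colocalized, fibrillar, long and sparse. Features are standardized
before LDA because they mix nm, counts and proportions — unstandardized
axes would let large-variance features dominate. The observation unit is
the donor x region mean vector (one marker per donor), not the technical
replicate.

`fit_lda()` solves the within/between scatter eigenproblem directly:
discriminant directions are eigenvectors of Sw^-1 Sb with at most
(classes - 1) components, each direction normalised with a deterministic
sign; when Sw is near-singular (few donors, many features) a ridge of
1e-6 x trace(Sw)/p is added. The explained-variance ratio of each
discriminant is its eigenvalue over the retained total, and the
coefficient columns act as pseudo-eigenvectors whose absolute values rank
each parameter's contribution (`rank_contributions()`, name-ordered on
ties). The implementation is cross-checked in the test suite against an
independent reference (MASS) on well-conditioned fixtures, and
`loo_nearest_centroid()` quantifies class separation in the 2-D projection
by leave-one-out nearest-centroid prediction.

# Aggregate-fraction proteomics

Protein-group tables are filtered to non-contaminant proteins identified
by at least two peptides with at least one unique
(`filter_quantified()`; contaminants are a flag column plus accession
prefixes, `CON__` and keratins by default). Reporter abundances are
normalised by reference sums (`reference_normalize()`): total-proteome
tables per run (all channels in a run share the run's pooled-reference
sum), aggregate tables per channel (affinity capture makes loading
channel-specific). Sums are scaled relative to their grand mean — the
grand mean rather than an arbitrary anchor run, so normalisation does not
depend on run order.

The core correction: for each protein quantified in at least one donor in
both fractions, per-case ratios against the mean control abundance are
formed in each fraction, and the aggregate ratio is divided by the total
ratio of the same protein. A proteome-wide change (every case channel
multiplied by a constant in both fractions) cancels exactly — this
identity is asserted in the tests. Corrected ratios are summarised by
their mean log2 and a one-sample t-test of log2 ratios against 0 —
equivalent in orientation to testing the ratios against a hypothetical
mean of 1, but symmetric in variance, which is why the log scale is used.
Volcano calls use |log2| > 1 and -log10 p > 1.3. One compositional caveat
is worth knowing: sum-based channel normalisation assumes enrichments are
sparse or balanced; a large one-sided spike-in inflates channel sums and
shrinks recovered log2 ratios by roughly log2 of the spiked mass fraction.
Realistic designs, with a small number of enriched and depleted proteins,
are essentially unaffected.

# What the synthetic generator emulates — and what it does not

The generator produces every input the pipeline consumes, with exported
ground truth: TIRF stacks (2-D Gaussian PSFs, Poisson shot noise plus
Gaussian read noise on a constant baseline), localization tables (rods as
line segments convolved with an isotropic Gaussian of 20 nm FWHM —
matching the near-1-D fibril picture — and globules as uniform discs;
per-axis precision jitter whose sigma is stored verbatim in the precision
columns; uniform frame assignment; uniform background; optional cumulative
linear drift), donor cohorts and two-fraction quantification tables.

The default cohort emulates the study design: 3 control, 2 SOD1-MND and 5
TDP-MND donors, two regions each (cerebellum, frontal cortex), three
technical replicates, and disease-direction effects — TDP-MND aggregates
longer, more frequently rod-shaped, sparser in localizations; counts
higher in disease cerebellum but lower in disease frontal cortex; pSER
colabelling raised in disease frontal cortex. Between-donor variability is
a log-normal multiplier with 8% CV on each parameter family. Per-aggregate
localization counts scale with extent at ~1.3 localizations/nm (about 200
for a 150 nm rod), defaults chosen as plausible rather than claimed.
Problem sizes in the tests are chosen for desk-scale runs: ~40 aggregates
per replicate, 5000-frame acquisitions, 10 donors per cohort for the
signature fixture, 300-protein quantification tables.

Not emulated: photoswitching kinetics and blinking statistics (frame
assignment is uniform, so repeated localizations of one fluorophore are
absent), EMCCD gain and pixel-correlated noise, optical aberrations,
non-uniform illumination, antibody labelling stoichiometry, and any
spatial correlation between morphology and position in the field. Passing
recovery tests therefore demonstrate that the analysis chain measures what
it claims on data matching its model assumptions — they do not certify
performance on tissue-derived data, where background structure, blinking
and labelling effects add error modes the generator does not contain.

# Known limitations

* Per-aggregate skeleton length is unreliable below ~150 nm (biased high;
  see the morphometrics section) and the 0.9 eccentricity cut
  under-classifies rods near 100 nm; population-level orderings remain
  monotone.
* The median-p bootstrap KS summary is conservative when populations
  greatly exceed the subsample size.
* Drift correction assumes structure-rich fields; a field with few
  aggregates gives noisy block correlations.
* The LDA observation unit (donor x region) gives small n; with 15
  features the within-class scatter is regularised, and explained-variance
  ratios at such n carry wide sampling variability.
* Localization-table I/O is CSV-based.
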