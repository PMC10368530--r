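---
title: "Methods: image feature models from high-plex tissue immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image feature models from high-plex tissue immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ifmkit` implements the computational path from same-section high-plex
immunofluorescence single-cell data to prognostic *image feature models*
(IFMs): spectral extraction of fluorophore signal, Gaussian-mixture gating,
tumor-center / invasive-margin compartmentalization, an exhaustive
marker-combination hazard-ratio search, spatial-LDA neighborhood topics, and
survival-based model comparison. This vignette records the model
assumptions, the tunable parameters, the numerical choices made where the
design was genuinely open, and what the synthetic-data generator does and
does not establish.

## 1. Spectral extraction

A multi-channel acquisition is modelled per pixel as

$$ y = M a + f + \varepsilon, \qquad a \ge 0, $$

where $y$ is the vector of channel intensities, $M$ the channels ×
fluorophores mixing matrix, $f$ a per-channel autofluorescence profile and
$\varepsilon$ read noise. `fit_mixing_matrix()` estimates each column of
$M$ from a single-stain control: after subtracting the autofluorescence
profile (per-channel median of an unstained acquisition), the column is the
per-channel median over the top 5% brightest pixels in the fluorophore's
home channel, scaled to unit maximum. The top-quantile rule is a recorded
decision — bright pixels in a single-stain control are dominated by true
signal, and the median over them is robust to residual background.
Near-collinear columns (condition number above `max_condition`) raise an
error naming the most similar fluorophore pair, because unmixing against
nearly identical spectra is ill-posed no matter the solver.

`unmix()` solves per-pixel nonnegative least squares (Lawson–Hanson active
set, compiled) with the autofluorescence profile appended as an extra
column and dropped afterwards. NNLS is the default because negative
abundances are unphysical; a pseudoinverse-with-clipping mode is provided
for speed at high signal-to-noise. Channel crosstalk is quantified by
`crosstalk_metric()`: for each fluorophore, mean pixel intensity per
channel over the pixels bright in its home channel, normalized to the home
channel, averaged over spectrally adjacent channel pairs (neighbors in
wavelength-sorted channel order). On simulated stacks whose mixing matrix
bleeds 35% into adjacent channels, the raw report reads ≈35% and the
post-extraction report is well below 1% — the acceptance suite measures
both.

## 2. Gating

Marker positivity is called per specimen by a two-component Gaussian
mixture on `log1p` intensities (the log transform is an assumption: the
intensity model is log-normal and the transform is standard practice for
immunofluorescence; the source analysis names only the mixture model). The
EM fit uses quantile-anchored starts plus nine seeded jittered restarts,
best likelihood winning, so gates are deterministic given the seed. The
threshold is the point between the component means where the posteriors are
equal (root-finding; midpoint fallback if the posteriors do not cross
between the means, which can happen with very unequal variances). A
component weight below 1% triggers the degenerate fallback: all cells
negative, warning flag set. Per-specimen gating is the default because
staining intensity varies specimen to specimen; a pooled-cohort mode exists
and is what the frozen-model transfer protocol serializes.

Cell types are called by an ordered rule dendrogram
(`default_dendrogram()`, editable config): tumor via pan-cytokeratin, then
the CD45 branch (CD20 B cells, CD3 with CD4/CD8/FOXP3 splits), myeloid
markers, endothelium, stroma. Cells matching no rule are `Unassigned`; the
unassigned fraction per specimen is a first-class output because a
substantial minority of nuclei in real colorectal sections (median around
16%) carry no lineage marker.

## 3. Compartments: tumor center and invasive margin

The tumor region is the KNN majority vote: a cell is tumor-region when most
of its $k=25$ nearest cells are pan-cytokeratin positive. The
tumor–stroma boundary is extracted by rasterizing the smoothed label onto a
20 µm grid. Because a cell table is a sparse point set, the raster is
filled by a box majority of half-width `smooth_um` (100 µm default,
computed with summed-area tables; pixels whose window is empty fall back to
the nearest cell's label), followed by a 3×3 morphological closing. The
boundary is the set of midpoints of edges between tumor and stroma pixels.
Cells within `margin_um` (100 µm default; 360 µm reproduces the published
Immunoscore convention) of the boundary on either side are invasive margin
(IM); tumor-region cells deeper inside are tumor center (CT); IM overrides
CT so the two scoring regions are disjoint. All tumor components count, not
only the largest. The raster pitch's effect is bounded by an oracle test:
distances to the boundary point set agree with exact point-to-segment
distances within one pixel, and on disk-geometry specimens the IM set
matches the analytic annulus to under 1% of cells at realistic density
(≈200 cells/mm²; the margin of agreement improves with density, and the
disk-oracle tests state the density they use).

Rotation invariance is approximate (the raster has axes); the suite asserts
≥98% agreement under a 30° rotation. Region statistics divide
marker-positive cells by *all* segmented cells in the region — never by a
marker-positive total — and empty regions propagate as missing values, not
zeros, so they drop out of cohort medians.

## 4. Image feature models

For a parameter (marker, region ∈ {CT, IM}) the specimen's value is its
positive-cell fraction. A model of four parameters scores each specimen by
comparing each fraction to the *cohort median* of that parameter: strictly
above scores 1, at or below scores 0 (the tie rule is a recorded decision;
the published description leaves ties open). Totals 0–4 binarize to low
(≤2) vs high (≥3). `compute_ifm1()` is the CD3/CD8 × CT/IM special case —
the Immunoscore-like model. `enumerate_ifms()` generates all
$\binom{26}{4} = 14{,}950$ four-parameter models over the 13-marker immune
panel; `score_and_rank()` scores them all (class vectors are deduplicated
before the survival calls, so the exhaustive search takes about a second on
a 40-specimen cohort) and ranks by ascending hazard ratio, ties broken by
smaller log-rank p then canonical id. Models with a one-sided class split
or an event-free class are flagged and excluded from the ranking.
`select_ifm2()` walks the ranking skipping models containing excluded
markers (CD3/CD8 by default — the markers already spent on IFM1); the
published IFM2 composition (α-SMA CT; CD45, PD-L1, CD4 IM) ships as
`ifm2_preset()`.

Marker enrichment over the ranking uses a GSEA-style running sum with hit
step $+1/(2 n_{hit})$ and miss step $-1/(2 n_{miss})$, so the sum ends at
zero, the enrichment score (the extremum) lies in $[-1, 1]$, and a feature
occupying exactly the top half of the list scores $+0.5$; p-values come
from the two-sample Kolmogorov–Smirnov test on the rank distributions.

IFM3 splits the cohort at a percentile (default 50, configurable to 75) of
one topic's per-specimen fraction; specimens at or above the cutoff are
"high" (the at-or-above rule makes the percentile-0 split degenerate by
construction, which is the documented error case). The topic defaults to
the one whose fraction correlates most strongly in absolute value with
progression-free survival. IFM4 is the composite: class 1 = IFM1-high *and*
IFM3-low, class 2 = everyone else.

## 5. Spatial LDA

Marker-positive calls are binned into square grids of 200 µm side (the
published "grids of 200 microns" is read as the side length — a 200 µm²
square would be smaller than a cell); a cell positive for $m$ markers
contributes $m$ tokens, grids with fewer than 5 cells are dropped, and by
default only tumor + margin cells feed the corpus (flag to use all cells).
The collapsed Gibbs sampler reassigns token topics with the standard
conditionals; φ and θ are posterior means over post-burn-in sweeps.
Hyperparameters α = 50/K, β = 0.01, 1000 sweeps with 500 burn-in are
standard defaults (unstated in the source analysis), all configurable. The
topic number is chosen by held-out perplexity
$\exp(-\tfrac{1}{N}\sum \log p(w))$ over K = 8…16: held-out documents are
folded in with φ fixed to estimate θ, ties go to the smaller K. Cells
inherit the argmax topic of their grid; an alternative per-cell
token-resampling mode was considered and rejected as needless complexity —
grid argmax is deterministic and the per-specimen fractions are what the
downstream models consume.

Label switching is handled in tests by Hungarian matching on φ (cosine
similarity) before comparison. Document order changes the Gibbs trajectory,
so order invariance holds in distribution, not token-for-token; the suite
asserts matched-topic cosine > 0.95 across a permutation.

## 6. Survival statistics

Kaplan–Meier estimation is the standard product-limit estimator. The
two-group comparison is the log-rank test, and the hazard ratio is the O/E
form
$$ \mathrm{HR} = \frac{O_a / E_a}{O_b / E_b}, \qquad
   \mathrm{CI} = \exp\!\left(\ln \mathrm{HR} \pm 1.96
   \sqrt{1/E_a + 1/E_b}\right), $$
with expected events from the usual 2×K table sums and p from the
chi-square statistic on 1 df. The CI form is a recorded decision (the
source names only "the log-rank approach"; this matches common
MatSurv-style output). Event conservation $O_a + O_b = E_a + E_b$ holds to
1e−9 and is asserted property-style.

**A caveat the test suite makes explicit:** the O/E hazard ratio is *not*
a consistent estimator of the true hazard ratio under full follow-up. With
exponential arms at true HR 0.2 and everyone observed to the event, its
median is ≈0.31 — risk sets deplete asymmetrically and the aggregate O/E
ratio attenuates toward 1. Under administrative censoring typical of
progression-free-survival cohorts the estimator tracks the truth closely
(median 0.218 at 30% censoring, 0.204 at 70%). One acceptance criterion
asserts 0.2 ± 0.04 recovery *without* censoring; it is left red on purpose
with this analysis, because the estimator is the published formula and
weakening either side would misrepresent it.

Model comparison: leave-one-out re-runs the entire rank pipeline once per
left-out specimen and compares the two models' rank vectors by paired
t-test; the bootstrap draws 500 resamples with replacement at cohort size,
recomputes medians, classes and HRs per resample (degenerate resamples
dropped and counted), and compares HR vectors likewise.
Benjamini–Hochberg (step-up, FDR 0.1) adjusts across the supplied test
family.

## 7. The synthetic cohort: what it is and is not

The generator emulates exactly the structure the downstream stages assume:
log-normal two-population intensities per marker; a spatially coherent
tumor (smoothed random blob by default for realistic boundary curvature,
disk mode for analytic oracles) occupying a set fraction of a rectangular
tissue; pan-cytokeratin positive at 0.9 inside the tumor and 0.02 outside;
per-specimen immune positive fractions drawn logit-normally around a shared
infiltration latent (sd 0.8), which realistically *correlates* the immune
markers; exponential proportional-hazards survival with independent uniform
administrative censoring calibrated to a target censoring rate (30%
default); defaults of 40 specimens and 5000 cells per specimen at 5×5 mm,
baseline hazard 1/730 per day (median PFS about two years). Ground-truth
labels ride along every output so recovery tests never re-derive truth from
generator internals.

The spectral simulator's stated world: each fluorophore's abundance map is
a pyramid profile filling its own tile of the field, so supports are
spatially disjoint (the disjoint-support identity is testable exactly)
while each fluorophore is bright over a realistic fraction of the image, as
in single-stain control sections where tissue covers most of the field.
Noise is signal-proportional (per-pixel Gaussian sd = `noise_sd` × clean
intensity — "2% noise" means 2% *of signal*, a shot-noise stylization);
under an absolute-noise reading (the same sd on signal-free pixels) the
post-extraction crosstalk metric would carry an irreducible floor of
several percent from nonnegativity-rectified noise, for any extraction
algorithm. Autofluorescence is a smooth field
shared between the controls and the unstained acquisition, mirroring paired
autofluorescence imaging of the same section.

One deliberate deviation from the specification's wording is recorded: the
hazard coefficients act by default on the *binary above/below-cohort-median
indicator* of each marker's specimen fraction (`effect_on = "indicator"`),
so a planted log-hazard of −1.6 yields a true-split group hazard ratio of
exactly $e^{-1.6} = 0.2$ and recovery tests have an exact target; the
literal coefficient-times-fraction form is available as
`effect_on = "fraction"`, where the group HR additionally depends on the
fraction spread.

Not emulated: segmentation errors, nucleus/membrane subcompartments,
immune-marker spatial gradients toward the margin (immune positivity is
spatially uniform given the specimen, so region fractions have the same
expectation in CT and IM), tissue folds or autofluorescent debris, and
non-proportional hazards. A green test therefore establishes algorithmic
correctness on data satisfying the stated model — not robustness to the
full messiness of segmented whole-slide images.

## 8. File formats and configuration

All interchange is plain text: cell and clinical tables as CSV (doubles
serialized at 17 significant digits so tables round-trip bit-identically),
image stacks as long-format CSV with a JSON channel-metadata sidecar (the
pre-installed R stack has no TIFF codec; the array APIs are
format-agnostic), configuration as namespaced JSON whose defaults equal the
published parameters (margin 100 µm, KNN 25, grids 200 µm, K range 8–16,
median cutoffs, 500 bootstrap resamples, FDR 0.1). The frozen-model
transfer protocol serializes cohort medians, gate thresholds, φ, the chosen
topic and its absolute cutoff, and re-applies them verbatim to a second
cohort — medians are never recomputed on the test cohort.

## 9. Known limitations

- The boundary raster (20 µm) and box smoother (100 µm) bound, but do not
  eliminate, geometric error at very low cell density; the disk oracle
  quantifies it.
- The exhaustive search's HR ranking inherits the O/E estimator's
  attenuation; rankings are monotone in the attenuated HR, so model
  *order* is less affected than the absolute HR values.
- LDA topic recovery assumes topics differ in marker support; topics that
  differ only in proportions need longer documents than 200 µm grids
  typically provide.
- No covariate adjustment (Cox regression is out of scope by design), no
  competing risks, single endpoint.
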