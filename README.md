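# ifmkit

Image feature models (IFMs) from high-plex tissue immunofluorescence
single-cell data.

## The problem

Whole-slide multiplexed immunofluorescence produces, for every segmented
cell, a position and a vector of marker intensities across 16–20 channels.
Turning that into a *prognostic score* for a patient cohort involves a
chain of well-defined computational steps, each easy to get subtly wrong:

1. **Spectral extraction** — estimate a channels × fluorophores mixing
   matrix `M` from single-stain controls and solve, per pixel, the
   nonnegative least-squares problem `M a ≈ y` to remove channel crosstalk.
2. **Gating** — call each marker positive/negative per cell with a
   two-component Gaussian mixture on log intensities.
3. **Compartments** — build a tumor mask from pan-cytokeratin⁺ cells with a
   KNN majority vote (k = 25), extract the tumor–stroma boundary, and label
   every cell tumor center (CT), invasive margin (IM, ±100 µm around the
   boundary), or outside.
4. **Model search** — for 13 immune markers × 2 regions = 26 parameters,
   score every specimen on every C(26,4) = 14,950 four-parameter model by
   cohort-median splits (subscore 1 if the positive-cell fraction exceeds
   the cohort median; totals 0–4 binarized low ≤ 2 / high ≥ 3), and rank
   the models by the log-rank O/E hazard ratio
   `HR = (Oa/Ea)/(Ob/Eb)` of high vs low progression-free survival.
5. **Spatial LDA** — bin marker-positive events into 200 µm grids, fit
   topics by collapsed Gibbs sampling, choose the topic number by held-out
   perplexity over K = 8…16, and derive a topic-fraction model (IFM3) and a
   composite immune + tumor-intrinsic model (IFM4).
6. **Comparison** — leave-one-out rank stability, 500-rep bootstrap of
   HRs, paired t-tests with Benjamini–Hochberg adjustment (FDR 0.1).

`ifmkit` implements the whole chain as a tested R package, plus a
synthetic-data generator (spectral stacks with a known mixing matrix;
patient cohorts with planted proportional-hazards effects and ground-truth
labels) so every stage is verifiable without any patient data. It is aimed
at computational pathology / tissue-imaging analysts who want the
Immunoscore-style pipeline as reusable, inspectable code.

## Worked example

```r
library(ifmkit)

# a synthetic 12-specimen cohort with a protective CD8 effect (HR 0.37)
sim <- simulate_cohort(cohort_sim_spec(
  n_specimens = 12, cells_per_specimen = 600,
  infiltration_effect = c(CD8 = -1.0), tissue_um = c(2000, 2000),
  seed = 19))

cfg <- pipeline_config(
  panel = list(tumor_marker = "panCK",
               immune_markers = c("CD3", "CD8", "CD45", "CD4", "CD20")),
  lda = list(K = 3, n_iter = 150, burnin = 80, min_cells = 3))

res <- run_pipeline(sim$cells, sim$clinical, cfg)
str(res$summary$ifm1)
```

```
List of 5
 $ rank   : int 19
 $ hr     : num 0.123
 $ ci_low : num 0.0238
 $ ci_high: num 0.641
 $ p      : num 0.0126
```

Reading: on this small synthetic cohort the Immunoscore-like IFM1 (CD3/CD8
in CT and IM, median cutoffs) stratifies patients at HR ≈ 0.12 with
log-rank p ≈ 0.013 — the high-score class progresses markedly more
slowly — ranking 19th among the 210 models of the trimmed 5-marker search
space.
`res$summary$ifm2` holds the best model avoiding CD3/CD8,
`res$summary$ifm3` the spatial-topic model, and `res$summary$ifm4` the
composite; `res$frozen` carries the trained medians/thresholds/topics for
re-applying the frozen model to a second cohort
(`run_pipeline(..., frozen = res$frozen)`), which never recomputes cohort
medians on the test cohort.

Individual stages are ordinary functions (`fit_mixing_matrix()`,
`unmix()`, `gmm_gate()`, `build_tumor_mask()`, `assign_compartments()`,
`region_fractions()`, `enumerate_ifms()`, `score_and_rank()`,
`marker_enrichment()`, `fit_lda()`, `select_K()`, `logrank_hr()`,
`bootstrap_compare()`, …); see the methods vignette
(`vignettes/methods.Rmd`) for the model assumptions and numerical choices.
A thin CLI wrapper lives at `inst/cli/ifmkit.R`.

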