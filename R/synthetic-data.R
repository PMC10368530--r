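#' Default marker panel
#'
#' Marker names used by the cohort simulator and the model search: the tumor
#' lineage marker (pan-cytokeratin) plus the 13 immune-focused markers whose
#' tumor-center / invasive-margin positive fractions form the 26-parameter
#' search space. The 13th immune marker is panel configuration (CD31 here);
#' the combinatorial search only depends on the count.
#'
#' @return list with elements `tumor` (single name) and `immune`
#'   (13 names).
#' @export
default_panel <- function() {
  list(tumor = "panCK",
       immune = c("CD3", "CD8", "CD45", "CD45RO", "CD68", "CD163", "CD4",
                  "CD20", "aSMA", "FOXP3", "PD1", "PDL1", "CD31"))
}

# ---------------------------------------------------------------------------
# Spectral stack simulation
# ---------------------------------------------------------------------------

#' Build a mixing matrix with adjacent-channel bleed
#'
#' Each fluorophore responds maximally in its home channel (channel index =
#' fluorophore index) and bleeds a fixed fraction of that response into the
#' spectrally adjacent channels, emulating narrow-bandpass emission overlap.
#' Columns are normalized to sum to one.
#'
#' @param n_channels,n_fluors counts, `n_channels >= n_fluors`.
#' @param bleed fraction of home-channel response appearing in each adjacent
#'   channel (default 0.35, the mean adjacent-channel crosstalk level of raw
#'   narrow-band acquisitions).
#' @return `n_channels x n_fluors` nonnegative matrix, columns summing to 1.
#' @export
adjacent_bleed_mixing <- function(n_channels, n_fluors, bleed = 0.35) {
  stopifnot(n_channels >= n_fluors, bleed >= 0)
  M <- matrix(0, n_channels, n_fluors)
  for (f in seq_len(n_fluors)) {
    M[f, f] <- 1
    if (f > 1) M[f - 1, f] <- bleed
    if (f < n_channels) M[f + 1, f] <- bleed
  }
  sweep(M, 2, colSums(M), "/")
}

#' Specification for a synthetic spectral stack
#'
#' @param n_channels number of acquisition channels.
#' @param n_fluors number of fluorophores (`<= n_channels`).
#' @param mixing optional `n_channels x n_fluors` nonnegative matrix of
#'   channel responses per fluorophore (columns sum to 1); defaults to
#'   [adjacent_bleed_mixing()] with 35% bleed. Every column must have a
#'   unique argmax channel (its home channel) and no column may be zero.
#' @param autofluor_level mean autofluorescence intensity added to every
#'   channel (arbitrary units; 0 disables).
#' @param noise_sd fractional Gaussian noise level: each pixel's sd is
#'   `noise_sd` times its clean intensity (0.02 = noise at 2% of signal, a
#'   shot-noise stylization; 0 disables).
#' @param image_shape `(rows, cols)` of the simulated field.
#' @param amplitude peak fluorophore abundance (arbitrary units).
#' @param seed integer seed; all outputs are deterministic given the seed.
#' @return object of class `spectral_sim_spec`.
#' @export
spectral_sim_spec <- function(n_channels, n_fluors, mixing = NULL,
                              autofluor_level = 0, noise_sd = 0,
                              image_shape = c(64, 64), amplitude = 1000,
                              seed = 1) {
  if (is.null(mixing)) mixing <- adjacent_bleed_mixing(n_channels, n_fluors)
  stopifnot(n_channels >= n_fluors,
            nrow(mixing) == n_channels, ncol(mixing) == n_fluors,
            all(mixing >= 0), autofluor_level >= 0, noise_sd >= 0,
            length(image_shape) == 2, all(image_shape >= 4))
  if (any(colSums(mixing) == 0)) {
    stop("mixing has a zero column: a fluorophore invisible in all channels")
  }
  homes <- apply(mixing, 2, which.max)
  if (anyDuplicated(homes)) {
    stop("mixing columns must have unique argmax (home) channels")
  }
  structure(list(n_channels = as.integer(n_channels),
                 n_fluors = as.integer(n_fluors), mixing = mixing,
                 autofluor_level = autofluor_level, noise_sd = noise_sd,
                 image_shape = as.integer(image_shape),
                 amplitude = amplitude, seed = as.integer(seed),
                 homes = homes),
            class = "spectral_sim_spec")
}

# One tile per fluorophore with a pyramid intensity profile filling the
# whole tile: supports are spatially disjoint (tiles partition the image),
# every fluorophore is bright somewhere, and each support covers a
# realistic fraction of the field (real single-stain controls have tissue
# across most of the image).
abundance_maps <- function(spec) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  nf <- spec$n_fluors
  ncol_t <- ceiling(sqrt(nf)); nrow_t <- ceiling(nf / ncol_t)
  A <- array(0, dim = c(nf, h, w))
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (f in seq_len(nf)) {
    ti <- (f - 1) %/% ncol_t; tj <- (f - 1) %% ncol_t
    r0 <- ti * h / nrow_t; c0 <- tj * w / ncol_t
    th <- h / nrow_t; tw <- w / ncol_t
    cy <- r0 + th * runif(1, 0.45, 0.55)
    cx <- c0 + tw * runif(1, 0.45, 0.55)
    in_tile <- rows > r0 & rows <= r0 + th & cols > c0 & cols <= c0 + tw
    prof <- pmax(0, 1 - pmax(abs(rows - cy) / (th / 2),
                             abs(cols - cx) / (tw / 2)))
    A[f, , ] <- spec$amplitude * runif(1, 0.6, 1.0) * prof * in_tile
  }
  A
}

# noise is signal-proportional (shot-noise stylization): per-pixel sd =
# noise_sd * clean intensity, so noise_sd = 0.02 means "2% of signal"
mix_stack <- function(A, M, af_map, noise_sd) {
  nf <- dim(A)[1]; h <- dim(A)[2]; w <- dim(A)[3]
  nc <- nrow(M)
  Af <- matrix(A, nrow = nf)            # fluor x pixel
  S <- M %*% Af                         # channel x pixel
  S <- S + matrix(af_map, nrow = nc, ncol = h * w, byrow = TRUE)
  if (noise_sd > 0) {
    S <- S + matrix(rnorm(length(S), 0, noise_sd * as.vector(S)),
                    nrow = nc)
  }
  array(pmax(S, 0), dim = c(nc, h, w))
}

#' Simulate a multi-channel spectral stack with known ground truth
#'
#' Generates per-fluorophore abundance maps on disjoint spatial supports,
#' mixes them through the specified channels-by-fluorophores matrix, adds a
#' smooth autofluorescence field and Gaussian read noise (clipped at zero),
#' and emits one single-stain control stack per fluorophore (only that
#' fluorophore's abundance nonzero) plus an unstained autofluorescence
#' control.
#'
#' @param spec a [spectral_sim_spec()].
#' @return list with `stack` (channels x rows x cols array), `abundance`
#'   (fluors x rows x cols ground truth), `controls` (named list of control
#'   stacks), `autofluor_control`, `mixing` (the true matrix), `spec`.
#' @export
simulate_spectral_stack <- function(spec) {
  stopifnot(inherits(spec, "spectral_sim_spec"))
  with_seed(spec$seed, {
    h <- spec$image_shape[1]; w <- spec$image_shape[2]
    A <- abundance_maps(spec)
    # smooth-ish autofluorescence field, constant across channels
    af_map <- if (spec$autofluor_level > 0) {
      gx <- outer(seq_len(h) / h, rep(1, w))
      gy <- outer(rep(1, h), seq_len(w) / w)
      ph <- runif(2, 0, 2 * pi)
      spec$autofluor_level *
        (1 + 0.3 * sin(2 * pi * gx + ph[1]) * cos(2 * pi * gy + ph[2]))
    } else {
      matrix(0, h, w)
    }
    stack <- mix_stack(A, spec$mixing, af_map, spec$noise_sd)
    fl_names <- paste0("F", seq_len(spec$n_fluors))
    controls <- vector("list", spec$n_fluors)
    names(controls) <- fl_names
    for (f in seq_len(spec$n_fluors)) {
      Af <- array(0, dim = dim(A))
      Af[f, , ] <- A[f, , ]
      controls[[f]] <- mix_stack(Af, spec$mixing, af_map, spec$noise_sd)
    }
    af_control <- mix_stack(array(0, dim = dim(A)), spec$mixing, af_map,
                            spec$noise_sd)
    dimnames(A) <- list(fl_names, NULL, NULL)
    M <- spec$mixing
    dimnames(M) <- list(paste0("ch", seq_len(spec$n_channels)), fl_names)
    list(stack = stack, abundance = A, controls = controls,
         autofluor_control = af_control, mixing = M,
         home_channels = stats::setNames(spec$homes, fl_names), spec = spec)
  })
}

# ---------------------------------------------------------------------------
# Cohort simulation
# ---------------------------------------------------------------------------

default_intensity_params <- function(markers) {
  base <- list(neg_meanlog = log(80), neg_sdlog = 0.6,
               pos_meanlog = log(1200), pos_sdlog = 0.5)
  stats::setNames(rep(list(base), length(markers)), markers)
}

# typical immune positive-cell base rates in colorectal resections
default_base_fractions <- function(immune) {
  defaults <- c(CD3 = 0.15, CD8 = 0.08, CD45 = 0.30, CD45RO = 0.12,
                CD68 = 0.08, CD163 = 0.06, CD4 = 0.10, CD20 = 0.05,
                aSMA = 0.20, FOXP3 = 0.03, PD1 = 0.04, PDL1 = 0.05,
                CD31 = 0.06)
  out <- defaults[immune]
  out[is.na(out)] <- 0.08
  stats::setNames(as.numeric(out), immune)
}

#' Specification for a synthetic patient cohort
#'
#' Describes the stated world of the cohort generator: a rectangular tissue
#' with a spatially coherent tumor region, log-normal two-population marker
#' intensities, a specimen-level immune-infiltration latent that correlates
#' the immune markers, and progression-free survival drawn from an
#' exponential proportional-hazards model with independent administrative
#' censoring.
#'
#' @param n_specimens number of specimens (default 40, a typical
#'   retrospective resection cohort size).
#' @param cells_per_specimen segmented cells per specimen (`>= 100`).
#' @param markers character vector; first marker is treated as the tumor
#'   lineage marker (pan-cytokeratin), the rest as immune markers.
#' @param tumor_fraction fraction of tissue area occupied by tumor.
#' @param infiltration_effect named numeric vector of log-hazard
#'   coefficients, one per (immune) marker; names must be marker names.
#'   Markers not named get 0.
#' @param baseline_hazard events per day (default 1/730: median PFS of about
#'   two years).
#' @param censoring_rate expected fraction of specimens censored.
#' @param intensity_params named list per marker with `neg_meanlog`,
#'   `neg_sdlog`, `pos_meanlog`, `pos_sdlog` (log-normal mixture components;
#'   positive log-mean must exceed negative log-mean).
#' @param base_fractions named per-marker baseline positive fractions in
#'   (0, 1) for immune markers.
#' @param tissue_um `(width, height)` of the tissue rectangle in microns.
#' @param geometry `"blob"` (smoothed random field, realistic boundary
#'   curvature) or `"disk"` (analytic geometry for oracle tests).
#' @param effect_on `"indicator"` (default): hazard coefficients multiply
#'   the binary above/below-cohort-median indicator of the specimen positive
#'   fraction, so the planted group hazard ratio is `exp(coef)` exactly;
#'   `"fraction"`: coefficients multiply the fraction itself.
#' @param infiltration_sd sd of the specimen-level infiltration latent on
#'   the logit scale.
#' @param seed integer seed.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_specimens = 40, cells_per_specimen = 5000,
                            markers = c(default_panel()$tumor,
                                        default_panel()$immune),
                            tumor_fraction = 0.4,
                            infiltration_effect = NULL,
                            baseline_hazard = 1 / 730,
                            censoring_rate = 0.3,
                            intensity_params = NULL,
                            base_fractions = NULL,
                            tissue_um = c(5000, 5000),
                            geometry = c("blob", "disk"),
                            effect_on = c("indicator", "fraction"),
                            infiltration_sd = 0.8,
                            seed = 1) {
  geometry <- match.arg(geometry)
  effect_on <- match.arg(effect_on)
  if (cells_per_specimen < 100) {
    stop("cells_per_specimen must be >= 100 (downstream medians unstable)")
  }
  stopifnot(n_specimens >= 2, tumor_fraction > 0, tumor_fraction < 1,
            baseline_hazard > 0, censoring_rate >= 0, censoring_rate < 1)
  immune <- markers[-1]
  eff <- stats::setNames(numeric(length(immune)), immune)
  if (!is.null(infiltration_effect)) {
    bad <- setdiff(names(infiltration_effect), immune)
    if (length(bad)) stop("infiltration_effect names unknown: ",
                          paste(bad, collapse = ", "))
    eff[names(infiltration_effect)] <- infiltration_effect
  }
  if (is.null(intensity_params)) {
    intensity_params <- default_intensity_params(markers)
  }
  for (m in markers) {
    p <- intensity_params[[m]]
    if (is.null(p)) stop("intensity_params missing marker ", m)
    if (p$pos_meanlog <= p$neg_meanlog) {
      stop("positive log-mean must exceed negative log-mean for ", m)
    }
  }
  if (is.null(base_fractions)) base_fractions <- default_base_fractions(immune)
  stopifnot(all(base_fractions > 0), all(base_fractions < 1))
  structure(list(n_specimens = as.integer(n_specimens),
                 cells_per_specimen = as.integer(cells_per_specimen),
                 markers = markers, tumor_marker = markers[1],
                 immune_markers = immune, tumor_fraction = tumor_fraction,
                 infiltration_effect = eff, baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 intensity_params = intensity_params,
                 base_fractions = base_fractions,
                 tissue_um = tissue_um, geometry = geometry,
                 effect_on = effect_on, infiltration_sd = infiltration_sd,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

# scalar field whose upper quantile set forms the tumor blob
blob_field <- function(x, y, tissue_um, n_centers = 12) {
  sigma <- 0.22 * min(tissue_um)
  cx <- runif(n_centers, 0, tissue_um[1])
  cy <- runif(n_centers, 0, tissue_um[2])
  wt <- runif(n_centers, 0.5, 1)
  f <- numeric(length(x))
  for (j in seq_len(n_centers)) {
    f <- f + wt[j] * exp(-((x - cx[j])^2 + (y - cy[j])^2) / (2 * sigma^2))
  }
  f
}

#' Simulate a synthetic patient cohort
#'
#' Each specimen is a rectangular tissue with uniformly placed cells and a
#' connected tumor region (disk or smoothed random blob) covering
#' `tumor_fraction` of the cells. The tumor lineage marker is positive with
#' probability 0.9 inside the tumor and 0.02 outside; each immune marker's
#' per-specimen positive fraction is drawn around a specimen-level
#' infiltration latent (logit-normal) and applied uniformly in space.
#' Intensities are two-component log-normal mixtures given the positivity
#' call. Progression-free survival is exponential with linear predictor
#' `sum(coef * covariate)` (covariate per `effect_on`), censored by an
#' independent uniform administrative close-out calibrated to
#' `censoring_rate`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return list with `cells` (one data.frame, all specimens; columns
#'   `specimen_id`, `cell_id`, `x_um`, `y_um`, one intensity column per
#'   marker, `truth_tumor`, and `truth_call_<marker>`), `clinical`
#'   (`specimen_id`, `pfs_days`, `event`), and `truth` (per-specimen planted
#'   positive-fraction parameters, realized fractions, hazard covariates and
#'   linear predictors).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_specimens; nc <- spec$cells_per_specimen
    ids <- sprintf("S%03d", seq_len(ns))
    immune <- spec$immune_markers
    u <- rnorm(ns, 0, 1)  # infiltration latent
    # per-specimen, per-marker positive-fraction parameters
    p_param <- matrix(0, ns, length(immune),
                      dimnames = list(ids, immune))
    for (m in immune) {
      p_param[, m] <- plogis(qlogis(spec$base_fractions[[m]]) +
                               spec$infiltration_sd * u +
                               rnorm(ns, 0, 0.3))
    }
    cells_list <- vector("list", ns)
    realized <- matrix(NA_real_, ns, length(spec$markers),
                       dimnames = list(ids, spec$markers))
    for (s in seq_len(ns)) {
      x <- runif(nc, 0, spec$tissue_um[1])
      y <- runif(nc, 0, spec$tissue_um[2])
      if (spec$geometry == "disk") {
        cx <- spec$tissue_um[1] / 2; cy <- spec$tissue_um[2] / 2
        R <- sqrt(spec$tumor_fraction * prod(spec$tissue_um) / pi)
        tumor <- (x - cx)^2 + (y - cy)^2 <= R^2
      } else {
        f <- blob_field(x, y, spec$tissue_um)
        tumor <- f >= quantile(f, 1 - spec$tumor_fraction)
      }
      calls <- matrix(FALSE, nc, length(spec$markers),
                      dimnames = list(NULL, spec$markers))
      calls[, spec$tumor_marker] <-
        runif(nc) < ifelse(tumor, 0.9, 0.02)
      for (m in immune) calls[, m] <- runif(nc) < p_param[s, m]
      inten <- matrix(0, nc, length(spec$markers),
                      dimnames = list(NULL, spec$markers))
      for (m in spec$markers) {
        ip <- spec$intensity_params[[m]]
        pos <- calls[, m]
        inten[!pos, m] <- rlnorm(sum(!pos), ip$neg_meanlog, ip$neg_sdlog)
        inten[pos, m] <- rlnorm(sum(pos), ip$pos_meanlog, ip$pos_sdlog)
      }
      realized[s, ] <- colMeans(calls)
      df <- data.frame(specimen_id = ids[s], cell_id = seq_len(nc),
                       x_um = x, y_um = y, check.names = FALSE)
      df <- cbind(df, as.data.frame(inten))
      df$truth_tumor <- tumor
      calls_df <- as.data.frame(calls)
      names(calls_df) <- paste0("truth_call_", spec$markers)
      cells_list[[s]] <- cbind(df, calls_df)
    }
    cells <- do.call(rbind, cells_list)
    rownames(cells) <- NULL
    # survival linkage
    frac <- realized[, immune, drop = FALSE]
    z <- switch(spec$effect_on,
      indicator = {
        med <- apply(frac, 2, median)
        sweep(frac, 2, med, ">") * 1
      },
      fraction = frac)
    eta <- as.numeric(z %*% spec$infiltration_effect[immune])
    lambda <- spec$baseline_hazard * exp(eta)
    t_event <- rexp(ns, rate = lambda)
    if (spec$censoring_rate > 0) {
      g <- function(xx) (1 - exp(-xx)) / xx - spec$censoring_rate
      xx <- uniroot(g, c(1e-8, 1e6))$root
      tau <- xx / spec$baseline_hazard
      t_cens <- runif(ns, 0, tau)
    } else {
      t_cens <- rep(Inf, ns)
    }
    pfs <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    clinical <- data.frame(specimen_id = ids,
                           pfs_days = pfs, event = event)
    list(cells = cells, clinical = clinical,
         truth = list(infiltration_latent = stats::setNames(u, ids),
                      planted_fraction = p_param,
                      realized_fraction = realized,
                      hazard_covariate = z, linear_predictor = eta,
                      infiltration_effect = spec$infiltration_effect),
         spec = spec)
  })
}

#' Simulate a two-arm exponential survival study
#'
#' Minimal generator for hazard-ratio recovery oracles: arm `"b"` has the
#' baseline hazard, arm `"a"` has hazard `hr * baseline`.
#'
#' @param n_per_arm subjects per arm.
#' @param hr true hazard ratio of arm a vs arm b.
#' @param baseline_hazard events per day in arm b.
#' @param censoring_rate expected censored fraction (uniform administrative).
#' @param seed integer seed.
#' @return data.frame with `time`, `event`, `group` (factor a/b).
#' @export
simulate_two_arm <- function(n_per_arm, hr = 0.2, baseline_hazard = 1 / 500,
                             censoring_rate = 0, seed = 1) {
  stopifnot(n_per_arm >= 1, hr > 0, baseline_hazard > 0)
  with_seed(seed, {
    lam <- c(rep(hr * baseline_hazard, n_per_arm),
             rep(baseline_hazard, n_per_arm))
    t_event <- rexp(2 * n_per_arm, lam)
    if (censoring_rate > 0) {
      g <- function(xx) (1 - exp(-xx)) / xx - censoring_rate
      tau <- uniroot(g, c(1e-8, 1e6))$root / baseline_hazard
      t_cens <- runif(2 * n_per_arm, 0, tau)
    } else {
      t_cens <- rep(Inf, 2 * n_per_arm)
    }
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               group = factor(rep(c("a", "b"), each = n_per_arm)))
  })
}

#' Simulate a corpus with planted topics
#'
#' Generates documents (marker-count vectors) from an LDA model whose planted
#' topics have disjoint two-word supports, for topic-recovery and
#' topic-number-selection oracles.
#'
#' @param n_docs number of documents.
#' @param K number of planted topics.
#' @param words_per_topic vocabulary words owned by each topic (disjoint).
#' @param doc_length mean tokens per document (Poisson).
#' @param alpha Dirichlet concentration of document-topic weights.
#' @param seed integer seed.
#' @return list with `docs` (docs x vocab count matrix), `phi` (planted
#'   K x vocab topic-word matrix), `theta` (planted doc-topic weights).
#' @export
simulate_topic_corpus <- function(n_docs, K, words_per_topic = 2,
                                  doc_length = 50, alpha = 0.3, seed = 1) {
  stopifnot(n_docs >= 1, K >= 2, words_per_topic >= 1)
  with_seed(seed, {
    V <- K * words_per_topic
    vocab <- paste0("w", seq_len(V))
    phi <- matrix(0, K, V, dimnames = list(paste0("topic", seq_len(K)), vocab))
    for (k in seq_len(K)) {
      idx <- ((k - 1) * words_per_topic + 1):(k * words_per_topic)
      w <- runif(words_per_topic, 0.5, 1)
      phi[k, idx] <- w / sum(w)
    }
    # Dirichlet(alpha) via gammas
    theta <- matrix(stats::rgamma(n_docs * K, shape = alpha), n_docs, K)
    theta <- theta / rowSums(theta)
    docs <- matrix(0L, n_docs, V, dimnames = list(NULL, vocab))
    len <- rpois(n_docs, doc_length)
    probs <- theta %*% phi
    for (d in seq_len(n_docs)) {
      if (len[d] > 0) {
        docs[d, ] <- as.integer(stats::rmultinom(1, len[d], probs[d, ]))
      }
    }
    list(docs = docs, phi = phi, theta = theta)
  })
}
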