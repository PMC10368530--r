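# Per-marker positive/negative gating by a two-component Gaussian mixture on
# log1p intensities, plus rule-dendrogram cell type calling.

# 1-D two-component EM, deterministic given the seed (quantile-anchored
# starts plus seeded jittered restarts; best likelihood wins).
gmm2_em <- function(z, n_restarts = 10, seed = 1, max_iter = 200,
                    tol = 1e-8) {
  n <- length(z)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      q <- if (r == 1) c(0.25, 0.75) else sort(runif(2, 0.05, 0.95))
      mu <- as.numeric(quantile(z, q))
      if (diff(mu) < 1e-8) mu <- mu + c(-1, 1) * sd(z) / 10
      s <- rep(max(sd(z) / 2, 1e-6), 2)
      w <- c(0.5, 0.5)
      ll_old <- -Inf
      for (it in seq_len(max_iter)) {
        d1 <- w[1] * dnorm(z, mu[1], s[1])
        d2 <- w[2] * dnorm(z, mu[2], s[2])
        tot <- d1 + d2
        tot[tot == 0] <- .Machine$double.xmin
        g <- d2 / tot
        ll <- sum(log(tot))
        if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
        ll_old <- ll
        w2 <- mean(g); w1 <- 1 - w2
        mu <- c(sum((1 - g) * z) / sum(1 - g), sum(g * z) / sum(g))
        s <- sqrt(c(sum((1 - g) * (z - mu[1])^2) / sum(1 - g),
                    sum(g * (z - mu[2])^2) / sum(g)))
        s <- pmax(s, 1e-6)
        w <- c(w1, w2)
      }
      # order components by mean
      if (mu[1] > mu[2]) { mu <- rev(mu); s <- rev(s); w <- rev(w) }
      fit <- list(mu = mu, sd = s, w = w, loglik = ll_old)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  best
}

# posterior-equality point between the two component means
gmm_threshold <- function(fit) {
  f <- function(x) {
    log(fit$w[2]) + dnorm(x, fit$mu[2], fit$sd[2], log = TRUE) -
      log(fit$w[1]) - dnorm(x, fit$mu[1], fit$sd[1], log = TRUE)
  }
  lo <- fit$mu[1]; hi <- fit$mu[2]
  flo <- f(lo); fhi <- f(hi)
  if (is.finite(flo) && is.finite(fhi) && flo < 0 && fhi > 0) {
    uniroot(f, c(lo, hi))$root
  } else {
    mean(c(lo, hi))  # posteriors never cross between the means
  }
}

#' Gate one marker by a two-component Gaussian mixture
#'
#' Fits a two-component Gaussian mixture to `log1p` intensities and calls a
#' cell positive when its intensity exceeds the point between the component
#' means where the posteriors are equal. A fit where either component
#' carries less than `min_weight` of the cells (or the data are degenerate)
#' falls back to an all-negative call with a warning flag.
#'
#' @param intensities nonnegative per-cell vector (`>= 100` cells).
#' @param marker marker name (annotation only).
#' @param specimen specimen id (annotation only).
#' @param seed seed for EM restarts; results are deterministic given it.
#' @param n_restarts random EM restarts (best likelihood wins).
#' @param min_weight minimum admissible component weight.
#' @return object of class `gate_result`: list with `marker`, `specimen`,
#'   `threshold` (log1p scale), `threshold_intensity` (raw scale),
#'   `positive_fraction`, `s_to_b` (ratio of mean positive to mean negative
#'   raw intensity), `calls` (logical vector), `degenerate` flag, `fit`.
#' @export
gmm_gate <- function(intensities, marker = "marker", specimen = NA_character_,
                     seed = 1, n_restarts = 10, min_weight = 0.01) {
  if (length(intensities) < 100) stop("gating requires >= 100 cells")
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  z <- log1p(intensities)
  degen <- function(msg) {
    warning(sprintf("degenerate gate for %s/%s: %s", marker, specimen, msg),
            call. = FALSE)
    structure(list(marker = marker, specimen = specimen,
                   threshold = NA_real_, threshold_intensity = NA_real_,
                   positive_fraction = 0, s_to_b = NA_real_,
                   calls = rep(FALSE, length(z)), degenerate = TRUE,
                   fit = NULL),
              class = "gate_result")
  }
  if (sd(z) < 1e-10) return(degen("constant intensities"))
  fit <- gmm2_em(z, n_restarts = n_restarts, seed = seed)
  if (min(fit$w) < min_weight || diff(fit$mu) < 1e-6) {
    return(degen(sprintf("component weight %.3f below %.3f",
                         min(fit$w), min_weight)))
  }
  thr <- gmm_threshold(fit)
  calls <- z > thr
  s_to_b <- if (any(calls) && any(!calls)) {
    mean(intensities[calls]) / mean(intensities[!calls])
  } else {
    NA_real_
  }
  structure(list(marker = marker, specimen = specimen, threshold = thr,
                 threshold_intensity = expm1(thr),
                 positive_fraction = mean(calls), s_to_b = s_to_b,
                 calls = calls, degenerate = FALSE, fit = fit),
            class = "gate_result")
}

#' Gate every marker in a cell table
#'
#' @param cells cell table (see [read_cell_table()]).
#' @param markers marker columns to gate (defaults to every non-reserved
#'   numeric column without a `truth_` prefix).
#' @param per_specimen gate each specimen separately (default; staining
#'   varies specimen to specimen) or pool the cohort.
#' @param seed seed forwarded to [gmm_gate()].
#' @return list with `calls` (logical cells x markers matrix, columns named
#'   `<marker>`), `summary` data.frame (specimen, marker, threshold,
#'   positive_fraction, s_to_b, degenerate).
#' @export
gate_cell_table <- function(cells, markers = NULL, per_specimen = TRUE,
                            seed = 1) {
  assert_cols(cells, c("specimen_id", "cell_id", "x_um", "y_um"),
              "cell table")
  if (is.null(markers)) {
    reserved <- c("specimen_id", "cell_id", "x_um", "y_um", "compartment")
    markers <- setdiff(names(cells)[vapply(cells, is.numeric, TRUE)],
                       c(reserved, "cell_id"))
    markers <- markers[!startsWith(markers, "truth_")]
  }
  calls <- matrix(FALSE, nrow(cells), length(markers),
                  dimnames = list(NULL, markers))
  rows <- list()
  groups <- if (per_specimen) split(seq_len(nrow(cells)), cells$specimen_id)
            else list(all = seq_len(nrow(cells)))
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (m in markers) {
      gr <- gmm_gate(cells[[m]][idx], marker = m, specimen = g, seed = seed)
      calls[idx, m] <- gr$calls
      rows[[length(rows) + 1]] <-
        data.frame(specimen = g, marker = m, threshold = gr$threshold,
                   positive_fraction = gr$positive_fraction,
                   s_to_b = gr$s_to_b, degenerate = gr$degenerate)
    }
  }
  list(calls = calls, summary = do.call(rbind, rows))
}

# ---------------------------------------------------------------------------
# Lineage dendrogram
# ---------------------------------------------------------------------------

#' Default lineage-calling dendrogram for a colorectal panel
#'
#' Ordered rules evaluated depth-first; the first rule whose positive and
#' negative marker requirements are met assigns the label. Cells matching no
#' rule are `Unassigned`.
#'
#' @return list of rules, each `list(label, pos, neg)`.
#' @export
default_dendrogram <- function() {
  list(
    list(label = "Tumor",        pos = "panCK",            neg = "CD45"),
    list(label = "B cell",       pos = c("CD45", "CD20"),  neg = character()),
    list(label = "T cell FOXP3", pos = c("CD45", "CD3", "FOXP3"),
         neg = character()),
    list(label = "T cell CD8",   pos = c("CD45", "CD3", "CD8"), neg = "CD4"),
    list(label = "T cell CD4",   pos = c("CD45", "CD3", "CD4"), neg = "CD8"),
    list(label = "T cell other", pos = c("CD45", "CD3"),   neg = character()),
    list(label = "Macrophage",   pos = "CD68",             neg = character()),
    list(label = "Macrophage M2", pos = "CD163",           neg = character()),
    list(label = "Other immune", pos = "CD45",             neg = character()),
    list(label = "Endothelial",  pos = "CD31",             neg = character()),
    list(label = "Stromal",      pos = "aSMA",             neg = character())
  )
}

#' Call cell types from per-marker gates via a rule dendrogram
#'
#' @param calls logical cells x markers matrix of gate calls.
#' @param dendrogram rule list as in [default_dendrogram()]; every marker a
#'   rule references must be a column of `calls`.
#' @param specimen_id optional per-cell specimen ids for the per-specimen
#'   unassigned fractions.
#' @return object of class `cell_type_call`: list with `label` (character
#'   vector, `"Unassigned"` for cells matching no rule),
#'   `unassigned_fraction` (overall), `per_specimen` data.frame.
#' @export
call_cell_types <- function(calls, dendrogram = default_dendrogram(),
                            specimen_id = NULL) {
  used <- unique(unlist(lapply(dendrogram, function(r) c(r$pos, r$neg))))
  missing <- setdiff(used, colnames(calls))
  if (length(missing)) {
    stop("dendrogram references ungated marker(s): ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(calls)
  label <- rep("Unassigned", n)
  open <- rep(TRUE, n)
  for (r in dendrogram) {
    hit <- open
    for (m in r$pos) hit <- hit & calls[, m]
    for (m in r$neg) hit <- hit & !calls[, m]
    label[hit] <- r$label
    open <- open & !hit
  }
  per_spec <- NULL
  if (!is.null(specimen_id)) {
    per_spec <- do.call(rbind, lapply(split(label, specimen_id), function(l) {
      data.frame(unassigned_fraction = mean(l == "Unassigned"))
    }))
    per_spec <- data.frame(specimen_id = rownames(per_spec),
                           unassigned_fraction = per_spec$unassigned_fraction,
                           row.names = NULL)
  }
  structure(list(label = label,
                 unassigned_fraction = mean(label == "Unassigned"),
                 per_specimen = per_spec),
            class = "cell_type_call")
}
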