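# Kaplan-Meier estimation, the log-rank test, and the O/E hazard ratio
# HR = (Oa/Ea)/(Ob/Eb) with CI exp(ln HR +/- 1.96 sqrt(1/Ea + 1/Eb)),
# plus leave-one-out and bootstrap model-comparison machinery with
# Benjamini-Hochberg adjustment.

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators (0 = right-censored).
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival` (non-increasing,
#'   right-continuous step function; survival before the first event time
#'   is 1).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0) stop("empty input")
  if (any(times <= 0)) stop("times must be positive")
  events <- as.integer(events)
  stopifnot(all(events %in% c(0L, 1L)))
  ut <- sort(unique(times))
  n <- length(times)
  out <- data.frame(time = ut, n_risk = NA_integer_, n_event = NA_integer_,
                    n_censor = NA_integer_)
  surv <- 1
  svec <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1L)
    c <- sum(times == ut[i] & events == 0L)
    out$n_risk[i] <- at_risk
    out$n_event[i] <- d
    out$n_censor[i] <- c
    if (d > 0) surv <- surv * (1 - d / at_risk)
    svec[i] <- surv
  }
  out$survival <- svec
  out
}

# Internal fast log-rank O/E machinery. `prep` sorts once; `oe` evaluates a
# group split against it, so the exhaustive model search can reuse the sort.
logrank_prep <- function(times, events) {
  o <- order(times)
  list(times = times[o], events = as.integer(events[o]), order = o,
       ut = sort(unique(times[events == 1])))
}

logrank_oe <- function(prep, in_a) {
  # in_a: logical in the *original* order
  a <- in_a[prep$order]
  t <- prep$times; ev <- prep$events
  Oa <- 0; Ea <- 0; V <- 0; Ob <- 0; Eb <- 0
  for (u in prep$ut) {
    at <- t >= u
    n <- sum(at)
    na <- sum(at & a)
    d <- sum(t == u & ev == 1L)
    da <- sum(t == u & ev == 1L & a)
    Oa <- Oa + da
    Ob <- Ob + (d - da)
    Ea <- Ea + d * na / n
    Eb <- Eb + d * (n - na) / n
    if (n > 1) V <- V + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  c(Oa = Oa, Ob = Ob, Ea = Ea, Eb = Eb, V = V)
}

#' Two-group log-rank test with O/E hazard ratio
#'
#' Observed and expected events come from the standard log-rank 2xK table
#' sums; the hazard ratio is `(Oa/Ea)/(Ob/Eb)` with confidence interval
#' `exp(ln HR +/- 1.96 sqrt(1/Ea + 1/Eb))` and p-value from the chi-square
#' log-rank statistic on 1 df.
#'
#' @param times,events as in [km_estimate()].
#' @param group two-level factor (or coercible); the first level is group
#'   "a", so `hr < 1` means group a progresses more slowly.
#' @return object of class `survival_comparison`: list with `Oa`, `Ob`,
#'   `Ea`, `Eb`, `hr`, `ci_low`, `ci_high`, `chi2`, `p`, `n_a`, `n_b`,
#'   `flag` (`"ok"`, or `"event_free_group"` when a group has no events and
#'   the HR is only a bound).
#' @export
logrank_hr <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  stopifnot(length(times) == length(events), length(group) == length(times))
  prep <- logrank_prep(times, events)
  in_a <- group == levels(group)[1]
  s <- logrank_oe(prep, in_a)
  chi2 <- if (s["V"] > 0) (s["Oa"] - s["Ea"])^2 / s["V"] else 0
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  flag <- "ok"
  if (s["Oa"] == 0 || s["Ob"] == 0) flag <- "event_free_group"
  hr <- if (s["Ea"] > 0 && s["Eb"] > 0 && s["Ob"] > 0) {
    (s["Oa"] / s["Ea"]) / (s["Ob"] / s["Eb"])
  } else {
    NA_real_
  }
  se <- sqrt(1 / s["Ea"] + 1 / s["Eb"])
  ci <- if (!is.na(hr) && hr > 0) exp(log(hr) + c(-1, 1) * 1.96 * se)
        else c(NA_real_, NA_real_)
  structure(list(Oa = unname(s["Oa"]), Ob = unname(s["Ob"]),
                 Ea = unname(s["Ea"]), Eb = unname(s["Eb"]),
                 hr = unname(hr), ci_low = unname(ci[1]),
                 ci_high = unname(ci[2]), chi2 = unname(chi2),
                 p = unname(p), n_a = sum(in_a), n_b = sum(!in_a),
                 groups = levels(group), flag = flag),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("log-rank: HR (%s vs %s) = %.3f [%.3f, %.3f], chi2 = %.2f, p = %.3g\n",
              x$groups[1], x$groups[2], x$hr, x$ci_low, x$ci_high, x$chi2,
              x$p))
  cat(sprintf("O/E: %g/%.2f vs %g/%.2f (n = %d vs %d)%s\n", x$Oa, x$Ea,
              x$Ob, x$Eb, x$n_a, x$n_b,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up procedure: adjusted p(i) = min over j >= i of
#' m p(j) / j (on the sorted scale), capped at 1.
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @param fdr false discovery rate for the rejection set (default 0.1).
#' @return list with `adjusted` (same order as input) and `rejected`
#'   (logical: adjusted p <= fdr).
#' @export
bh_adjust <- function(pvalues, fdr = 0.1) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  m <- length(pvalues)
  o <- order(pvalues)
  ranked <- pvalues[o] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(ranked)))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, rejected = adjusted <= fdr)
}

#' Leave-one-out comparison of two candidate models' ranks
#'
#' For each left-out specimen the full score-and-rank pipeline is re-run on
#' the remaining cohort (medians recomputed, every candidate re-ranked) and
#' the two models' ranks are collected; a paired t-test compares the rank
#' vectors, with Benjamini-Hochberg adjustment across the tests supplied in
#' `extra_p` (the adjustment of a single p against itself leaves it
#' unchanged).
#'
#' @param defs candidate definition list (see [enumerate_ifms()]).
#' @param stats region-fraction table (see [region_fractions()]).
#' @param clinical clinical table (`specimen_id`, `pfs_days`, `event`).
#' @param model_a,model_b definition ids to track.
#' @param fdr FDR for the BH adjustment (default 0.1).
#' @param extra_p optional other p-values entering the BH family.
#' @return object of class `comparison_study`: list with `mode = "loo"`,
#'   `ranks` (data.frame resample x both models), `paired_p`, `adjusted_p`,
#'   `dropped` (resamples without a defined rank).
#' @export
loo_compare <- function(defs, stats, clinical, model_a, model_b, fdr = 0.1,
                        extra_p = numeric(0)) {
  specs <- clinical$specimen_id
  if (length(specs) < 3) stop("cohort must have >= 3 specimens")
  ra <- rb <- rep(NA_real_, length(specs))
  for (i in seq_along(specs)) {
    cl <- clinical[clinical$specimen_id != specs[i], ]
    st <- stats[stats$specimen != specs[i], ]
    rk <- score_and_rank(defs, st, cl)$table
    ra[i] <- rk$rank[match(model_a, rk$id)]
    rb[i] <- rk$rank[match(model_b, rk$id)]
  }
  ok <- !is.na(ra) & !is.na(rb)
  dropped <- sum(!ok)
  paired_p <- if (all(ra[ok] == rb[ok])) {
    1
  } else {
    t.test(ra[ok], rb[ok], paired = TRUE)$p.value
  }
  adj <- bh_adjust(c(paired_p, extra_p), fdr = fdr)
  structure(list(mode = "loo", n_resamples = length(specs),
                 ranks = data.frame(left_out = specs, rank_a = ra,
                                    rank_b = rb),
                 paired_p = paired_p, adjusted_p = adj$adjusted[1],
                 fdr = fdr, dropped = dropped),
            class = "comparison_study")
}

#' Bootstrap comparison of two candidate models' hazard ratios
#'
#' Resamples specimens with replacement at the original cohort size,
#' recomputes each model's score medians, classes, and O/E hazard ratio per
#' resample, and compares the paired HR vectors with a t-test plus
#' Benjamini-Hochberg adjustment. Resamples where either model's class
#' split is degenerate are dropped and counted.
#'
#' @param def_a,def_b model definitions (parameter data.frames as produced
#'   by [enumerate_ifms()], or definition ids resolvable in `defs`).
#' @param stats,clinical as in [loo_compare()].
#' @param n_resamples bootstrap draws (default 500).
#' @param seed integer seed.
#' @param fdr,extra_p as in [loo_compare()].
#' @return object of class `comparison_study` with `mode = "bootstrap"`,
#'   `hrs` (retained resample HRs for both models), `paired_p`,
#'   `adjusted_p`, `dropped`.
#' @export
bootstrap_compare <- function(def_a, def_b, stats, clinical,
                              n_resamples = 500, seed = 1, fdr = 0.1,
                              extra_p = numeric(0)) {
  specs <- clinical$specimen_id
  if (length(specs) < 10) stop("cohort must have >= 10 specimens")
  wide <- stats_to_wide(stats)
  ha <- hb <- rep(NA_real_, n_resamples)
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      idx <- sample(seq_along(specs), replace = TRUE)
      cl <- clinical[idx, ]
      w <- wide[match(cl$specimen_id, rownames(wide)), , drop = FALSE]
      ha[r] <- boot_model_hr(def_a, w, cl)
      hb[r] <- boot_model_hr(def_b, w, cl)
    }
  })
  ok <- is.finite(ha) & is.finite(hb)
  dropped <- sum(!ok)
  paired_p <- if (all(ha[ok] == hb[ok])) {
    1
  } else {
    t.test(ha[ok], hb[ok], paired = TRUE)$p.value
  }
  adj <- bh_adjust(c(paired_p, extra_p), fdr = fdr)
  structure(list(mode = "bootstrap", n_resamples = n_resamples,
                 n_retained = sum(ok),
                 hrs = data.frame(hr_a = ha[ok], hr_b = hb[ok]),
                 paired_p = paired_p, adjusted_p = adj$adjusted[1],
                 fdr = fdr, dropped = dropped),
            class = "comparison_study")
}

# HR of one model on a (possibly resampled) wide fraction matrix + clinical
boot_model_hr <- function(def, wide, clinical) {
  sc <- ifm_score_matrix(def, wide)
  cls <- sc$class
  if (length(unique(cls)) < 2) return(NA_real_)
  cmp <- logrank_hr(clinical$pfs_days, clinical$event,
                    factor(cls, levels = c("high", "low")))
  if (cmp$flag != "ok") return(NA_real_)
  cmp$hr
}
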