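# Image feature models (IFMs): Immunoscore-style median-split scores over
# (marker, region) positive-fraction parameters, the exhaustive 4-of-26
# combination search ranked by hazard ratio, GSEA-style marker enrichment
# over the ranking, the topic-fraction model (IFM3), and the composite
# (IFM4).

param_id <- function(marker, region) paste0(marker, "@", region)

split_param <- function(p) {
  parts <- strsplit(p, "@", fixed = TRUE)
  data.frame(marker = vapply(parts, `[`, "", 1),
             region = vapply(parts, `[`, "", 2))
}

#' Enumerate all 4-parameter model definitions
#'
#' Every choice of 4 distinct (marker, region) parameters, canonically
#' ordered with no duplicates. With 13 markers and the two scoring regions
#' this is C(26, 4) = 14,950 definitions.
#'
#' @param markers marker names (default: the 13 immune markers of
#'   [default_panel()]).
#' @param regions scoring regions (default `c("CT", "IM")`).
#' @param size parameters per model (default 4).
#' @return object of class `ifm_definitions`: list with `params`
#'   (definitions x size character matrix of `marker@region` ids), `id`
#'   (canonical definition strings), `all_params`.
#' @export
enumerate_ifms <- function(markers = default_panel()$immune,
                           regions = c("CT", "IM"), size = 4) {
  all_params <- sort(as.vector(outer(markers, regions, param_id)))
  if (length(all_params) < size) {
    stop("fewer parameters than the model size")
  }
  combos <- t(combn(all_params, size))
  structure(list(params = combos,
                 id = apply(combos, 1, paste, collapse = "+"),
                 all_params = all_params, markers = markers,
                 regions = regions, size = size),
            class = "ifm_definitions")
}

#' The published IFM2 composition as a named preset
#'
#' Alpha-smooth-muscle-actin positive fraction in the tumor center plus
#' CD45, PD-L1 and CD4 positive fractions in the invasive margin, so the
#' model can be scored directly without re-running the search.
#'
#' @return character vector of 4 `marker@region` parameter ids.
#' @export
ifm2_preset <- function() {
  sort(c(param_id("aSMA", "CT"), param_id("CD45", "IM"),
         param_id("PDL1", "IM"), param_id("CD4", "IM")))
}

#' Reshape a region-fraction table to specimens x parameters
#'
#' @param stats data.frame from [region_fractions()].
#' @return numeric matrix, rows = specimens, columns = `marker@region`.
#' @export
stats_to_wide <- function(stats) {
  assert_cols(stats, c("specimen", "marker", "region", "positive_fraction"),
              "region stats")
  specs <- unique(stats$specimen)
  params <- sort(unique(param_id(stats$marker, stats$region)))
  wide <- matrix(NA_real_, length(specs), length(params),
                 dimnames = list(specs, params))
  wide[cbind(match(stats$specimen, specs),
             match(param_id(stats$marker, stats$region), params))] <-
    stats$positive_fraction
  wide
}

# Median-split scoring of one definition on a wide fraction matrix.
# Ties at the median score 0 (strict "above" scores 1). Missing fractions
# give a missing subscore and a flagged total.
ifm_score_matrix <- function(params, wide, medians = NULL) {
  params <- sort(params)
  miss <- setdiff(params, colnames(wide))
  if (length(miss)) stop("parameters absent from stats: ",
                         paste(miss, collapse = ", "))
  sub <- wide[, params, drop = FALSE]
  if (is.null(medians)) {
    medians <- apply(sub, 2, median, na.rm = TRUE)
  } else if (!is.null(names(medians))) {
    if (!all(params %in% names(medians))) {
      stop("frozen medians missing parameter(s): ",
           paste(setdiff(params, names(medians)), collapse = ", "))
    }
    medians <- medians[params]
  }
  subscore <- sweep(sub, 2, medians, ">") * 1
  total <- rowSums(subscore)
  cls <- ifelse(is.na(total), NA_character_,
                ifelse(total >= 3, "high", "low"))
  list(params = params, medians = medians, subscores = subscore,
       total = total, class = cls, flagged = is.na(total))
}

#' Compute the Immunoscore-like IFM1
#'
#' CD3 and CD8 positive fractions in the tumor center and the invasive
#' margin; the cohort median of each of the four parameters is the cutoff
#' (a fraction strictly above the median scores 1, at or below scores 0);
#' the specimen's score is the sum of the four subscores (0-4) and the
#' binary class is low (score <= 2) vs high (score 3 or 4).
#'
#' @param stats region-fraction table (see [region_fractions()]) covering
#'   the model's markers in CT and IM for at least 3 specimens.
#' @param clinical optional clinical table; when given, the high-vs-low
#'   log-rank hazard ratio is attached.
#' @param markers the two markers (default CD3, CD8).
#' @param medians optional frozen parameter medians (transfer mode: apply a
#'   trained cohort's cutoffs without refitting).
#' @return object of class `ifm_result`: list with `id`, `params`,
#'   `medians`, `scores` (data.frame specimen, subscores, total, class),
#'   `hr` (a `survival_comparison` or NULL).
#' @export
compute_ifm1 <- function(stats, clinical = NULL, markers = c("CD3", "CD8"),
                         medians = NULL) {
  params <- sort(as.vector(outer(markers, c("CT", "IM"), param_id)))
  wide <- stats_to_wide(stats)
  if (sum(stats::complete.cases(wide[, intersect(params, colnames(wide)),
                                     drop = FALSE])) < 3) {
    stop("need fractions for all parameters in at least 3 specimens")
  }
  sc <- ifm_score_matrix(params, wide, medians = medians)
  scores <- data.frame(specimen = rownames(wide), sc$subscores,
                       total = sc$total, class = sc$class,
                       check.names = FALSE, row.names = NULL)
  hr <- NULL
  if (!is.null(clinical)) {
    hr <- class_hr(sc$class, rownames(wide), clinical)
  }
  structure(list(id = paste(params, collapse = "+"), params = params,
                 medians = sc$medians, scores = scores, hr = hr),
            class = "ifm_result")
}

# high-vs-low log-rank comparison for a named class vector
class_hr <- function(cls, specimens, clinical) {
  m <- match(clinical$specimen_id, specimens)
  cc <- cls[m]
  ok <- !is.na(cc)
  if (length(unique(cc[ok])) < 2) return(NULL)
  logrank_hr(clinical$pfs_days[ok], clinical$event[ok],
             factor(cc[ok], levels = c("high", "low")))
}

#' Score and rank every candidate model by hazard ratio
#'
#' Each definition is scored exactly as [compute_ifm1()] generalized to its
#' four parameters (cohort medians as cutoffs, low = score <= 2, high =
#' score >= 3), the high-vs-low O/E hazard ratio is computed, and models
#' are ranked by ascending HR (equivalently descending 1/HR). Ties break by
#' smaller log-rank p, then canonical id. Models with a degenerate class
#' split, an event-free class, or a non-finite HR are flagged and excluded
#' from the ranking.
#'
#' @param defs an `ifm_definitions` object (or character matrix of
#'   parameter ids).
#' @param stats region-fraction table.
#' @param clinical clinical table (`specimen_id`, `pfs_days`, `event`).
#' @param medians optional frozen parameter medians (transfer mode).
#' @return object of class `ifm_ranking`: list with `table` (data.frame
#'   id, hr, ci_low, ci_high, p, flag, rank — `NA` rank when excluded),
#'   `defs`, `medians`, `n_ranked`.
#' @export
score_and_rank <- function(defs, stats, clinical, medians = NULL) {
  if (inherits(defs, "ifm_definitions")) {
    params_mat <- defs$params; ids <- defs$id
  } else {
    params_mat <- defs; ids <- apply(defs, 1, paste, collapse = "+")
  }
  wide <- stats_to_wide(stats)
  all_params <- sort(unique(as.vector(params_mat)))
  miss <- setdiff(all_params, colnames(wide))
  if (length(miss)) stop("parameters absent from stats: ",
                         paste(miss, collapse = ", "))
  if (is.null(medians)) {
    medians <- apply(wide[, all_params, drop = FALSE], 2, median,
                     na.rm = TRUE)
  }
  B <- sweep(wide[, all_params, drop = FALSE], 2, medians[all_params],
             ">") * 1
  # membership: parameters x definitions
  C <- matrix(0L, length(all_params), nrow(params_mat),
              dimnames = list(all_params, NULL))
  for (j in seq_len(ncol(params_mat))) {
    C[cbind(match(params_mat[, j], all_params), seq_len(nrow(params_mat)))] <-
      C[cbind(match(params_mat[, j], all_params),
              seq_len(nrow(params_mat)))] + 1L
  }
  total <- B %*% C                     # specimens x definitions
  cls <- ifelse(total >= 3, "H", "L")  # NA totals stay NA
  cls[is.na(total)] <- "X"             # missing -> excluded per model below
  keys <- apply(cls, 2, paste, collapse = "")
  uk <- unique(keys)
  prep_full <- NULL
  m_clin <- match(rownames(wide), clinical$specimen_id)
  times <- clinical$pfs_days[m_clin]
  events <- clinical$event[m_clin]
  res <- matrix(NA_real_, length(uk), 4,
                dimnames = list(uk, c("hr", "ci_low", "ci_high", "p")))
  flags <- rep("ok", length(uk))
  for (i in seq_along(uk)) {
    cc <- strsplit(uk[i], "")[[1]]
    ok <- cc != "X"
    if (length(unique(cc[ok])) < 2) { flags[i] <- "degenerate_split"; next }
    cmp <- logrank_hr(times[ok], events[ok],
                      factor(cc[ok], levels = c("H", "L")))
    if (cmp$flag != "ok" || !is.finite(cmp$hr)) {
      flags[i] <- "event_free_group"
      next
    }
    res[i, ] <- c(cmp$hr, cmp$ci_low, cmp$ci_high, cmp$p)
  }
  mi <- match(keys, uk)
  tab <- data.frame(id = ids, hr = res[mi, "hr"],
                    ci_low = res[mi, "ci_low"], ci_high = res[mi, "ci_high"],
                    p = res[mi, "p"], flag = flags[mi],
                    stringsAsFactors = FALSE)
  rankable <- tab$flag == "ok" & is.finite(tab$hr)
  o <- order(tab$hr[rankable], tab$p[rankable], tab$id[rankable])
  tab$rank <- NA_integer_
  tab$rank[which(rankable)[o]] <- seq_len(sum(rankable))
  structure(list(table = tab, defs = params_mat, ids = ids,
                 medians = medians, n_ranked = sum(rankable)),
            class = "ifm_ranking")
}

#' Select the next-best model excluding given markers
#'
#' Walks the ranking from the best (smallest) HR, skipping every model that
#' contains any excluded marker, and returns the first survivor (the
#' selection rule that produced IFM2 with `exclude_markers = c("CD3",
#' "CD8")`, the IFM1 markers).
#'
#' @param ranking an `ifm_ranking`.
#' @param exclude_markers markers that disqualify a model (default CD3 and
#'   CD8; an empty set returns the rank-1 model).
#' @return one-row data.frame from the ranking table, plus a `params`
#'   attribute.
#' @export
select_ifm2 <- function(ranking, exclude_markers = c("CD3", "CD8")) {
  tab <- ranking$table
  ranked <- which(!is.na(tab$rank))
  if (length(ranked) == 0) stop("no ranked models")
  ranked <- ranked[order(tab$rank[ranked])]
  for (i in ranked) {
    mk <- split_param(ranking$defs[i, ])$marker
    if (!any(mk %in% exclude_markers)) {
      out <- tab[i, , drop = FALSE]
      attr(out, "params") <- ranking$defs[i, ]
      return(out)
    }
  }
  stop("every ranked model contains an excluded marker")
}

#' GSEA-style marker/region enrichment over a model ranking
#'
#' For each (marker, region) parameter a running sum walks the ranked model
#' list: up by `1/(2 n_hit)` at models containing the parameter, down by
#' `1/(2 n_miss)` otherwise, so the sum ends at zero and the enrichment
#' score (the extremum of the running sum) lies in `[-1, 1]`. A positive ES
#' means the parameter concentrates among the best (lowest-HR) models. The
#' p-value is the two-sample Kolmogorov-Smirnov test comparing the rank
#' distributions of containing vs non-containing models.
#'
#' @param ranking an `ifm_ranking`.
#' @return data.frame `param`, `marker`, `region`, `n_hit`, `es`, `p`,
#'   `flag` (`"all_or_none"` rows have undefined ES).
#' @export
marker_enrichment <- function(ranking) {
  tab <- ranking$table
  keep <- !is.na(tab$rank)
  ord <- order(tab$rank[keep])
  idx <- which(keep)[ord]
  L <- length(idx)
  params <- sort(unique(as.vector(ranking$defs)))
  out <- list()
  for (p in params) {
    hit <- apply(ranking$defs[idx, , drop = FALSE] == p, 1, any)
    nh <- sum(hit); nm <- L - nh
    pr <- split_param(p)
    if (nh == 0 || nm == 0) {
      out[[p]] <- data.frame(param = p, marker = pr$marker,
                             region = pr$region, n_hit = nh, es = NA_real_,
                             p = NA_real_, flag = "all_or_none")
      next
    }
    steps <- ifelse(hit, 1 / (2 * nh), -1 / (2 * nm))
    run <- cumsum(steps)
    es <- run[which.max(abs(run))]
    ks <- suppressWarnings(ks.test(which(hit), which(!hit)))
    out[[p]] <- data.frame(param = p, marker = pr$marker, region = pr$region,
                           n_hit = nh, es = es, p = ks$p.value, flag = "ok")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Topic-fraction survival model (IFM3)
#'
#' Splits the cohort at a percentile of one topic's per-specimen fraction
#' (high: at or above the cutoff; low: below) and computes the high-vs-low
#' log-rank hazard ratio. The threshold is configurable over 50-75 without
#' materially changing the story on smooth cohorts; 50 (the median) is the
#' default.
#'
#' @param topic_fractions specimens x topics matrix (rownames = specimen
#'   ids) or a named per-specimen vector.
#' @param clinical clinical table.
#' @param topic topic column (index or name) when a matrix is given.
#' @param percentile cutoff percentile in (0, 100).
#' @return object of class `ifm_result`: `class` (named high/low vector),
#'   `cutoff`, `hr` (a `survival_comparison`).
#' @export
compute_ifm3 <- function(topic_fractions, clinical, topic = NULL,
                         percentile = 50) {
  frac <- if (is.matrix(topic_fractions)) {
    if (is.null(topic)) stop("topic must be given with a fraction matrix")
    stats::setNames(topic_fractions[, topic], rownames(topic_fractions))
  } else {
    topic_fractions
  }
  if (length(unique(frac)) < 2) stop("degenerate split: constant fractions")
  cutoff <- quantile(frac, percentile / 100, names = FALSE)
  cls <- ifelse(frac >= cutoff, "high", "low")
  if (length(unique(cls)) < 2) {
    stop("degenerate split: all specimens on one side of the cutoff")
  }
  hr <- class_hr(cls, names(frac), clinical)
  structure(list(id = "IFM3", class = cls, cutoff = cutoff,
                 percentile = percentile, hr = hr),
            class = "ifm_result")
}

#' Composite immune + tumor-intrinsic model (IFM4)
#'
#' Class 1: specimens high on the immune model (IFM1) and low on the topic
#' model (IFM3); class 2: all other specimens. The class is a pure function
#' of the two input classes. The hazard ratio compares class 1 vs class 2.
#'
#' @param ifm1_class named per-specimen `"high"`/`"low"` vector.
#' @param ifm3_class named per-specimen `"high"`/`"low"` vector over the
#'   same specimens.
#' @param clinical clinical table.
#' @return object of class `ifm_result` with `class` (`"class1"` /
#'   `"class2"`) and `hr`.
#' @export
compute_ifm4 <- function(ifm1_class, ifm3_class, clinical) {
  specs <- names(ifm1_class)
  if (is.null(specs) || !setequal(specs, names(ifm3_class))) {
    stop("ifm1_class and ifm3_class must be named over the same specimens")
  }
  cls <- ifelse(ifm1_class == "high" & ifm3_class[specs] == "low",
                "class1", "class2")
  if (length(unique(cls)) < 2) stop("degenerate composite: one class empty")
  m <- match(clinical$specimen_id, specs)
  cc <- cls[m]
  hr <- logrank_hr(clinical$pfs_days, clinical$event,
                   factor(cc, levels = c("class1", "class2")))
  structure(list(id = "IFM4", class = cls, hr = hr), class = "ifm_result")
}
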