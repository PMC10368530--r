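# Umbrella pipeline: gating -> compartments -> region fractions -> IFM
# search -> spatial LDA -> IFM3/IFM4 -> survival summary, with a frozen-model
# transfer mode (medians, gate thresholds, topic-word distributions and
# cutoffs learned on a training cohort re-applied verbatim to a test cohort).

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stage_fail <- function(stage, e) {
  stop(structure(class = c("pipeline_error", "error", "condition"),
                 list(message = sprintf("stage '%s' failed: %s", stage,
                                        conditionMessage(e)),
                      call = NULL, stage = stage)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stage_fail(stage, e))
}

#' Run the full analysis pipeline on one cohort
#'
#' Composes the stages in analysis order: per-marker GMM gating, KNN tumor
#' mask and invasive-margin compartments, per-region positive fractions,
#' the exhaustive 4-parameter model search with IFM1/IFM2 selection,
#' grid-binned spatial LDA with perplexity-based topic-number selection,
#' the topic model IFM3, and the composite IFM4. Deterministic given the
#' seeds in the config.
#'
#' When `frozen` (a previous run's `$frozen` element) is supplied, nothing
#' is re-learned on this cohort: gate thresholds, parameter medians, the
#' topic-word matrix, the IFM3 topic and absolute cutoff are applied
#' verbatim (the training-cohort transfer protocol). Cohort medians are
#' never recomputed on the test cohort in that mode.
#'
#' @param cells cell table (data.frame or CSV path).
#' @param clinical clinical table (data.frame or CSV path).
#' @param config a [pipeline_config()].
#' @param frozen optional frozen model from a previous run.
#' @param out optional output directory; per-stage CSVs and a JSON summary
#'   are written there.
#' @return list with per-stage outputs (`gates`, `compartments`,
#'   `region_stats`, `ranking`, `ifm1`..`ifm4`, `lda`), `summary` (plain
#'   list, JSON-serializable), and `frozen` (reusable trained model).
#' @export
run_pipeline <- function(cells, clinical, config = pipeline_config(),
                         frozen = NULL, out = NULL) {
  if (is.character(cells)) cells <- read_cell_table(cells)
  if (is.character(clinical)) clinical <- read_clinical_table(clinical)
  cells <- validate_cell_table(cells)
  panel <- config$panel
  markers <- c(panel$tumor_marker, panel$immune_markers)
  markers <- intersect(markers, names(cells))

  # --- gating ---------------------------------------------------------------
  gates <- run_stage("gating", {
    if (is.null(frozen)) {
      g <- gate_cell_table(cells, markers = markers,
                           per_specimen = config$gating$per_specimen,
                           seed = config$gating$seed)
      pipeline_log("gating", "%d markers x %d cells, %d gates",
                   length(markers), nrow(cells), nrow(g$summary))
      g
    } else {
      thr <- frozen$gate_thresholds
      calls <- vapply(markers, function(m) log1p(cells[[m]]) > thr[[m]],
                      logical(nrow(cells)))
      pipeline_log("gating", "applied %d frozen thresholds", length(markers))
      list(calls = calls, summary = NULL)
    }
  })

  # --- compartments ---------------------------------------------------------
  comp <- run_stage("compartments", {
    compartment <- factor(rep("OUT", nrow(cells)),
                          levels = c("CT", "IM", "OUT"))
    maps <- list()
    for (sp in unique(cells$specimen_id)) {
      i <- cells$specimen_id == sp
      tum <- build_tumor_mask(cells$x_um[i], cells$y_um[i],
                              gates$calls[i, panel$tumor_marker],
                              k = config$compartments$knn_k)
      mp <- assign_compartments(cells[i, ], tum,
                                margin_um = config$compartments$margin_um,
                                raster_um = config$compartments$raster_um)
      compartment[i] <- mp$compartment
      maps[[sp]] <- mp
    }
    pipeline_log("compartments", "CT %d / IM %d / OUT %d cells",
                 sum(compartment == "CT"), sum(compartment == "IM"),
                 sum(compartment == "OUT"))
    list(compartment = compartment, maps = maps)
  })

  # --- region fractions -----------------------------------------------------
  stats <- run_stage("region_fractions", {
    s <- region_fractions(cells, comp$compartment, gates$calls,
                          markers = intersect(panel$immune_markers, markers))
    pipeline_log("region_fractions", "%d rows", nrow(s))
    s
  })

  # --- IFM search -----------------------------------------------------------
  search <- run_stage("ifm_search", {
    defs <- enumerate_ifms(intersect(panel$immune_markers, markers),
                           size = config$ifm$size)
    ranking <- score_and_rank(defs, stats, clinical,
                              medians = frozen$param_medians)
    ifm1 <- compute_ifm1(stats, clinical, medians = frozen$param_medians)
    ifm2 <- tryCatch(
      select_ifm2(ranking, exclude_markers = config$ifm$exclude_markers),
      error = function(e) {
        pipeline_log("ifm_search", "IFM2 selection failed: %s",
                     conditionMessage(e))
        NULL
      })
    pipeline_log("ifm_search", "%d definitions, %d ranked",
                 length(defs$id), ranking$n_ranked)
    list(defs = defs, ranking = ranking, ifm1 = ifm1, ifm2 = ifm2)
  })

  # --- spatial LDA ----------------------------------------------------------
  lda <- run_stage("lda", {
    keep <- comp$compartment %in% config$lda$regions
    corpus <- grid_binning(cells,
                           gates$calls[, intersect(panel$immune_markers,
                                                   markers), drop = FALSE],
                           grid_um = config$lda$grid_um,
                           min_cells = config$lda$min_cells, keep = keep)
    if (!is.null(frozen)) {
      theta <- with_seed(config$lda$seed,
        .lda_fold_in(matrix(as.integer(corpus$docs), nrow(corpus$docs)),
                     phi = frozen$phi, alpha = 50 / nrow(frozen$phi),
                     n_iter = 200, burnin = 100))
      fit <- structure(list(K = nrow(frozen$phi), phi = frozen$phi,
                            theta = theta, corpus = corpus,
                            alpha = 50 / nrow(frozen$phi)),
                       class = "topic_model_fit")
      sel <- list(K = nrow(frozen$phi), perplexity_curve = NULL, fit = fit)
    } else if (!is.null(config$lda$K)) {
      fit <- fit_lda(corpus, K = config$lda$K, n_iter = config$lda$n_iter,
                     burnin = config$lda$burnin, seed = config$lda$seed)
      sel <- list(K = config$lda$K, perplexity_curve = NULL, fit = fit)
    } else {
      kr <- config$lda$k_range
      sel <- select_K(corpus, K_range = kr[1]:kr[2],
                      heldout_fraction = config$lda$heldout_fraction,
                      n_iter = config$lda$n_iter,
                      burnin = config$lda$burnin, seed = config$lda$seed)
    }
    asg <- assign_cells(sel$fit, corpus, cells$specimen_id)
    pipeline_log("lda", "K = %d over %d grids", sel$K, nrow(corpus$docs))
    list(corpus = corpus, selection = sel, fit = sel$fit, assignment = asg)
  })

  # --- IFM3 / IFM4 ----------------------------------------------------------
  topic_models <- run_stage("topic_models", {
    tf <- lda$assignment$specimen_fractions
    topic <- if (!is.null(frozen)) frozen$ifm3_topic
             else if (!is.null(config$ifm$topic)) config$ifm$topic
             else {
               # strongest |correlation| of topic fraction with PFS
               m <- match(rownames(tf), clinical$specimen_id)
               cors <- apply(tf, 2, function(v)
                 suppressWarnings(stats::cor(v, clinical$pfs_days[m])))
               cors[is.na(cors)] <- 0
               colnames(tf)[which.max(abs(cors))]
             }
    ifm3 <- if (!is.null(frozen)) {
      frac <- stats::setNames(tf[, topic], rownames(tf))
      cls <- ifelse(frac >= frozen$ifm3_cutoff, "high", "low")
      structure(list(id = "IFM3", class = cls, cutoff = frozen$ifm3_cutoff,
                     percentile = NA_real_,
                     hr = class_hr(cls, names(frac), clinical)),
                class = "ifm_result")
    } else {
      compute_ifm3(tf, clinical, topic = topic,
                   percentile = config$ifm$percentile)
    }
    ifm1_class <- stats::setNames(search$ifm1$scores$class,
                                  search$ifm1$scores$specimen)
    ifm4 <- tryCatch(compute_ifm4(ifm1_class, ifm3$class, clinical),
                     error = function(e) {
                       pipeline_log("topic_models", "IFM4 degenerate: %s",
                                    conditionMessage(e))
                       NULL
                     })
    pipeline_log("topic_models", "IFM3 topic = %s", topic)
    list(topic = topic, ifm3 = ifm3, ifm4 = ifm4)
  })

  frozen_out <- list(
    gate_thresholds = if (is.null(frozen)) {
      s <- gates$summary
      stats::setNames(vapply(split(s$threshold, s$marker),
                             median, numeric(1), na.rm = TRUE),
                      names(split(s$threshold, s$marker)))
    } else frozen$gate_thresholds,
    param_medians = search$ranking$medians,
    phi = lda$fit$phi,
    ifm3_topic = topic_models$topic,
    ifm3_cutoff = topic_models$ifm3$cutoff
  )

  hr_of <- function(x) {
    if (is.null(x)) return(NULL)
    list(hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p)
  }
  tab <- search$ranking$table
  summary <- list(
    n_specimens = length(unique(cells$specimen_id)),
    n_cells = nrow(cells),
    ifm1 = c(list(rank = tab$rank[match(search$ifm1$id, tab$id)]),
             hr_of(search$ifm1$hr)),
    ifm2 = if (!is.null(search$ifm2)) {
      list(id = search$ifm2$id, rank = search$ifm2$rank,
           hr = search$ifm2$hr, ci_low = search$ifm2$ci_low,
           ci_high = search$ifm2$ci_high, p = search$ifm2$p)
    },
    ifm3 = c(list(topic = topic_models$topic,
                  cutoff = topic_models$ifm3$cutoff),
             hr_of(topic_models$ifm3$hr)),
    ifm4 = if (!is.null(topic_models$ifm4)) hr_of(topic_models$ifm4$hr),
    lda = list(K = lda$selection$K, n_grids = nrow(lda$corpus$docs)),
    n_models_ranked = search$ranking$n_ranked
  )

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write.csv(stats, file.path(out, "region_stats.csv"), row.names = FALSE)
    write.csv(tab, file.path(out, "ranking.csv"), row.names = FALSE)
    write.csv(search$ifm1$scores, file.path(out, "ifm1_scores.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(lda$fit$phi), file.path(out, "phi.csv"))
    write.csv(as.data.frame(lda$assignment$specimen_fractions),
              file.path(out, "topic_fractions.csv"))
    if (!is.null(lda$selection$perplexity_curve)) {
      write.csv(lda$selection$perplexity_curve,
                file.path(out, "perplexity.csv"), row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(gates = gates, compartments = comp, region_stats = stats,
       defs = search$defs, ranking = search$ranking, ifm1 = search$ifm1,
       ifm2 = search$ifm2, lda = lda, ifm3 = topic_models$ifm3,
       ifm4 = topic_models$ifm4, summary = summary, frozen = frozen_out,
       config = config)
}
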