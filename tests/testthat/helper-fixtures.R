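# Shared fixtures built in code. Everything is seeded; nothing touches disk
# except through tempfiles created by the tests themselves.

# A small cohort reused by several IFM/survival tests: 20 specimens with a
# protective CD8 effect, region stats built from the generator's truth calls
# and a seeded random CT/IM assignment (spatial steps are tested separately).
fixture_truth_stats <- function(n_specimens = 20, seed = 42,
                                effect = c(CD8 = -1.6),
                                cells_per_specimen = 300,
                                infiltration_sd = 0.8) {
  spec <- cohort_sim_spec(n_specimens = n_specimens,
                          cells_per_specimen = cells_per_specimen,
                          infiltration_effect = effect, seed = seed,
                          infiltration_sd = infiltration_sd)
  sim <- simulate_cohort(spec)
  immune <- default_panel()$immune
  calls <- as.matrix(sim$cells[, paste0("truth_call_", immune)])
  colnames(calls) <- immune
  compartment <- with_test_seed(seed, {
    factor(sample(c("CT", "IM"), nrow(sim$cells), replace = TRUE),
           levels = c("CT", "IM", "OUT"))
  })
  stats <- region_fractions(sim$cells, compartment, calls)
  list(sim = sim, stats = stats, calls = calls, compartment = compartment)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# fabricate an ifm_ranking with prescribed hit positions for one parameter,
# for the closed-form enrichment tests
fixture_ranking <- function(n_models, hit_positions, param = "CD8@CT",
                            filler = c("CD3@CT", "CD4@CT", "CD20@CT")) {
  defs <- matrix(rep(c(filler, "PD1@IM"), n_models), n_models, 4,
                 byrow = TRUE)
  defs[hit_positions, 1] <- param  # replaces CD3@CT at the hit positions
  ids <- apply(defs, 1, paste, collapse = "+")
  tab <- data.frame(id = ids, hr = seq(0.1, 2, length.out = n_models),
                    ci_low = NA_real_, ci_high = NA_real_,
                    p = runif(n_models), flag = "ok",
                    rank = seq_len(n_models))
  structure(list(table = tab, defs = defs, ids = ids,
                 medians = NULL, n_ranked = n_models),
            class = "ifm_ranking")
}

# exact point-to-segment distance, brute force (oracle for the rasterized
# boundary distance)
dist_point_segments <- function(px, py, seg) {
  # seg: data.frame x1,y1,x2,y2
  vapply(seq_along(px), function(i) {
    dx <- seg$x2 - seg$x1; dy <- seg$y2 - seg$y1
    len2 <- dx^2 + dy^2
    t <- ((px[i] - seg$x1) * dx + (py[i] - seg$y1) * dy) / pmax(len2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    qx <- seg$x1 + t * dx; qy <- seg$y1 + t * dy
    sqrt(min((px[i] - qx)^2 + (py[i] - qy)^2))
  }, numeric(1))
}
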