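# ifm_models: enumeration, median-split scoring, ranking, enrichment,
# topic and composite models

test_that("enumeration counts equal the binomial coefficient", {
  expect_equal(length(enumerate_ifms()$id), 14950)
  expect_equal(length(enumerate_ifms(c("CD3", "CD8"))$id), 1)
  defs3 <- enumerate_ifms(c("CD3", "CD8", "CD4"))
  expect_equal(length(defs3$id), 15)
  # brute-force oracle: count distinct 4-subsets by enumeration
  params <- defs3$all_params
  brute <- 0
  for (a in 1:3) for (b in 2:4) for (cc in 3:5) for (d in 4:6) {
    if (a < b && b < cc && cc < d) brute <- brute + 1
  }
  expect_equal(length(defs3$id), brute)
  expect_false(anyDuplicated(defs3$id) > 0)
})

toy_stats <- function(values) {
  # values: named list specimen -> c(CD3@CT, CD3@IM, CD8@CT, CD8@IM)
  do.call(rbind, lapply(names(values), function(sp) {
    data.frame(specimen = sp,
               marker = rep(c("CD3", "CD3", "CD8", "CD8")),
               region = rep(c("CT", "IM", "CT", "IM")),
               positive_fraction = values[[sp]])
  }))
}

test_that("IFM1 spans 0 to 4 with the strict-above median rule", {
  st <- toy_stats(list(S1 = c(0.9, 0.9, 0.9, 0.9),
                       S2 = c(0.5, 0.5, 0.5, 0.5),
                       S3 = c(0.1, 0.1, 0.1, 0.1)))
  res <- compute_ifm1(st)
  sc <- res$scores[match(c("S1", "S2", "S3"), res$scores$specimen), ]
  expect_equal(sc$total, c(4, 0, 0))  # S2 sits exactly at the median: 0
  expect_equal(sc$class, c("high", "low", "low"))
})

test_that("IFM1 totals are centred at 2 for i.i.d. fractions", {
  # even cohort: the interpolated median leaves exactly half the specimens
  # strictly above, so the expected total is 4 * 1/2 = 2 (an odd cohort
  # would centre at 4 * (n-1)/(2n) under the strict-above rule)
  means <- vapply(1:100, function(s) {
    st <- toy_stats(stats::setNames(
      lapply(1:10, function(i) runif(4)), paste0("S", 1:10)))
    mean(compute_ifm1(st)$scores$total)
  }, numeric(1))
  expect_lt(abs(mean(means) - 2), 0.1)
})

test_that("missing fractions flag the specimen and propagate", {
  st <- toy_stats(list(S1 = c(0.9, 0.9, 0.9, 0.9),
                       S2 = c(0.5, 0.5, 0.5, 0.5),
                       S3 = c(0.1, 0.1, 0.1, 0.1),
                       S4 = c(0.3, 0.4, 0.3, 0.4)))
  st$positive_fraction[st$specimen == "S1" & st$region == "IM" &
                         st$marker == "CD3"] <- NA
  res <- compute_ifm1(st)
  expect_true(is.na(res$scores$total[res$scores$specimen == "S1"]))
  expect_error(compute_ifm1(st[st$specimen %in% c("S1", "S2"), ]),
               "at least 3")
})

test_that("the search path reproduces compute_ifm1 exactly", {
  fx <- fixture_truth_stats(n_specimens = 16, seed = 31)
  ifm1 <- compute_ifm1(fx$stats, fx$sim$clinical)
  defs <- matrix(ifm1$params, nrow = 1)
  rk <- score_and_rank(defs, fx$stats, fx$sim$clinical)
  expect_equal(rk$table$hr, ifm1$hr$hr)
  expect_equal(rk$table$p, ifm1$hr$p)
})

test_that("scoring is invariant to specimen order", {
  fx <- fixture_truth_stats(n_specimens = 14, seed = 32)
  defs <- enumerate_ifms(c("CD3", "CD8", "CD4"))
  rk1 <- score_and_rank(defs, fx$stats, fx$sim$clinical)
  shuf <- fx$stats[sample(nrow(fx$stats)), ]
  rk2 <- score_and_rank(defs, shuf, fx$sim$clinical)
  expect_equal(rk1$table$hr, rk2$table$hr)
  expect_equal(rk1$table$rank, rk2$table$rank)
})

test_that("shuffled survival times centre the HR distribution at 1", {
  # permutation null: survival times shuffled across specimens, so the
  # fractions carry no information; the per-permutation median log HR over
  # all 14,950 models must average to zero across permutations
  fx <- fixture_truth_stats(n_specimens = 40, seed = 333, effect = NULL)
  defs <- enumerate_ifms()
  set.seed(334)
  stats <- vapply(1:10, function(r) {
    clin <- fx$sim$clinical
    clin[, c("pfs_days", "event")] <-
      clin[sample(nrow(clin)), c("pfs_days", "event")]
    rk <- score_and_rank(defs, fx$stats, clin)
    ok <- rk$table$flag == "ok"
    c(med = median(log(rk$table$hr[ok])),
      hit = mean(rk$table$p[ok] < 0.05))
  }, numeric(2))
  expect_lt(abs(mean(stats["med", ])), 0.25)
  # multiplicity sanity: models are heavily correlated within a cohort, so
  # only the across-permutation mean sits anywhere near the nominal 5%
  expect_lt(mean(stats["hit", ]), 0.2)
})

test_that("IFM2 selection skips models containing excluded markers", {
  rk <- fixture_ranking(10, hit_positions = 3:10, param = "CD8@CT")
  # models 1-2 carry only the filler markers (CD3 among them): excluded
  pick <- select_ifm2(rk, exclude_markers = "CD3")
  expect_equal(pick$rank, 3)
  expect_true("CD8@CT" %in% attr(pick, "params"))
  # empty exclusion set returns the top model
  expect_equal(select_ifm2(rk, exclude_markers = character(0))$rank, 1)
  expect_error(select_ifm2(rk, exclude_markers = c("CD3", "CD4", "CD20",
                                                   "CD8", "PD1")),
               "every ranked model")
})

test_that("enrichment score is exactly 0.5 for a top-half feature", {
  rk <- fixture_ranking(40, hit_positions = 1:20)
  en <- marker_enrichment(rk)
  row <- en[en$param == "CD8@CT", ]
  expect_equal(row$es, 0.5)
  expect_lt(row$p, 0.01)
  # reversing the ranking flips the sign
  rk_rev <- rk
  rk_rev$table$rank <- rev(rk_rev$table$rank)
  en_rev <- marker_enrichment(rk_rev)
  expect_equal(en_rev[en_rev$param == "CD8@CT", "es"], -0.5)
})

test_that("uniformly spread features have small ES; constants are flagged", {
  rk <- fixture_ranking(400, hit_positions = seq(1, 400, by = 2))
  en <- marker_enrichment(rk)
  expect_lt(abs(en[en$param == "CD8@CT", "es"]), 0.1)
  # fillers appear in every model: undefined ES
  expect_equal(en[en$param == "CD4@CT", "flag"], "all_or_none")
  expect_true(is.na(en[en$param == "CD4@CT", "es"]))
})

test_that("a planted protective marker is enriched among top models", {
  fx <- fixture_truth_stats(n_specimens = 40, seed = 34,
                            effect = c(CD8 = -1.6))
  defs <- enumerate_ifms()
  rk <- score_and_rank(defs, fx$stats, fx$sim$clinical)
  en <- marker_enrichment(rk)
  cd8 <- en[en$marker == "CD8", ]
  expect_true(any(cd8$es > 0 & cd8$p < 0.05))
})

test_that("IFM3 splits at the requested percentile", {
  set.seed(71)
  n <- 40
  frac <- stats::setNames(runif(n), paste0("S", 1:n))
  haz <- 1 / 500 * exp(1.2 * (frac >= median(frac)))  # high topic = bad
  clin <- data.frame(specimen_id = names(frac),
                     pfs_days = rexp(n, haz), event = 1)
  res <- compute_ifm3(frac, clin, percentile = 50)
  expect_equal(sum(res$class == "high"), n / 2)
  expect_gt(res$hr$hr, 1)  # high vs low: harmful topic
  # percentile 50 vs 60: same sign, overlapping CIs
  res60 <- compute_ifm3(frac, clin, percentile = 60)
  expect_equal(sign(log(res$hr$hr)), sign(log(res60$hr$hr)))
  expect_true(res60$hr$ci_low < res$hr$ci_high &&
                res$hr$ci_low < res60$hr$ci_high)
  # degenerate cutoffs
  expect_error(compute_ifm3(frac, clin, percentile = 0), "degenerate")
  expect_error(compute_ifm3(stats::setNames(rep(0.3, n), names(frac)),
                            clin), "degenerate")
})

test_that("IFM4 is a pure function of the two input classes", {
  cls1 <- c(S1 = "high", S2 = "high", S3 = "low", S4 = "low")
  cls3 <- c(S1 = "low", S2 = "high", S3 = "low", S4 = "high")
  clin <- data.frame(specimen_id = names(cls1), pfs_days = c(10, 20, 30, 40),
                     event = c(1, 1, 1, 1))
  res <- compute_ifm4(cls1, cls3, clin)
  expect_equal(unname(res$class),
               c("class1", "class2", "class2", "class2"))
  # degenerate: every specimen in class 1
  expect_error(compute_ifm4(c(S1 = "high", S2 = "high"),
                            c(S1 = "low", S2 = "low"),
                            clin[1:2, ]), "degenerate")
})

test_that("the composite beats its components on independent effects", {
  # Monte-Carlo oracle: immune (protective) and tumor-intrinsic (harmful)
  # effects independent; |log HR| of the composite exceeds both marginals
  # in expectation
  reps <- 30
  l1 <- l3 <- l4 <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(400 + r)
    n <- 60
    c1 <- ifelse(runif(n) < 0.5, "high", "low")
    c3 <- ifelse(runif(n) < 0.5, "high", "low")
    haz <- 1 / 400 * exp(-0.9 * (c1 == "high") + 0.9 * (c3 == "high"))
    clin <- data.frame(specimen_id = paste0("S", 1:n),
                       pfs_days = rexp(n, haz),
                       event = as.integer(runif(n) > 0.3))
    clin$pfs_days <- pmax(clin$pfs_days, 1e-3)
    names(c1) <- names(c3) <- clin$specimen_id
    h1 <- logrank_hr(clin$pfs_days, clin$event,
                     factor(c1, levels = c("high", "low")))$hr
    h3 <- logrank_hr(clin$pfs_days, clin$event,
                     factor(c3, levels = c("high", "low")))$hr
    h4 <- compute_ifm4(c1, c3, clin)$hr$hr
    l1[r] <- abs(log(h1)); l3[r] <- abs(log(h3)); l4[r] <- abs(log(h4))
  }
  expect_gt(mean(l4), mean(l1))
  expect_gt(mean(l4), mean(l3))
})

test_that("the published IFM2 preset is scoreable directly", {
  fx <- fixture_truth_stats(n_specimens = 16, seed = 35)
  wide <- stats_to_wide(fx$stats)
  sc <- ifmkit:::ifm_score_matrix(ifm2_preset(), wide)
  expect_true(all(sc$total %in% 0:4 | is.na(sc$total)))
  expect_setequal(sc$params,
                  c("aSMA@CT", "CD45@IM", "PDL1@IM", "CD4@IM"))
})
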