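# spatial_lda: grid binning, collapsed Gibbs, K selection, cell assignment

test_that("grid binning counts marker-positive events per grid", {
  cells <- data.frame(specimen_id = "S1", cell_id = 1:10,
                      x_um = runif(10, 0, 150), y_um = runif(10, 0, 150))
  calls <- cbind(CD3 = rep(TRUE, 10), CD4 = rep(TRUE, 10),
                 CD8 = rep(FALSE, 10))
  corp <- grid_binning(cells, calls, grid_um = 200)
  expect_equal(nrow(corp$docs), 1)
  expect_equal(as.vector(corp$docs), c(10L, 10L, 0L))
  expect_true(all(corp$cell_grid == 1))
})

test_that("a 1x1 mm specimen tiles into 25 grids of 200 um", {
  xy <- expand.grid(gx = 0:4, gy = 0:4)
  cells <- do.call(rbind, lapply(seq_len(nrow(xy)), function(i) {
    data.frame(specimen_id = "S1", cell_id = NA,
               x_um = xy$gx[i] * 200 + c(50, 100, 150, 120, 80),
               y_um = xy$gy[i] * 200 + c(50, 100, 150, 80, 120))
  }))
  cells$cell_id <- seq_len(nrow(cells))
  calls <- cbind(CD3 = rep(TRUE, nrow(cells)))
  corp <- grid_binning(cells, calls, grid_um = 200, min_cells = 1)
  expect_equal(nrow(corp$docs), 25)
})

test_that("grids below the cell floor are dropped", {
  cells <- data.frame(specimen_id = "S1", cell_id = 1:8,
                      x_um = c(rep(50, 6), 500, 510),
                      y_um = c(seq(10, 60, 10), 500, 510))
  calls <- cbind(CD3 = rep(TRUE, 8))
  corp <- grid_binning(cells, calls, grid_um = 200, min_cells = 5)
  expect_equal(nrow(corp$docs), 1)
  expect_equal(sum(is.na(corp$cell_grid)), 2)
  expect_error(grid_binning(cells, calls, grid_um = 200, min_cells = 50),
               "no grids")
})

test_that("spatially separated marker regimes yield separable documents", {
  set.seed(41)
  n <- 2000
  x <- runif(n, 0, 2000)
  cells <- data.frame(specimen_id = "S1", cell_id = 1:n, x_um = x,
                      y_um = runif(n, 0, 2000))
  left <- x < 1000
  calls <- cbind(A = left & runif(n) < 0.8, B = !left & runif(n) < 0.8)
  corp <- grid_binning(cells, calls, grid_um = 200)
  cs <- ifmkit:::cosine_rows(corp$docs + 1e-9, corp$docs + 1e-9)
  lab <- corp$grid_info$gx < 5
  within <- mean(cs[lab, lab]) + mean(cs[!lab, !lab])
  between <- 2 * mean(cs[lab, !lab])
  expect_gt(within, between + 0.5)
})

test_that("the Gibbs sampler is deterministic and recovers planted topics", {
  corp <- simulate_topic_corpus(400, K = 3, seed = 4)
  fit1 <- fit_lda(corp$docs, K = 3, n_iter = 300, burnin = 150, seed = 9)
  fit2 <- fit_lda(corp$docs, K = 3, n_iter = 300, burnin = 150, seed = 9)
  expect_identical(fit1$phi, fit2$phi)
  expect_identical(fit1$theta, fit2$theta)
  perm <- match_topics(fit1$phi, corp$phi)
  expect_true(all(attr(perm, "similarity") > 0.9))
  expect_equal(rowSums(fit1$phi), rep(1, 3), ignore_attr = TRUE)
  expect_equal(rowSums(fit1$theta), rep(1, 400), ignore_attr = TRUE)
})

test_that("document order does not change the recovered topics", {
  corp <- simulate_topic_corpus(400, K = 3, seed = 14)
  fit <- fit_lda(corp$docs, K = 3, n_iter = 300, burnin = 150, seed = 9)
  perm_docs <- corp$docs[sample(nrow(corp$docs)), ]
  fit_p <- fit_lda(perm_docs, K = 3, n_iter = 300, burnin = 150, seed = 9)
  m <- match_topics(fit_p$phi, fit$phi)
  expect_true(all(attr(m, "similarity") > 0.95))
})

test_that("K = 1 degenerates to the corpus-wide frequency", {
  corp <- simulate_topic_corpus(100, K = 3, seed = 5)
  fit <- fit_lda(corp$docs, K = 1)
  freq <- colSums(corp$docs) / sum(corp$docs)
  expect_equal(as.vector(fit$phi), unname(freq), tolerance = 0.01)
  expect_true(all(fit$theta == 1))
  expect_error(fit_lda(corp$docs[1:3, ], K = 5), "exceeds")
})

test_that("held-out perplexity selects close to the planted topic count", {
  corp <- simulate_topic_corpus(1200, K = 10, doc_length = 60, seed = 77)
  sel <- select_K(corp$docs, K_range = 8:12, n_iter = 250, burnin = 120,
                  seed = 3, refit = FALSE)
  expect_true(sel$K %in% 9:11)
  expect_equal(nrow(sel$perplexity_curve), 5)
  expect_true(all(is.finite(sel$perplexity_curve$perplexity)))
})

test_that("training perplexity does not exceed held-out perplexity", {
  # generalization direction, averaged over replicates
  diffs <- vapply(1:5, function(s) {
    corp <- simulate_topic_corpus(300, K = 4, seed = 50 + s)
    train <- corp$docs[1:240, ]; test <- corp$docs[241:300, ]
    fit <- fit_lda(train, K = 4, n_iter = 250, burnin = 120, seed = s)
    lda_perplexity(fit, test, seed = s) -
      lda_perplexity(fit, train, seed = s)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("cells inherit their grid's argmax topic", {
  # two far-apart grids with disjoint marker regimes
  n <- 40
  cells <- data.frame(specimen_id = rep(c("S1", "S2"), each = n / 2),
                      cell_id = 1:n,
                      x_um = c(runif(n / 2, 0, 180), runif(n / 2, 0, 180)),
                      y_um = c(runif(n / 2, 0, 180), runif(n / 2, 0, 180)))
  calls <- cbind(A = c(rep(TRUE, n / 2), rep(FALSE, n / 2)),
                 B = c(rep(FALSE, n / 2), rep(TRUE, n / 2)))
  corp <- grid_binning(cells, calls, grid_um = 200)
  fit <- fit_lda(corp, K = 2, n_iter = 200, burnin = 100, seed = 1)
  asg <- assign_cells(fit, corp, cells$specimen_id)
  # single-regime specimens have a pure topic fraction
  expect_equal(unname(apply(asg$specimen_fractions, 1, max)), c(1, 1))
  expect_equal(rowSums(asg$specimen_fractions), c(S1 = 1, S2 = 1))
  # the two specimens land on different topics
  expect_false(all(asg$cell_topic[1:(n / 2)] ==
                     asg$cell_topic[(n / 2 + 1):n]))
})

test_that("specimens mixing two pure regimes split fractions evenly", {
  n <- 80
  cells <- data.frame(specimen_id = "S1", cell_id = 1:n,
                      x_um = c(runif(n / 2, 0, 180),
                               runif(n / 2, 1000, 1180)),
                      y_um = runif(n, 0, 180))
  calls <- cbind(A = c(rep(TRUE, n / 2), rep(FALSE, n / 2)),
                 B = c(rep(FALSE, n / 2), rep(TRUE, n / 2)))
  corp <- grid_binning(cells, calls, grid_um = 200)
  fit <- fit_lda(corp, K = 2, n_iter = 200, burnin = 100, seed = 2)
  asg <- assign_cells(fit, corp, cells$specimen_id)
  expect_equal(unname(asg$specimen_fractions["S1", ]), c(0.5, 0.5),
               ignore_attr = TRUE)
})
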