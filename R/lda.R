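# Spatial LDA: bin marker-positive calls into square grids ("documents"),
# fit topics by collapsed Gibbs sampling, choose the topic number by
# held-out perplexity, and push grid topics back to single cells.

#' Bin marker-positive calls into spatial grid documents
#'
#' A square grid of side `grid_um` tiles each specimen's bounding box. The
#' document of a grid is the count of marker-positive events per marker
#' among its cells (a cell positive for m markers contributes m tokens).
#' Grids with fewer than `min_cells` cells are dropped.
#'
#' @param cells cell table with `specimen_id`, `x_um`, `y_um`.
#' @param calls logical cells x markers gate-call matrix.
#' @param grid_um grid side in microns (default 200).
#' @param min_cells minimum cells per retained grid (default 5).
#' @param keep logical per-cell filter (e.g. restrict to tumor + margin
#'   compartments); default keeps every cell.
#' @return object of class `grid_corpus`: list with `docs` (grids x markers
#'   integer count matrix), `grid_info` (specimen, grid indices, cell
#'   count), `cell_grid` (per-cell row index into `docs`, `NA` for cells in
#'   dropped grids or filtered out).
#' @export
grid_binning <- function(cells, calls, grid_um = 200, min_cells = 5,
                         keep = NULL) {
  assert_cols(cells, c("specimen_id", "x_um", "y_um"), "cell table")
  stopifnot(nrow(calls) == nrow(cells), grid_um > 0)
  if (is.null(keep)) keep <- rep(TRUE, nrow(cells))
  markers <- colnames(calls)
  n <- nrow(cells)
  gid <- rep(NA_character_, n)
  sel <- which(keep)
  for (sp in unique(cells$specimen_id[sel])) {
    i <- sel[cells$specimen_id[sel] == sp]
    gx <- floor((cells$x_um[i] - min(cells$x_um[i])) / grid_um)
    gy <- floor((cells$y_um[i] - min(cells$y_um[i])) / grid_um)
    gid[i] <- paste(sp, gx, gy, sep = "|")
  }
  tab <- table(gid[!is.na(gid)])
  keep_grids <- names(tab)[tab >= min_cells]
  if (length(keep_grids) == 0) stop("no grids with >= ", min_cells, " cells")
  docs <- matrix(0L, length(keep_grids), length(markers),
                 dimnames = list(keep_grids, markers))
  gidx <- match(gid, keep_grids)
  ok <- !is.na(gidx)
  for (m in markers) {
    cnt <- tapply(calls[ok, m], gidx[ok], sum)
    docs[as.integer(names(cnt)), m] <- as.integer(cnt)
  }
  parts <- do.call(rbind, strsplit(keep_grids, "|", fixed = TRUE))
  grid_info <- data.frame(specimen = parts[, 1],
                          gx = as.integer(parts[, 2]),
                          gy = as.integer(parts[, 3]),
                          n_cells = as.integer(tab[keep_grids]))
  structure(list(docs = docs, grid_info = grid_info, cell_grid = gidx,
                 grid_um = grid_um),
            class = "grid_corpus")
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Token-level topic reassignment with the standard collapsed conditionals;
#' `phi` and `theta` are posterior means averaged over post-burn-in sweeps.
#' Deterministic given `seed`.
#'
#' @param docs documents x vocabulary integer count matrix (or a
#'   `grid_corpus`).
#' @param K topic count (`>= 1`; must not exceed the document count).
#' @param alpha document-topic Dirichlet hyperparameter (default `50 / K`).
#' @param beta topic-word Dirichlet hyperparameter (default 0.01).
#' @param n_iter total Gibbs sweeps (default 1000).
#' @param burnin sweeps discarded before averaging (default 500).
#' @param seed integer seed.
#' @return object of class `topic_model_fit`: list with `K`, `phi`
#'   (K x vocabulary, rows sum to 1), `theta` (documents x K, rows sum to
#'   1), hyperparameters, `seed`.
#' @export
fit_lda <- function(docs, K, alpha = 50 / K, beta = 0.01, n_iter = 1000,
                    burnin = 500, seed = 1) {
  corpus <- if (inherits(docs, "grid_corpus")) docs else NULL
  if (!is.null(corpus)) docs <- corpus$docs
  stopifnot(is.matrix(docs), all(docs >= 0), K >= 1, burnin < n_iter)
  if (K > nrow(docs)) {
    stop("K (", K, ") exceeds the number of documents (", nrow(docs), ")")
  }
  vocab <- colnames(docs)
  if (K == 1) {
    tot <- colSums(docs) + beta
    phi <- matrix(tot / sum(tot), 1, ncol(docs),
                  dimnames = list("topic1", vocab))
    theta <- matrix(1, nrow(docs), 1,
                    dimnames = list(rownames(docs), "topic1"))
    return(structure(list(K = 1L, phi = phi, theta = theta, alpha = alpha,
                          beta = beta, n_iter = n_iter, burnin = burnin,
                          seed = seed, corpus = corpus),
                     class = "topic_model_fit"))
  }
  res <- with_seed(seed,
                   .lda_gibbs(docs = matrix(as.integer(docs), nrow(docs)),
                              K = as.integer(K), alpha = alpha, beta = beta,
                              n_iter = as.integer(n_iter),
                              burnin = as.integer(burnin)))
  phi <- res$phi / rowSums(res$phi)
  theta <- res$theta / rowSums(res$theta)
  dimnames(phi) <- list(paste0("topic", seq_len(K)), vocab)
  dimnames(theta) <- list(rownames(docs), paste0("topic", seq_len(K)))
  structure(list(K = as.integer(K), phi = phi, theta = theta, alpha = alpha,
                 beta = beta, n_iter = n_iter, burnin = burnin, seed = seed,
                 corpus = corpus),
            class = "topic_model_fit")
}

#' Held-out perplexity of an LDA fit
#'
#' Folds held-out documents into the fitted topic-word distribution (Gibbs
#' with `phi` fixed) to estimate their topic weights, then reports
#' `exp(-mean per-token predictive log-likelihood)`.
#'
#' @param fit a `topic_model_fit` (or a phi matrix).
#' @param docs held-out documents x vocabulary count matrix.
#' @param alpha fold-in Dirichlet hyperparameter (defaults to the fit's).
#' @param n_iter,burnin fold-in Gibbs sweeps.
#' @param seed integer seed.
#' @return perplexity (scalar, lower is better).
#' @export
lda_perplexity <- function(fit, docs, alpha = NULL, n_iter = 200,
                           burnin = 100, seed = 1) {
  phi <- if (inherits(fit, "topic_model_fit")) fit$phi else fit
  if (is.null(alpha)) {
    alpha <- if (inherits(fit, "topic_model_fit")) fit$alpha else 50 / nrow(phi)
  }
  stopifnot(ncol(docs) == ncol(phi))
  nonempty <- rowSums(docs) > 0
  docs <- docs[nonempty, , drop = FALSE]
  if (nrow(docs) == 0) stop("no non-empty held-out documents")
  theta <- if (nrow(phi) == 1) {
    matrix(1, nrow(docs), 1)
  } else {
    with_seed(seed,
              .lda_fold_in(docs = matrix(as.integer(docs), nrow(docs)),
                           phi = phi, alpha = alpha,
                           n_iter = as.integer(n_iter),
                           burnin = as.integer(burnin)))
  }
  pw <- theta %*% phi            # docs x vocab predictive token probabilities
  ll <- sum(docs * log(pmax(pw, .Machine$double.xmin)))
  exp(-ll / sum(docs))
}

#' Choose the topic count by held-out perplexity
#'
#' Splits the corpus into training and held-out documents, fits one model
#' per candidate K on the training part, and picks the K minimizing held-out
#' perplexity (ties go to the smaller K).
#'
#' @param docs documents x vocabulary count matrix (or `grid_corpus`).
#' @param K_range candidate topic counts (default 8:16).
#' @param heldout_fraction fraction of documents held out (default 0.2).
#' @param n_iter,burnin Gibbs sweeps per candidate fit.
#' @param seed integer seed (controls the split and every fit).
#' @param refit refit the chosen K on the full corpus (default TRUE).
#' @return list with `K` (chosen), `perplexity_curve` (data.frame K,
#'   perplexity), `fit` (final model if `refit`).
#' @export
select_K <- function(docs, K_range = 8:16, heldout_fraction = 0.2,
                     n_iter = 1000, burnin = 500, seed = 1, refit = TRUE) {
  corpus <- if (inherits(docs, "grid_corpus")) docs else NULL
  if (!is.null(corpus)) docs <- corpus$docs
  D <- nrow(docs)
  stopifnot(D >= 5, heldout_fraction > 0, heldout_fraction < 1)
  n_held <- max(1, round(heldout_fraction * D))
  held <- with_seed(seed, sample.int(D, n_held))
  train <- docs[-held, , drop = FALSE]
  test <- docs[held, , drop = FALSE]
  perp <- vapply(K_range, function(K) {
    f <- fit_lda(train, K = K, n_iter = n_iter, burnin = burnin, seed = seed)
    lda_perplexity(f, test, seed = seed)
  }, numeric(1))
  Kbest <- K_range[which.min(perp)]  # which.min takes the first = smallest K
  fit <- NULL
  if (refit) {
    fit <- fit_lda(if (is.null(corpus)) docs else corpus, K = Kbest,
                   n_iter = n_iter, burnin = burnin, seed = seed)
  }
  list(K = Kbest,
       perplexity_curve = data.frame(K = K_range, perplexity = perp),
       fit = fit)
}

#' Assign topics to single cells and summarize per specimen
#'
#' Each cell inherits the argmax topic of its grid's document-topic weights;
#' cells outside every retained grid get `NA`. Specimen topic fractions are
#' cells assigned the topic divided by all topic-assigned cells in the
#' specimen.
#'
#' @param fit a `topic_model_fit` whose `theta` rows correspond to the
#'   corpus grids.
#' @param corpus the `grid_corpus` the fit was trained on (defaults to the
#'   one stored in the fit).
#' @param specimen_id per-cell specimen ids (same length/order as the cell
#'   table used for binning).
#' @return list with `cell_topic` (integer per cell, `NA` when unbinned),
#'   `specimen_fractions` (specimens x topics matrix, rows sum to 1).
#' @export
assign_cells <- function(fit, corpus = NULL, specimen_id) {
  if (is.null(corpus)) corpus <- fit$corpus
  if (is.null(corpus)) stop("no grid corpus available")
  stopifnot(nrow(fit$theta) == nrow(corpus$docs))
  grid_topic <- max.col(fit$theta, ties.method = "first")
  cell_topic <- grid_topic[corpus$cell_grid]
  ok <- !is.na(cell_topic)
  frac <- table(specimen = specimen_id[ok],
                topic = factor(cell_topic[ok], levels = seq_len(fit$K)))
  frac <- as.matrix(frac)
  frac <- frac / rowSums(frac)
  colnames(frac) <- paste0("topic", seq_len(fit$K))
  list(cell_topic = cell_topic, specimen_fractions = frac)
}
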