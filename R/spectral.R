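# Spectral (linear) extraction: estimate a channels x fluorophores mixing
# matrix from single-stain controls, then solve per-pixel nonnegative least
# squares to isolate fluorophore signal and remove channel crosstalk.

stack_dims <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3) stop("a stack must be a channels x rows x cols array")
  d
}

# top (1 - q) fraction of pixels by rank; rank-based rather than a plain
# quantile cut so compactly supported (mostly zero) images still yield a
# bright set of the intended size
top_pixels <- function(v, q) {
  n_top <- max(1L, ceiling((1 - q) * length(v)))
  keep <- order(v, decreasing = TRUE)[seq_len(n_top)]
  out <- logical(length(v))
  out[keep[v[keep] > 0]] <- TRUE
  out
}

# per-channel robust background profile from an unstained acquisition
autofluor_profile_of <- function(af_stack) {
  if (is.null(af_stack)) return(NULL)
  d <- stack_dims(af_stack)
  apply(matrix(af_stack, nrow = d[1]), 1, median)
}

#' Fit a mixing matrix from single-stain controls
#'
#' For each fluorophore's control acquisition, the home channel is the
#' channel with the largest robust response; the column of the mixing matrix
#' is the per-channel median over the brightest pixels (top quantile by
#' home-channel intensity), after subtracting the autofluorescence profile
#' estimated from an unstained control. Columns are scaled to unit maximum.
#'
#' @param control_stacks named list, one channels x rows x cols array per
#'   fluorophore, all sharing channel ordering.
#' @param autofluor_stack optional unstained stack. When its dimensions
#'   match the controls it is subtracted pixelwise (a paired
#'   autofluorescence acquisition of the same field); otherwise its
#'   per-channel median profile is subtracted.
#' @param bright_quantile pixels above this home-channel quantile are used
#'   (default 0.95: top 5% brightest).
#' @param max_condition condition-number threshold above which the matrix is
#'   rejected as near-collinear, naming the most similar fluorophore pair.
#' @return object of class `mixing_matrix`: list with `M` (columns unit-max
#'   normalized), `channels`, `fluors`, `autofluor_profile`.
#' @export
fit_mixing_matrix <- function(control_stacks, autofluor_stack = NULL,
                              bright_quantile = 0.95, max_condition = 1e4) {
  stopifnot(is.list(control_stacks), length(control_stacks) >= 1)
  fluors <- names(control_stacks)
  if (is.null(fluors)) fluors <- paste0("F", seq_along(control_stacks))
  d <- stack_dims(control_stacks[[1]])
  nc <- d[1]
  af <- autofluor_profile_of(autofluor_stack)
  if (is.null(af)) af <- numeric(nc)
  af_pixelwise <- !is.null(autofluor_stack) &&
    all(dim(autofluor_stack) == d)
  M <- matrix(0, nc, length(fluors),
              dimnames = list(paste0("ch", seq_len(nc)), fluors))
  for (f in seq_along(fluors)) {
    st <- control_stacks[[f]]
    if (!all(dim(st) == d)) stop("control stacks must share dimensions")
    px <- if (af_pixelwise) {
      matrix(st - autofluor_stack, nrow = nc)
    } else {
      matrix(st, nrow = nc) - af
    }
    home <- which.max(apply(px, 1, function(v) mean(pmax(v, 0))))
    bright <- top_pixels(px[home, ], bright_quantile)
    if (!any(bright)) stop("no bright pixels in control for ", fluors[f])
    col <- apply(px[, bright, drop = FALSE], 1, median)
    col <- pmax(col, 0)
    if (max(col) <= 0) stop("control for ", fluors[f], " carries no signal")
    M[, f] <- col / max(col)
  }
  if (length(fluors) > 1) {
    kap <- kappa(M, exact = TRUE)
    if (!is.finite(kap) || kap > max_condition) {
      cs <- cosine_rows(t(M), t(M))
      diag(cs) <- -Inf
      ij <- arrayInd(which.max(cs), dim(cs))
      stop(sprintf(paste0("mixing matrix is near-singular (condition %.3g): ",
                          "fluorophores %s and %s have nearly identical ",
                          "spectra"),
                   kap, fluors[ij[1]], fluors[ij[2]]))
    }
  }
  structure(list(M = M, channels = rownames(M), fluors = fluors,
                 autofluor_profile = af),
            class = "mixing_matrix")
}

# Plain matrices are wrapped as-is (no rescaling: unmixing must invert the
# matrix the caller supplies; only fit_mixing_matrix applies the unit-max
# reporting convention to its own estimate).
as_mixing_matrix <- function(M, autofluor_profile = NULL) {
  if (inherits(M, "mixing_matrix")) return(M)
  stopifnot(is.matrix(M), all(M >= 0))
  if (is.null(autofluor_profile)) autofluor_profile <- numeric(nrow(M))
  fl <- colnames(M); if (is.null(fl)) fl <- paste0("F", seq_len(ncol(M)))
  structure(list(M = M, channels = rownames(M), fluors = fl,
                 autofluor_profile = autofluor_profile),
            class = "mixing_matrix")
}

#' Unmix a multi-channel stack into per-fluorophore abundances
#'
#' Solves, for every pixel, `M a ~= observed` with `a >= 0`. The
#' autofluorescence profile is appended as an extra column during the solve
#' and dropped from the result, so structured background is absorbed rather
#' than misattributed to fluorophores.
#'
#' @param stack channels x rows x cols array.
#' @param mixing a `mixing_matrix` (or plain nonnegative matrix).
#' @param method `"nnls"` (default; nonnegative least squares — negative
#'   abundances are unphysical) or `"pinv"` (pseudoinverse with clipping at
#'   zero; faster, adequate at high signal-to-noise).
#' @return fluors x rows x cols abundance array.
#' @export
unmix <- function(stack, mixing, method = c("nnls", "pinv")) {
  method <- match.arg(method)
  mixing <- as_mixing_matrix(mixing)
  d <- stack_dims(stack)
  if (d[1] != nrow(mixing$M)) {
    stop(sprintf("stack has %d channels but mixing matrix has %d rows",
                 d[1], nrow(mixing$M)))
  }
  A <- mixing$M
  af <- mixing$autofluor_profile
  use_af <- !is.null(af) && any(af > 0)
  if (use_af) A <- cbind(A, autofluor = af / max(af))
  Y <- matrix(stack, nrow = d[1])
  X <- if (method == "nnls") {
    .nnls_cols(A, Y)
  } else {
    pmax(solve(crossprod(A), crossprod(A, Y)), 0)
  }
  if (use_af) X <- X[-nrow(X), , drop = FALSE]
  out <- array(X, dim = c(ncol(mixing$M), d[2], d[3]))
  dimnames(out) <- list(mixing$fluors, NULL, NULL)
  out
}

#' Quantify channel crosstalk from single-fluorophore acquisitions
#'
#' For each fluorophore the brightest pixels in its home channel are
#' selected; the report row is the mean pixel intensity per channel over
#' that set, normalized to the home-channel value. Mean adjacent crosstalk
#' averages the entries at the channels spectrally adjacent to each home
#' channel (neighbors in wavelength-sorted channel order).
#'
#' @param stacks named list of single-fluorophore stacks (raw acquisitions
#'   or unmixed outputs re-expanded per channel). For unmixed outputs pass
#'   the per-fluorophore abundance planes as channels.
#' @param home_channels integer vector, one home channel per stack; inferred
#'   as the brightest channel when `NULL`.
#' @param bright_quantile quantile defining "bright" in the home channel.
#' @return object of class `crosstalk_report`: list with `matrix`
#'   (fluorophore x channel, home-normalized), `mean_adjacent_crosstalk`
#'   (percent), `per_pair` data.frame.
#' @export
crosstalk_metric <- function(stacks, home_channels = NULL,
                             bright_quantile = 0.95) {
  stopifnot(is.list(stacks), length(stacks) >= 1)
  fluors <- names(stacks)
  if (is.null(fluors)) fluors <- paste0("F", seq_along(stacks))
  d <- stack_dims(stacks[[1]])
  nc <- d[1]
  if (!is.null(home_channels)) stopifnot(length(home_channels) == length(stacks))
  mat <- matrix(NA_real_, length(stacks), nc,
                dimnames = list(fluors, paste0("ch", seq_len(nc))))
  homes <- integer(length(stacks))
  for (f in seq_along(stacks)) {
    px <- matrix(stacks[[f]], nrow = nc)
    homes[f] <- if (is.null(home_channels)) which.max(rowMeans(px)) else home_channels[f]
    bright <- top_pixels(px[homes[f], ], bright_quantile)
    if (!any(bright)) stop("empty bright-pixel set for ", fluors[f])
    mu <- rowMeans(px[, bright, drop = FALSE])
    if (mu[homes[f]] <= 0) stop("zero home-channel signal for ", fluors[f])
    mat[f, ] <- mu / mu[homes[f]]
  }
  pairs <- do.call(rbind, lapply(seq_along(stacks), function(f) {
    adj <- intersect(c(homes[f] - 1, homes[f] + 1), seq_len(nc))
    data.frame(fluor = fluors[f], home_channel = homes[f], channel = adj,
               crosstalk_pct = 100 * mat[f, adj])
  }))
  structure(list(matrix = mat,
                 mean_adjacent_crosstalk = mean(pairs$crosstalk_pct),
                 per_pair = pairs, home_channels = homes),
            class = "crosstalk_report")
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat(sprintf("crosstalk report: %d fluorophores, %d channels\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("mean adjacent-channel crosstalk: %.2f%%\n",
              x$mean_adjacent_crosstalk))
  invisible(x)
}

# Re-expand an unmixed abundance stack into per-fluor "acquisitions" whose
# channel planes hold the abundance of each fluorophore, so crosstalk_metric
# can score residual bleed after extraction: fluor f's acquisition has the
# unmixed planes as channels and home channel = f.
#' Crosstalk of unmixed single-stain acquisitions
#'
#' Convenience wrapper: unmixes each single-fluorophore control with the
#' given mixing matrix and measures residual crosstalk between fluorophore
#' planes (the post-extraction analogue of the raw-channel report).
#'
#' @inheritParams crosstalk_metric
#' @param controls named list of raw single-stain stacks.
#' @param mixing a `mixing_matrix`.
#' @param method passed to [unmix()].
#' @return a `crosstalk_report` over fluorophore planes.
#' @export
crosstalk_after_unmix <- function(controls, mixing,
                                  bright_quantile = 0.95,
                                  method = "nnls") {
  mixing <- as_mixing_matrix(mixing)
  un <- lapply(controls, unmix, mixing = mixing, method = method)
  crosstalk_metric(un, home_channels = match(names(controls), mixing$fluors),
                   bright_quantile = bright_quantile)
}
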