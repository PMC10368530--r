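# Tumor mask from pan-cytokeratin calls via KNN majority smoothing, then
# invasive-margin geometry: the tumor-stroma boundary is extracted from a
# rasterized label field and every cell is assigned to tumor center (CT),
# invasive margin (IM, within margin_um of the boundary on either side), or
# outside (OUT).

#' Smooth per-cell tumor membership with a KNN majority vote
#'
#' A cell belongs to the tumor region when the majority of its `k` nearest
#' cells (Euclidean distance in microns, the cell itself included in its
#' neighborhood) are positive for the tumor lineage marker. The smoother is
#' applied to all cells, not only the marker-positive ones.
#'
#' @param x,y cell coordinates in microns.
#' @param tumor_pos logical per-cell pan-cytokeratin (tumor marker) call.
#' @param k neighborhood size in cells (default 25).
#' @return logical vector: tumor-region membership.
#' @export
build_tumor_mask <- function(x, y, tumor_pos, k = 25) {
  n <- length(x)
  stopifnot(length(y) == n, length(tumor_pos) == n)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")")
  .knn_majority(as.numeric(x), as.numeric(y), as.logical(tumor_pos),
                as.integer(k))
}

# Rasterize the per-cell tumor label onto a grid covering the cells'
# bounding box: every pixel takes the label of its nearest cell (nearest-
# neighbor fill, so sparse point sets still yield a contiguous label field),
# a 3x3 morphological closing smooths the tumor field, and the boundary is
# returned as the midpoints of edges between tumor and stroma pixels.
raster_boundary <- function(x, y, tumor, raster_um, smooth_um = 100,
                            max_pixels = 4e6) {
  x0 <- min(x); y0 <- min(y)
  nx <- max(1L, ceiling((max(x) - x0) / raster_um))
  ny <- max(1L, ceiling((max(y) - y0) / raster_um))
  if (as.double(nx) * ny > max_pixels) {
    stop("raster of ", nx, "x", ny, " pixels exceeds max_pixels; ",
         "increase raster_um")
  }
  # bucket cells, then a box majority of half-width smooth_um via
  # summed-area tables: regularizes the interface against cell-placement
  # noise at realistic densities
  ix <- pmin(nx, pmax(1L, ceiling((x - x0) / raster_um)))
  iy <- pmin(ny, pmax(1L, ceiling((y - y0) / raster_um)))
  n_tum <- matrix(0, nx, ny); n_all <- matrix(0, nx, ny)
  for (i in seq_along(x)) {
    n_all[ix[i], iy[i]] <- n_all[ix[i], iy[i]] + 1
    if (tumor[i]) n_tum[ix[i], iy[i]] <- n_tum[ix[i], iy[i]] + 1
  }
  box_sum <- function(m, h) {
    S <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed SAT
    S <- t(S)
    S <- rbind(0, cbind(0, S))
    i1 <- pmax(seq_len(nx) - h - 1, 0); i2 <- pmin(seq_len(nx) + h, nx)
    j1 <- pmax(seq_len(ny) - h - 1, 0); j2 <- pmin(seq_len(ny) + h, ny)
    S[i2 + 1, j2 + 1, drop = FALSE] - S[i1 + 1, j2 + 1, drop = FALSE] -
      S[i2 + 1, j1 + 1, drop = FALSE] + S[i1 + 1, j1 + 1, drop = FALSE]
  }
  h <- max(1L, as.integer(ceiling(smooth_um / raster_um)))
  bt <- box_sum(n_tum, h); ba <- box_sum(n_all, h)
  lab <- matrix(FALSE, nx, ny)
  lab[ba > 0] <- bt[ba > 0] * 2 > ba[ba > 0]
  if (any(ba == 0)) {  # fall back to nearest-cell label in empty windows
    empty <- which(ba == 0, arr.ind = TRUE)
    pxe <- x0 + (empty[, 1] - 0.5) * raster_um
    pye <- y0 + (empty[, 2] - 0.5) * raster_um
    d_t <- .min_dist_to_points(pxe, pye, x[tumor], y[tumor])
    d_s <- .min_dist_to_points(pxe, pye, x[!tumor], y[!tumor])
    lab[empty] <- d_t < d_s
  }
  # 3x3 morphological closing
  dil <- function(m) {
    out <- m
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      sh <- matrix(FALSE, nrow(m), ncol(m))
      xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
      okx <- xs - dx >= 1 & xs - dx <= nrow(m)
      oky <- ys - dy >= 1 & ys - dy <= ncol(m)
      sh[xs[okx], ys[oky]] <- m[xs[okx] - dx, ys[oky] - dy]
      out <- out | sh
    }
    out
  }
  ero <- function(m) !dil(!m)
  lab <- ero(dil(lab))
  bx <- numeric(0); by <- numeric(0)
  for (sh in list(c(1L, 0L), c(0L, 1L))) {
    dx <- sh[1]; dy <- sh[2]
    xs <- seq_len(nx - dx); ys <- seq_len(ny - dy)
    a <- lab[xs, ys, drop = FALSE]
    b <- lab[xs + dx, ys + dy, drop = FALSE]
    hit <- which(a != b, arr.ind = TRUE)
    if (nrow(hit)) {
      bx <- c(bx, x0 + (hit[, 1] - 0.5 + dx / 2) * raster_um)
      by <- c(by, y0 + (hit[, 2] - 0.5 + dy / 2) * raster_um)
    }
  }
  list(x = bx, y = by)
}

#' Assign cells to tumor center, invasive margin, or outside
#'
#' The tumor-stroma boundary is the interface of the rasterized tumor label
#' (pixel pitch `raster_um`, morphological closing applied). Cells within
#' `margin_um` of the boundary on either side are IM; tumor-region cells
#' farther inside are CT; everything else is OUT. IM overrides CT within the
#' band, so CT and IM are disjoint scoring regions.
#'
#' @param cells cell table with `x_um`, `y_um`.
#' @param tumor_label logical per-cell tumor-region membership (from
#'   [build_tumor_mask()]).
#' @param margin_um half-width of the invasive margin band (default 100).
#' @param raster_um raster pitch for boundary extraction (default 20).
#' @param smooth_um half-width of the box-majority smoother applied to the
#'   rasterized label field before contour tracing (default 100; regularizes
#'   the interface against cell-placement noise).
#' @return object of class `compartment_map`: list with `compartment`
#'   (factor CT/IM/OUT per cell), `boundary` (data.frame of boundary points
#'   in microns), `distance_um` (per-cell distance to the boundary),
#'   `margin_um`, `degenerate` flag.
#' @export
assign_compartments <- function(cells, tumor_label, margin_um = 100,
                                raster_um = 20, smooth_um = 100) {
  assert_cols(cells, c("x_um", "y_um"), "cell table")
  n <- nrow(cells)
  stopifnot(length(tumor_label) == n, margin_um >= 0)
  lev <- c("CT", "IM", "OUT")
  if (all(tumor_label) || all(!tumor_label)) {
    comp <- factor(ifelse(tumor_label, "CT", "OUT"), levels = lev)
    return(structure(list(compartment = comp,
                          boundary = data.frame(x = numeric(0),
                                                y = numeric(0)),
                          distance_um = rep(NA_real_, n),
                          margin_um = margin_um, degenerate = TRUE),
                     class = "compartment_map"))
  }
  b <- raster_boundary(cells$x_um, cells$y_um, tumor_label, raster_um,
                       smooth_um = smooth_um)
  if (length(b$x) == 0) {
    comp <- factor(ifelse(tumor_label, "CT", "OUT"), levels = lev)
    return(structure(list(compartment = comp,
                          boundary = data.frame(x = numeric(0),
                                                y = numeric(0)),
                          distance_um = rep(NA_real_, n),
                          margin_um = margin_um, degenerate = TRUE),
                     class = "compartment_map"))
  }
  d <- .min_dist_to_points(as.numeric(cells$x_um), as.numeric(cells$y_um),
                           b$x, b$y)
  im <- margin_um > 0 & d <= margin_um
  comp <- factor(ifelse(im, "IM", ifelse(tumor_label, "CT", "OUT")),
                 levels = lev)
  structure(list(compartment = comp, boundary = data.frame(x = b$x, y = b$y),
                 distance_um = d, margin_um = margin_um, degenerate = FALSE),
            class = "compartment_map")
}

#' Per-region marker-positive fractions
#'
#' One row per (specimen, marker, region in CT/IM). The denominator is the
#' total of all successfully segmented cells in the region, never a
#' marker-positive total. Empty regions yield `NA` (missing, not zero), so
#' such specimens drop out of cohort medians.
#'
#' @param cells cell table with `specimen_id`.
#' @param compartment factor CT/IM/OUT per cell (from a `compartment_map`,
#'   possibly concatenated across specimens).
#' @param calls logical cells x markers gate-call matrix.
#' @param markers which call columns to report (default: all).
#' @return data.frame `specimen`, `marker`, `region`, `positive_fraction`.
#' @export
region_fractions <- function(cells, compartment, calls, markers = NULL) {
  assert_cols(cells, "specimen_id", "cell table")
  if (is.null(markers)) markers <- colnames(calls)
  stopifnot(length(compartment) == nrow(cells),
            nrow(calls) == nrow(cells))
  out <- list()
  for (sp in unique(cells$specimen_id)) {
    in_sp <- cells$specimen_id == sp
    for (reg in c("CT", "IM")) {
      idx <- in_sp & compartment == reg
      denom <- sum(idx)
      for (m in markers) {
        frac <- if (denom == 0) NA_real_ else sum(calls[idx, m]) / denom
        out[[length(out) + 1]] <-
          data.frame(specimen = sp, marker = m, region = reg,
                     positive_fraction = frac)
      }
    }
  }
  do.call(rbind, out)
}
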