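# Readers and writers for the plain-text interchange formats: cell tables
# and clinical tables as CSV, image stacks as long-format CSV with a JSON
# channel-metadata sidecar, configuration as JSON.

#' Read a single-cell table
#'
#' Required columns: `specimen_id`, `cell_id`, `x_um`, `y_um`, and at least
#' one marker intensity column. Unknown columns are preserved. Coordinates
#' are in microns.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  validate_cell_table(df)
}

#' @rdname read_cell_table
#' @param df a data.frame to validate in place.
#' @export
validate_cell_table <- function(df) {
  assert_cols(df, c("specimen_id", "cell_id", "x_um", "y_um"), "cell table")
  reserved <- c("specimen_id", "cell_id", "x_um", "y_um", "compartment")
  markers <- setdiff(names(df)[vapply(df, is.numeric, TRUE)],
                     c(reserved, "cell_id"))
  markers <- markers[!startsWith(markers, "truth_")]
  if (length(markers) == 0) stop("cell table has no marker columns")
  dup <- tapply(df$cell_id, df$specimen_id, anyDuplicated)
  if (any(dup > 0)) {
    stop("duplicated cell_id within specimen: ",
         paste(names(dup)[dup > 0], collapse = ", "))
  }
  df
}

# serialize doubles at full precision so tables round-trip bit-identically
format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(df, path) {
  write.csv(format_full_precision(df), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read or write a clinical table
#'
#' Schema: `specimen_id`, `pfs_days` (positive), `event` (0/1).
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_clinical_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  assert_cols(df, c("specimen_id", "pfs_days", "event"), "clinical table")
  if (any(df$pfs_days <= 0)) stop("pfs_days must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df
}

#' @rdname read_clinical_table
#' @param df data.frame to write.
#' @export
write_clinical_table <- function(df, path) {
  write.csv(format_full_precision(df), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write / read an image stack as long-format CSV plus JSON sidecar
#'
#' Plain-text stand-in for multi-page TIFF: rows `channel,row,col,value`
#' (1-based indices), with channel names and image shape in
#' `<path>.meta.json`.
#'
#' @param stack channels x rows x cols array.
#' @param path CSV path; the sidecar is written next to it.
#' @param channel_names optional channel names.
#' @export
write_stack_csv <- function(stack, path, channel_names = NULL) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[1]))
  idx <- arrayInd(seq_along(stack), d)
  df <- data.frame(channel = idx[, 1], row = idx[, 2], col = idx[, 3],
                   value = as.vector(stack))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(channels = channel_names, shape = d),
                       paste0(path, ".meta.json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @return `read_stack_csv`: the stack array with channel dimnames.
#' @export
read_stack_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  stack <- array(NA_real_, dim = d)
  stack[cbind(df$channel, df$row, df$col)] <- df$value
  dimnames(stack) <- list(meta$channels, NULL, NULL)
  stack
}

#' Default pipeline configuration
#'
#' Namespaced parameter defaults matching the published analysis: 100 um
#' margin, KNN kernel of 25 cells, 200 um LDA grids with topic counts
#' scanned over 8-16, median (50th percentile) cutoffs, 500 bootstrap
#' resamples, FDR 0.1.
#'
#' @param ... named overrides replacing whole namespaces or scalar fields,
#'   e.g. `lda = list(k_range = c(4, 8))`.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    panel = list(tumor_marker = default_panel()$tumor,
                 immune_markers = default_panel()$immune),
    gating = list(per_specimen = TRUE, seed = 1),
    compartments = list(margin_um = 100, knn_k = 25, raster_um = 20),
    lda = list(grid_um = 200, k_range = c(8, 16), min_cells = 5,
               n_iter = 1000, burnin = 500, heldout_fraction = 0.2,
               regions = c("CT", "IM"), seed = 7, K = NULL),
    ifm = list(size = 4, percentile = 50, exclude_markers = c("CD3", "CD8"),
               topic = NULL),
    survival = list(bootstrap_n = 500, fdr = 0.1),
    seed = 1
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(cfg)) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config configuration to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
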