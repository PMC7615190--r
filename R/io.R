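# File interfaces: multi-page 16-bit TIFF stacks (one page per Z-slice,
# channels as separate files or interleaved), CSV cell tables and margin
# points, YAML configs, JSON summaries.

#' Write a 3D intensity stack as a multi-page 16-bit TIFF
#'
#' One page per Z-slice. Intensities are stored on the 16-bit scale
#' (values are clamped to `[0, 65535]`).
#'
#' @param stack 3D array (x, y, z).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  assert_array3d(stack, "stack")
  pages <- lapply(seq_len(dim(stack)[3]), function(z) {
    # tiff expects row-major matrices in [0,1]
    t(pmin(pmax(stack[, , z], 0), 65535)) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF file.
#' @return 3D array (x, y, z) on the 16-bit intensity scale.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(pg) t(pg) * 65535,
                matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  dim(arr) <- c(dim(arr)[1], dim(arr)[2], length(pages))
  arr
}

#' Write / read a cell table as CSV
#'
#' Plain CSV with one row per nucleus and documented columns (`label`,
#' centroid `x_um`/`y_um`/`z_um`, `volume_vox`, `surface_area`, channel
#' means, and any annotation columns such as `phi_deg`, `psi_deg`, `tier`,
#' `is_ysl`, `is_dfc`, marker flags).
#'
#' @param table cell table data.frame.
#' @param path CSV file.
#' @return `path` (write) or the data.frame (read).
#' @export
write_cell_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read margin boundary points from CSV
#'
#' Expects ordered `x`, `y` pixel coordinates, one boundary point per row.
#'
#' @param path CSV file with `x` and `y` columns.
#' @return Matrix of boundary points.
#' @export
read_margin_points <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("margin CSV must have `x` and `y` columns", call. = FALSE)
  as.matrix(df[, c("x", "y")])
}

#' Write a label image as a multi-page 16-bit TIFF
#'
#' @param labels integer 3D label image (at most 65535 labels).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 65535)
    stop("label image has more than 65535 labels", call. = FALSE)
  write_stack_tiff(labels, path)
}
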