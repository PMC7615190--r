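# Whole-embryo 3D nuclear segmentation: local adaptive thresholding of the
# DAPI channel along three orientations, watershed splitting on the blurred
# DAPI landscape, morphological opening, object filtering (dim and flat
# objects), and per-nucleus multi-channel intensity measurement.

#' Segmentation configuration
#'
#' @param local_window_px odd side length of the local-mean window for
#'   adaptive thresholding (pixels within a slice).
#' @param local_offset intensity subtracted from the local mean before
#'   comparison; a voxel is foreground where
#'   `value > local_mean - local_offset`.
#' @param gaussian_sigma_px Gaussian blur sigma (XY pixels) for the
#'   watershed landscape; the Z sigma is scaled by voxel anisotropy.
#' @param erosion_dilation_rounds rounds of binary opening (6-connected)
#'   applied before filtering.
#' @param dapi_min_mean objects with mean DAPI below this are removed
#'   (default 1000 on the 16-bit scale).
#' @param flatness_coef objects with `flatness_coef * volume < surface_area`
#'   are removed as overly flat (default 1.25, voxel units: volume in
#'   voxels, surface area in exposed faces).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(local_window_px = 25L, local_offset = 0,
                                gaussian_sigma_px = 2,
                                erosion_dilation_rounds = 1L,
                                dapi_min_mean = 1000, flatness_coef = 1.25) {
  local_window_px <- stopifnot_count(local_window_px, "local_window_px", min = 3L)
  if (local_window_px %% 2L == 0L)
    stop("`local_window_px` must be odd", call. = FALSE)
  stopifnot_scalar(local_offset, "local_offset")
  stopifnot_scalar(gaussian_sigma_px, "gaussian_sigma_px", positive = TRUE)
  erosion_dilation_rounds <- stopifnot_count(erosion_dilation_rounds,
                                             "erosion_dilation_rounds")
  stopifnot_scalar(dapi_min_mean, "dapi_min_mean")
  stopifnot_scalar(flatness_coef, "flatness_coef", positive = TRUE)
  structure(list(local_window_px = local_window_px,
                 local_offset = local_offset,
                 gaussian_sigma_px = gaussian_sigma_px,
                 erosion_dilation_rounds = erosion_dilation_rounds,
                 dapi_min_mean = dapi_min_mean,
                 flatness_coef = flatness_coef),
            class = "segmentation_config")
}

# local mean over slices perpendicular to `axis` (1 = resliced along X:
# slices are YZ planes; 3 = native Z-slices, i.e. XY planes)
.local_mean_axis <- function(dapi, window, axis) {
  d <- dim(dapi)
  if (axis == 3L) {
    out <- cpp_box_mean_xy(as.numeric(dapi), d[1], d[2], d[3], window)
    dim(out) <- d
    return(out)
  }
  perm <- if (axis == 1L) c(2L, 3L, 1L) else c(1L, 3L, 2L)
  a <- aperm(dapi, perm)
  da <- dim(a)
  m <- cpp_box_mean_xy(as.numeric(a), da[1], da[2], da[3], window)
  dim(m) <- da
  aperm(m, order(perm))
}

#' Adaptive thresholding along three orientations
#'
#' Runs a local-mean adaptive threshold on every slice of the stack, once
#' per axis (native Z-slices, and the stack resliced along X and along Y),
#' and intersects the three foreground masks. A voxel is nuclear only if it
#' exceeds its local mean (minus the offset) in all three orientations.
#'
#' @param dapi 3D DAPI intensity array.
#' @param cfg a [segmentation_config()].
#' @param return_axes also return the three single-orientation masks.
#' @return Logical 3D mask (or a list with `mask` and `axis_masks` when
#'   `return_axes = TRUE`).
#' @export
adaptive_threshold_3way <- function(dapi, cfg = segmentation_config(),
                                    return_axes = FALSE) {
  assert_array3d(dapi, "dapi")
  stopifnot(inherits(cfg, "segmentation_config"))
  masks <- lapply(1:3, function(ax) {
    mu <- .local_mean_axis(dapi, cfg$local_window_px, ax)
    dapi > (mu - cfg$local_offset)
  })
  mask <- masks[[1]] & masks[[2]] & masks[[3]]
  if (return_axes) list(mask = mask, axis_masks = masks) else mask
}

#' Watershed splitting of the nuclear mask
#'
#' Computes watershed regions of the inverted, Gaussian-blurred DAPI
#' channel (each nucleus is one catchment basin), removes the region
#' boundary voxels from the mask, and labels the remaining mask as
#' 26-connected 3D components.
#'
#' @param dapi 3D DAPI intensity array (unthresholded).
#' @param mask logical mask from [adaptive_threshold_3way()].
#' @param cfg a [segmentation_config()].
#' @param voxel_size_um (x, y, z) voxel size; only the anisotropy is used,
#'   to scale the Z blur sigma.
#' @return Integer 3D label image (0 = background).
#' @export
watershed_split <- function(dapi, mask, cfg = segmentation_config(),
                            voxel_size_um = c(1, 1, 1)) {
  assert_array3d(dapi, "dapi")
  if (!identical(dim(dapi), dim(mask)))
    stop("`mask` must have the same shape as `dapi`", call. = FALSE)
  stopifnot(inherits(cfg, "segmentation_config"))
  d <- dim(dapi)
  if (!any(mask)) {
    return(array(0L, dim = d))
  }
  s_xy <- cfg$gaussian_sigma_px
  s_z <- s_xy * voxel_size_um[1] / voxel_size_um[3]
  blurred <- cpp_gaussian_blur_3d(as.numeric(dapi), d[1], d[2], d[3],
                                  s_xy, s_xy, s_z)
  surface <- max(blurred) - blurred   # basins at the nuclei
  regions <- cpp_watershed_regions(surface, d[1], d[2], d[3])
  boundary <- cpp_region_boundary(regions, d[1], d[2], d[3])
  kept <- as.logical(mask) & !boundary
  labels <- cpp_label_components(kept, d[1], d[2], d[3], 26L)
  dim(labels) <- d
  labels
}

# per-label voxel statistics used by filtering and measurement
.label_stats <- function(labels, dapi) {
  idx <- which(labels > 0L)
  lab <- labels[idx]
  n_lab <- max(labels)
  vol <- tabulate(lab, nbins = n_lab)
  mean_dapi <- rowsum(dapi[idx], lab)[, 1] / vol[sort(unique(lab))]
  sa <- cpp_surface_counts(as.integer(labels), dim(labels)[1],
                           dim(labels)[2], dim(labels)[3], n_lab)
  present <- sort(unique(lab))
  data.frame(label = present, volume_vox = vol[present],
             surface_area = sa[present],
             mean_dapi = as.numeric(mean_dapi))
}

#' Filter segmented objects
#'
#' Applies the configured rounds of binary opening (erosion then dilation)
#' to the foreground, relabels, then removes dim objects (mean DAPI below
#' `dapi_min_mean`) and overly flat objects (those with
#' `flatness_coef * volume < surface_area`). Idempotent on its own output.
#'
#' @param labels integer 3D label image from [watershed_split()].
#' @param dapi 3D DAPI intensity array.
#' @param cfg a [segmentation_config()].
#' @return Filtered, compactly relabelled 3D label image.
#' @export
filter_objects <- function(labels, dapi, cfg = segmentation_config()) {
  assert_array3d(dapi, "dapi")
  if (!identical(dim(labels), dim(dapi)))
    stop("`labels` must have the same shape as `dapi`", call. = FALSE)
  stopifnot(inherits(cfg, "segmentation_config"))
  d <- dim(labels)
  fg <- labels > 0L
  for (r in seq_len(cfg$erosion_dilation_rounds)) {
    fg <- cpp_binary_erode6(as.logical(fg), d[1], d[2], d[3])
    fg <- cpp_binary_dilate6(fg, d[1], d[2], d[3])
  }
  # opening can merge nothing but can split; keep the watershed separations
  fg <- fg & (labels > 0L)
  relab <- cpp_label_components(as.logical(fg), d[1], d[2], d[3], 26L)
  dim(relab) <- d
  if (max(relab) == 0L) return(relab)
  st <- .label_stats(relab, dapi)
  keep <- st$label[st$mean_dapi >= cfg$dapi_min_mean &
                     !(cfg$flatness_coef * st$volume_vox < st$surface_area)]
  out <- array(0L, dim = d)
  if (length(keep)) {
    remap <- integer(max(relab))
    remap[keep] <- seq_along(keep)
    idx <- which(relab > 0L)
    out[idx] <- remap[relab[idx]]
  }
  out
}

#' Measure nuclei across channels
#'
#' One record per label: centroid in micrometres, volume in voxels,
#' surface area as the count of voxel faces adjoining a different label,
#' background, or the stack boundary, and the mean intensity of each
#' channel over the label's voxels.
#'
#' @param labels integer 3D label image.
#' @param channels named list of 3D intensity arrays, same shape as
#'   `labels`.
#' @param voxel_size_um (x, y, z) voxel size in micrometres.
#' @return data.frame with `label`, `x_um`, `y_um`, `z_um`, `volume_vox`,
#'   `surface_area` and one mean-intensity column per channel.
#' @export
measure_nuclei <- function(labels, channels, voxel_size_um) {
  if (!(is.array(labels) && length(dim(labels)) == 3L))
    stop("`labels` must be a 3D array", call. = FALSE)
  if (length(channels) == 0 || is.null(names(channels)))
    stop("`channels` must be a named list of arrays", call. = FALSE)
  for (nm in names(channels))
    if (!identical(dim(channels[[nm]]), dim(labels)))
      stop(sprintf("channel `%s` shape differs from `labels`", nm), call. = FALSE)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be three positive values", call. = FALSE)
  d <- dim(labels)
  idx <- which(labels > 0L)
  if (length(idx) == 0)
    return(cbind(data.frame(label = integer(0), x_um = numeric(0),
                            y_um = numeric(0), z_um = numeric(0),
                            volume_vox = integer(0), surface_area = integer(0)),
                 setNames(as.data.frame(matrix(numeric(0), 0, length(channels))),
                          names(channels))))
  lab <- labels[idx]
  n_lab <- max(labels)
  vol_all <- tabulate(lab, nbins = n_lab)
  present <- which(vol_all > 0)
  co <- arrayInd(idx, d)
  vol <- vol_all[present]
  cx <- (rowsum(as.numeric(co[, 1]), lab)[, 1] / vol - 0.5) * voxel_size_um[1]
  cy <- (rowsum(as.numeric(co[, 2]), lab)[, 1] / vol - 0.5) * voxel_size_um[2]
  cz <- (rowsum(as.numeric(co[, 3]), lab)[, 1] / vol - 0.5) * voxel_size_um[3]
  sa <- cpp_surface_counts(as.integer(labels), d[1], d[2], d[3], n_lab)
  out <- data.frame(label = present, x_um = cx, y_um = cy, z_um = cz,
                    volume_vox = vol, surface_area = sa[present])
  for (nm in names(channels))
    out[[nm]] <- rowsum(channels[[nm]][idx], lab)[, 1] / vol
  out
}

#' Segment and measure all nuclei in a stack
#'
#' Convenience wrapper: adaptive threshold along three orientations,
#' watershed splitting, object filtering, then per-nucleus measurement.
#'
#' @param channels named list of 3D arrays; must include `dapi`.
#' @param cfg a [segmentation_config()].
#' @param voxel_size_um (x, y, z) voxel size in micrometres.
#' @return List with `labels` (3D label image) and `cells`
#'   (the [measure_nuclei()] table).
#' @export
segment_nuclei <- function(channels, cfg = segmentation_config(),
                           voxel_size_um = c(0.125, 0.125, 0.250)) {
  if (!"dapi" %in% names(channels))
    stop("`channels` must include a `dapi` array", call. = FALSE)
  dapi <- channels$dapi
  mask <- adaptive_threshold_3way(dapi, cfg)
  labels <- watershed_split(dapi, mask, cfg, voxel_size_um)
  labels <- filter_objects(labels, dapi, cfg)
  list(labels = labels, cells = measure_nuclei(labels, channels, voxel_size_um))
}
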