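# Margin geometry: fit a closed spline to the hand-marked blastoderm/YSL
# boundary, assign every nucleus an angular position around it (dorsal = 0),
# flag YSL nuclei and dorsal forerunner cells, and rescale the remaining
# positions so their circular distribution stays uniform after exclusion.

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  seg_a <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (share an endpoint)
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (segments_intersect(pts[seg_a[i, 1], ], pts[seg_a[i, 2], ],
                             pts[seg_a[j, 1], ], pts[seg_a[j, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

# even-odd rule point-in-polygon, vectorised over query points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- ((ys[k] > py) != (ye[k] > py))
    if (any(crosses)) {
      xint <- xs[k] + (py[crosses] - ys[k]) / (ye[k] - ys[k]) * (xe[k] - xs[k])
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
  }
  inside
}

#' Fit a closed spline to sparse margin boundary points
#'
#' Interpolates ordered boundary points (marked on a maximum XY projection)
#' with a periodic cubic spline and resamples it to regularly spaced points
#' at unit-pixel arc-length increments. The dorsal reference is the curve
#' point nearest `dorsal_hint`.
#'
#' @param boundary_points matrix or data.frame of >= 4 ordered (x, y) pixel
#'   coordinates going once around the margin (either orientation).
#' @param pixel_size_um physical size of one pixel in micrometres.
#' @param dorsal_hint length-2 (x, y) pixel position marking dorsal.
#' @return An object of class `margin_curve`: list with `points_px`
#'   (n x 2 matrix of resampled points), `dorsal_index`, `pixel_size_um`
#'   and `length_px` (total arc length).
#' @export
fit_margin_spline <- function(boundary_points, pixel_size_um, dorsal_hint) {
  pts <- as.matrix(boundary_points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (nrow(pts) < 4L)
    stop("at least 4 ordered boundary points are required", call. = FALSE)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (length(dorsal_hint) != 2L || !all(is.finite(dorsal_hint)))
    stop("`dorsal_hint` must be a finite (x, y) pair", call. = FALSE)
  if (polygon_self_intersects(pts))
    stop("boundary points describe a self-intersecting curve", call. = FALSE)

  # periodic parameterisation by cumulative chord length, closing the loop
  closed <- rbind(pts, pts[1, ])
  tt <- c(0, cumsum(sqrt(rowSums(diff(closed)^2))))
  fx <- splinefun(tt, closed[, 1], method = "periodic")
  fy <- splinefun(tt, closed[, 2], method = "periodic")
  t_dense <- seq(0, max(tt), length.out = max(2000L, 8L * nrow(pts)))
  xd <- fx(t_dense); yd <- fy(t_dense)
  arc <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  L <- arc[length(arc)]
  n_out <- max(4L, round(L))
  s_out <- (seq_len(n_out) - 1) * L / n_out
  t_out <- approx(arc, t_dense, xout = s_out, ties = "ordered")$y
  out <- cbind(x = fx(t_out), y = fy(t_out))
  d2 <- (out[, 1] - dorsal_hint[1])^2 + (out[, 2] - dorsal_hint[2])^2
  structure(list(points_px = out, dorsal_index = which.min(d2),
                 pixel_size_um = pixel_size_um, length_px = L),
            class = "margin_curve")
}

#' @export
print.margin_curve <- function(x, ...) {
  cat(sprintf("Margin curve: %d points (%.1f px circumference), dorsal index %d, %.3f um/px\n",
              nrow(x$points_px), x$length_px, x$dorsal_index, x$pixel_size_um))
  invisible(x)
}

#' Assign each nucleus an angular position around the margin
#'
#' Each nucleus is matched to its closest margin point (in XY); its marginal
#' position `phi_deg` is the signed arc-length fraction from the dorsal
#' point times 360, wrapped to `[-180, 180)` with dorsal at 0. The sign of
#' `dist_to_margin_um` marks inside (positive) versus beyond (negative) the
#' closed margin curve.
#'
#' @param cells data.frame of nucleus records with micrometre centroid
#'   columns `x_um`, `y_um` (e.g. from [measure_nuclei()]).
#' @param margin a [fit_margin_spline()] result.
#' @return `cells` with `phi_deg` and `dist_to_margin_um` columns added.
#' @export
assign_marginal_position <- function(cells, margin) {
  stopifnot(inherits(margin, "margin_curve"))
  if (!all(c("x_um", "y_um") %in% names(cells)))
    stop("`cells` must have `x_um` and `y_um` columns", call. = FALSE)
  pts <- margin$points_px
  n <- nrow(pts)
  px <- cells$x_um / margin$pixel_size_um
  py <- cells$y_um / margin$pixel_size_um
  phi <- numeric(length(px)); dmin <- numeric(length(px))
  for (i in seq_along(px)) {
    d2 <- (pts[, 1] - px[i])^2 + (pts[, 2] - py[i])^2
    j <- which.min(d2)
    dmin[i] <- sqrt(d2[j])
    phi[i] <- wrap_angle_deg(((j - margin$dorsal_index) %% n) / n * 360)
  }
  inside <- points_in_polygon(px, py, pts)
  cells$phi_deg <- phi
  cells$dist_to_margin_um <- ifelse(inside, 1, -1) * dmin * margin$pixel_size_um
  cells
}

#' Flag yolk syncytial layer nuclei
#'
#' A nucleus is YSL if it lies beyond the margin, or if its Z position is
#' within `z_window_um` of the lowest nucleus among its XY neighbours
#' (within `local_radius_um`). Requires [assign_marginal_position()] first.
#'
#' @param table cell table with `dist_to_margin_um` and `z_um`.
#' @param z_window_um vertical exclusion window above the local lowest
#'   nucleus; 5 um by default.
#' @param local_radius_um XY radius defining "locally"; 30 um by default.
#' @return `table` with a logical `is_ysl` column added.
#' @export
flag_ysl <- function(table, z_window_um = 5, local_radius_um = 30) {
  if (!all(c("dist_to_margin_um", "z_um", "x_um", "y_um") %in% names(table)))
    stop("`table` needs x_um, y_um, z_um and dist_to_margin_um", call. = FALSE)
  stopifnot_scalar(z_window_um, "z_window_um", positive = TRUE)
  stopifnot_scalar(local_radius_um, "local_radius_um", positive = TRUE)
  n <- nrow(table)
  is_ysl <- logical(n)
  if (n > 0) {
    dx <- outer(table$x_um, table$x_um, "-")
    dy <- outer(table$y_um, table$y_um, "-")
    near <- (dx^2 + dy^2) <= local_radius_um^2
    local_min_z <- vapply(seq_len(n), function(i) min(table$z_um[near[i, ]]),
                          numeric(1))
    is_ysl <- (table$dist_to_margin_um < 0) |
      (table$z_um <= local_min_z + z_window_um)
  }
  table$is_ysl <- is_ysl
  table
}

#' Rescale a marginal angle after removing the dorsal DFC band
#'
#' Maps retained positions so the circle stays fully covered after the
#' dorsal band of half-width `dfc_half_width_deg` is cut out:
#' for `phi > 0`, `psi = 180 - s * (180 - phi)`; for `phi < 0`,
#' `psi = -180 - s * (-180 - phi)`, with `s = 180 / (180 - half_width)`
#' (1.25 for the default 36-degree half-width). Angles strictly inside the
#' band map to `NA`.
#'
#' @param phi_deg numeric vector of marginal positions in degrees.
#' @param dfc_half_width_deg half-width of the excluded dorsal band.
#' @return Rescaled positions `psi_deg` covering `(-180, 180]`.
#' @export
#' @examples
#' rescale_margin_angle(c(36, 180, -108))  # 0, 180, -90
rescale_margin_angle <- function(phi_deg, dfc_half_width_deg = 36) {
  stopifnot_scalar(dfc_half_width_deg, "dfc_half_width_deg", positive = TRUE)
  if (dfc_half_width_deg >= 180)
    stop("`dfc_half_width_deg` must be < 180", call. = FALSE)
  s <- 180 / (180 - dfc_half_width_deg)
  psi <- rep(NA_real_, length(phi_deg))
  pos <- !is.na(phi_deg) & phi_deg >= dfc_half_width_deg
  neg <- !is.na(phi_deg) & phi_deg <= -dfc_half_width_deg
  psi[pos] <- 180 - s * (180 - phi_deg[pos])
  psi[neg] <- -180 - s * (-180 - phi_deg[neg])
  psi
}

#' Flag dorsal forerunner cells and rescale remaining positions
#'
#' sox32-positive cells strictly inside the dorsal band (`|phi| <`
#' `dfc_half_width_deg`, the top 20% of the embryo for the default 36
#' degrees) are flagged `is_dfc`. Every cell outside the band receives the
#' rescaled position `psi_deg` (see [rescale_margin_angle()]); cells inside
#' the band get `NA`.
#'
#' @param table cell table with `phi_deg` and a logical sox32 column.
#' @param dfc_half_width_deg half-width of the excluded dorsal band.
#' @param sox32_col name of the logical sox32-positive column.
#' @return `table` with `is_dfc` and `psi_deg` columns added.
#' @export
exclude_and_rescale_dfc <- function(table, dfc_half_width_deg = 36,
                                    sox32_col = "sox32_pos") {
  if (!"phi_deg" %in% names(table))
    stop("`table` needs a `phi_deg` column", call. = FALSE)
  if (!sox32_col %in% names(table))
    stop(sprintf("`table` needs a logical `%s` column", sox32_col), call. = FALSE)
  in_band <- abs(table$phi_deg) < dfc_half_width_deg
  table$is_dfc <- in_band & as.logical(table[[sox32_col]])
  table$psi_deg <- rescale_margin_angle(table$phi_deg, dfc_half_width_deg)
  table
}

#' Assign cell tiers by distance from the margin
#'
#' Tier 1 is the ring of cells within one tier width of the margin, tier 2
#' the next ring, and so on; cells beyond the margin get tier 0.
#'
#' @param table cell table with `dist_to_margin_um`.
#' @param tier_width_um tier width in micrometres; 15 um (about one
#'   blastomere diameter) by default.
#' @return `table` with an integer `tier` column added.
#' @export
assign_tiers <- function(table, tier_width_um = 15) {
  if (!"dist_to_margin_um" %in% names(table))
    stop("`table` needs a `dist_to_margin_um` column", call. = FALSE)
  stopifnot_scalar(tier_width_um, "tier_width_um", positive = TRUE)
  d <- table$dist_to_margin_um
  table$tier <- ifelse(d < 0, 0L, as.integer(floor(d / tier_width_um) + 1L))
  table
}
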