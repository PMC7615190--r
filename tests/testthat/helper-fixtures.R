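# Shared fixtures built in code: small 3D blob stacks, toy cell tables,
# and brute-force oracles kept independent of the implementation paths
# they check.

# Gaussian blobs at given voxel centres in an otherwise dark stack
make_blob_stack <- function(centers, dims, amp = 10000, sigma = 2) {
  arr <- array(0, dim = dims)
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, ]
    ix <- seq_len(dims[1]); iy <- seq_len(dims[2]); iz <- seq_len(dims[3])
    d2 <- outer(outer((ix - cx[1])^2, (iy - cx[2])^2, "+"), (iz - cx[3])^2, "+")
    arr <- arr + amp * exp(-d2 / (2 * sigma^2))
  }
  arr
}

# axis-aligned box of given intensity (half-open voxel index ranges)
make_box_stack <- function(dims, lo, hi, value = 10000, background = 0) {
  arr <- array(background, dim = dims)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- value
  arr
}

# label image with a solid box object per row of `boxes` (lo1,hi1,...)
make_box_labels <- function(dims, boxes) {
  lab <- array(0L, dim = dims)
  for (k in seq_len(nrow(boxes))) {
    b <- boxes[k, ]
    lab[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- k
  }
  lab
}

# independent brute-force oracle for sliding-window conditional proportions
oracle_sliding_proportion <- function(values, positive, window_frac, queries) {
  h <- window_frac * (max(values) - min(values))
  vapply(queries, function(q) {
    hits <- which(values >= q - h & values <= q + h)
    if (length(hits) == 0) NA_real_ else sum(positive[hits]) / length(hits)
  }, numeric(1))
}

# exposed-face surface area by exhaustive voxel enumeration
oracle_surface_area <- function(labels, id) {
  d <- dim(labels)
  faces <- 0L
  idx <- which(labels == id, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      nb <- v + off
      if (any(nb < 1) || any(nb > d) || labels[nb[1], nb[2], nb[3]] != id)
        faces <- faces + 1L
    }
  }
  faces
}

# circular margin boundary in pixel coordinates
circle_margin <- function(radius_px = 100, n = 36, center = c(150, 150),
                          pixel_size_um = 1, dorsal_deg = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + dorsal_deg * pi / 180
  pts <- cbind(x = center[1] + radius_px * cos(th),
               y = center[2] + radius_px * sin(th))
  fit_margin_spline(pts, pixel_size_um, dorsal_hint = pts[1, ])
}
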