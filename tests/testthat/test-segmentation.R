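test_that("adaptive thresholding intersects three orientations", {
  cfg <- segmentation_config(local_window_px = 5)
  zero <- array(0, dim = c(12, 12, 6))
  expect_true(!any(adaptive_threshold_3way(zero, cfg)))

  # single bright cube on dark background (smaller than the window, so every
  # local window sees background and the whole cube clears its local mean)
  stack <- make_box_stack(c(20, 20, 12), c(8, 8, 5), c(11, 11, 8))
  res <- adaptive_threshold_3way(stack, cfg, return_axes = TRUE)
  cube <- array(FALSE, dim = dim(stack))
  cube[8:11, 8:11, 5:8] <- TRUE
  expect_true(all(res$mask[cube]))
  # nothing beyond the cube dilated by the window radius
  far <- array(TRUE, dim = dim(stack))
  far[max(1, 8 - 2):min(20, 11 + 2), max(1, 8 - 2):min(20, 11 + 2),
      max(1, 5 - 2):min(12, 8 + 2)] <- FALSE
  expect_false(any(res$mask[far]))
  # intersection is a subset of every single-orientation mask
  for (m in res$axis_masks) expect_true(all(m[res$mask]))

  expect_error(adaptive_threshold_3way(matrix(0, 3, 3), cfg), "3D")
})

test_that("watershed splits touching nuclei at the intensity saddle", {
  cfg <- segmentation_config(local_window_px = 9, gaussian_sigma_px = 1)
  dims <- c(40, 20, 12)

  # well separated blobs
  far <- make_blob_stack(rbind(c(10, 10, 6), c(30, 10, 6)), dims)
  mask <- far > 3000
  lab <- watershed_split(far, mask, cfg)
  expect_equal(max(lab), 2)

  # touching blobs with a saddle between the peaks
  near <- make_blob_stack(rbind(c(17, 10, 6), c(23, 10, 6)), dims)
  mask_near <- near > 3000
  d <- dim(mask_near)
  expect_equal(max(endomargin:::cpp_label_components(
    as.logical(mask_near), d[1], d[2], d[3], 26L)), 1)  # merged in the mask
  lab_near <- watershed_split(near, mask_near, cfg)
  expect_equal(max(lab_near), 2)

  # single blob: one label, voxels within the input mask
  one <- make_blob_stack(rbind(c(20, 10, 6)), dims)
  mask_one <- one > 3000
  lab_one <- watershed_split(one, mask_one, cfg)
  expect_equal(max(lab_one), 1)
  expect_true(all(mask_one[lab_one > 0]))

  # empty mask is not an error
  empty <- watershed_split(one, array(FALSE, dims), cfg)
  expect_true(all(empty == 0))
})

test_that("object filters enforce the DAPI and flatness rules exactly", {
  cfg <- segmentation_config(erosion_dilation_rounds = 0)
  dims <- c(30, 30, 20)
  # two 8x8x8 cubes (volume 512, surface 384; 1.25*512 = 640 > 384 keeps both
  # on shape) with mean DAPI 999 and 1001: only the dim one is removed
  labels <- make_box_labels(dims, rbind(c(2, 9, 2, 9, 2, 9),
                                        c(15, 22, 15, 22, 2, 9)))
  dapi <- array(0, dim = dims)
  dapi[labels == 1] <- 999
  dapi[labels == 2] <- 1001
  out <- filter_objects(labels, dapi, cfg)
  expect_equal(max(out), 1)
  expect_true(all(out[labels == 2] == 1))
  expect_true(all(out[labels == 1] == 0))

  # flatness: a 4-cube (V=64, SA=96; 80 < 96) is removed as too flat/small,
  # an 8-cube (V=512, SA=384; 640 > 384) is retained
  labels2 <- make_box_labels(dims, rbind(c(2, 5, 2, 5, 2, 5),
                                         c(15, 22, 15, 22, 2, 9)))
  dapi2 <- array(0, dim = dims)
  dapi2[labels2 > 0] <- 5000
  out2 <- filter_objects(labels2, dapi2, cfg)
  expect_equal(max(out2), 1)
  expect_true(all(out2[labels2 == 1] == 0))

  # both rules pass: retained untouched
  labels3 <- make_box_labels(dims, rbind(c(15, 22, 15, 22, 2, 9)))
  out3 <- filter_objects(labels3, dapi2, cfg)
  expect_equal(max(out3), 1)
})

test_that("filter_objects is idempotent on its own output", {
  p <- synthetic_embryo_params(n_nuclei = 15, n_ysl = 0, n_dfc = 0,
                               noise_sd = 0, voxel_size_um = c(0.5, 0.5, 0.5),
                               seed = 8)
  img <- generate_embryo_image(p)
  cfg <- segmentation_config()
  mask <- adaptive_threshold_3way(img$channels$dapi, cfg)
  lab <- watershed_split(img$channels$dapi, mask, cfg, p$voxel_size_um)
  once <- filter_objects(lab, img$channels$dapi, cfg)
  twice <- filter_objects(once, img$channels$dapi, cfg)
  expect_identical(once, twice)
})

test_that("nucleus measurements match brute-force voxel sums", {
  dims <- c(10, 10, 6)
  labels <- array(0L, dim = dims)
  labels[2:4, 2:4, 2:3] <- 1L
  labels[7, 7, 4] <- 2L
  set.seed(1)
  ch1 <- array(runif(prod(dims), 0, 100), dim = dims)
  ch2 <- array(0, dim = dims); ch2[labels == 1L] <- 55
  cells <- measure_nuclei(labels, list(a = ch1, b = ch2), c(0.5, 0.5, 1))

  expect_equal(nrow(cells), 2)
  expect_equal(cells$volume_vox, c(18, 1))
  # 1-voxel object: 6 exposed faces; brute-force check for both
  expect_equal(cells$surface_area[2], 6)
  expect_equal(cells$surface_area, c(oracle_surface_area(labels, 1),
                                     oracle_surface_area(labels, 2)))
  expect_equal(cells$a, c(mean(ch1[labels == 1L]), ch1[7, 7, 4]))
  expect_equal(cells$b, c(55, 0))
  # centroids in micrometres (voxel centres)
  expect_equal(cells$x_um[1], (3 - 0.5) * 0.5)
  expect_equal(cells$z_um[1], (2.5 - 0.5) * 1)

  expect_error(measure_nuclei(labels, list(a = ch1[, , 1:3]), c(1, 1, 1)),
               "shape")
})

test_that("planted uniform nuclei are measured at the planted intensity", {
  p <- synthetic_embryo_params(n_nuclei = 20, n_ysl = 0, n_dfc = 0,
                               noise_sd = 200, voxel_size_um = c(0.5, 0.5, 0.5),
                               seed = 12)
  img <- generate_embryo_image(p)
  # measure a constant synthetic channel under the true labels: the mean must
  # equal the constant to noise_sd / sqrt(volume) accuracy
  truth_labels <- img$truth$label_image
  set.seed(12)
  const <- array(700, dim = dim(truth_labels)) +
    array(rnorm(length(truth_labels), 0, 200), dim = dim(truth_labels))
  cells <- measure_nuclei(truth_labels, list(marker = const), p$voxel_size_um)
  tol <- 3 * 200 / sqrt(min(cells$volume_vox))
  expect_true(all(abs(cells$marker - 700) < tol))
})
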