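test_that("the margin spline resamples a circle at unit-pixel spacing", {
  m <- circle_margin(radius_px = 100, n = 36)
  expect_equal(m$length_px, 2 * pi * 100, tolerance = 0.01)
  gaps <- sqrt(rowSums((m$points_px - m$points_px[c(2:nrow(m$points_px), 1), ])^2))
  expect_true(all(abs(gaps - 1) < 0.01))
  # dorsal hint on the curve resolves to the nearest resampled point
  expect_lt(sqrt(sum((m$points_px[m$dorsal_index, ] - c(250, 150))^2)), 1)

  expect_error(fit_margin_spline(cbind(c(0, 1, 2), c(0, 1, 0)), 1, c(0, 0)),
               "at least 4")
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(fit_margin_spline(bowtie, 1, c(0, 0)), "self-intersecting")
})

test_that("marginal positions measure signed arc fraction from dorsal", {
  m <- circle_margin(radius_px = 100, n = 48)
  mk <- function(deg, r = 95) {
    th <- deg * pi / 180
    data.frame(x_um = 150 + r * cos(th), y_um = 150 + r * sin(th), z_um = 0)
  }
  at_dorsal <- assign_marginal_position(mk(0, 100), m)
  expect_equal(at_dorsal$phi_deg, 0, tolerance = 0.5)
  antipode <- assign_marginal_position(mk(180, 100), m)
  expect_equal(abs(antipode$phi_deg), 180, tolerance = 0.5)
  planted <- assign_marginal_position(mk(73), m)
  expect_equal(planted$phi_deg, 73, tolerance = 1)
  # inside vs beyond the margin
  expect_gt(planted$dist_to_margin_um, 0)
  outside <- assign_marginal_position(mk(30, r = 110), m)
  expect_lt(outside$dist_to_margin_um, 0)
  expect_equal(abs(outside$dist_to_margin_um), 10, tolerance = 0.5)
})

test_that("rotating the scene leaves marginal positions unchanged", {
  set.seed(4)
  angles <- runif(25, -180, 180)
  radii <- runif(25, 80, 98)
  for (rot in c(0, 40)) {
    th0 <- rot * pi / 180
    pts_th <- seq(0, 2 * pi, length.out = 37)[-37] + th0
    boundary <- cbind(150 + 100 * cos(pts_th), 150 + 100 * sin(pts_th))
    m <- fit_margin_spline(boundary, 1, boundary[1, ])
    cells <- data.frame(
      x_um = 150 + radii * cos((angles + rot) * pi / 180),
      y_um = 150 + radii * sin((angles + rot) * pi / 180), z_um = 0)
    phi <- assign_marginal_position(cells, m)$phi_deg
    if (rot == 0) phi0 <- phi
    expect_true(all(abs(wrap_angle_deg(phi - phi0)) < 1))
  }
})

test_that("YSL flagging combines the beyond-margin and local-Z rules", {
  m <- circle_margin(radius_px = 100, n = 36)
  cells <- data.frame(
    x_um = c(253, 240, 240, 240),   # first is 3 um beyond the margin
    y_um = c(150, 150, 150, 150),
    z_um = c(0, 0, 4, 10))
  tab <- assign_marginal_position(cells, m)
  tab <- flag_ysl(tab, z_window_um = 5, local_radius_um = 30)
  expect_true(tab$is_ysl[1])    # beyond the margin
  expect_true(tab$is_ysl[2])    # the locally lowest nucleus itself
  expect_true(tab$is_ysl[3])    # 4 um above the local lowest
  expect_false(tab$is_ysl[4])   # 10 um above the local lowest
})

test_that("the DFC rescale formula has the printed fixed points", {
  expect_identical(rescale_margin_angle(180), 180)
  expect_identical(rescale_margin_angle(36), 0)
  expect_identical(rescale_margin_angle(-36), 0)
  expect_identical(rescale_margin_angle(-108), -90)
  expect_identical(rescale_margin_angle(-180), -180)
  expect_true(is.na(rescale_margin_angle(0)))
  # strictly increasing on each half
  pos <- rescale_margin_angle(seq(36, 180, by = 0.5))
  neg <- rescale_margin_angle(seq(-180, -36, by = 0.5))
  expect_true(all(diff(pos) > 0))
  expect_true(all(diff(neg) > 0))
  # retained range maps onto the full circle
  expect_equal(range(c(pos, neg)), c(-180, 180))
})

test_that("DFC exclusion flags dorsal sox32 cells and rescales the rest", {
  tab <- data.frame(phi_deg = c(0, 20, -35, 36, 90, -170),
                    sox32_pos = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  out <- exclude_and_rescale_dfc(tab)
  expect_equal(out$is_dfc, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(is.na(out$psi_deg[1:3])))
  expect_equal(out$psi_deg[4:6], rescale_margin_angle(c(36, 90, -170)))
})

test_that("rescaling preserves circular uniformity of the retained cells", {
  set.seed(10)
  pass <- replicate(100, {
    phi <- runif(300, -180, 180)
    phi <- phi[abs(phi) >= 36]
    watson_u2(rescale_margin_angle(phi), method = "asymptotic")$p_value >= 0.01
  })
  expect_gte(mean(pass), 0.96)
})

test_that("tier assignment partitions cells by margin distance", {
  tab <- data.frame(dist_to_margin_um = c(0, 22.5, -3, 14.99, 15, 150))
  out <- assign_tiers(tab, tier_width_um = 15)
  expect_equal(out$tier, c(1L, 2L, 0L, 1L, 2L, 11L))
  # conservation: every inside-margin cell gets exactly one positive tier
  set.seed(2)
  d <- runif(500, -20, 160)
  tiers <- assign_tiers(data.frame(dist_to_margin_um = d))$tier
  expect_equal(sum(tiers == 0), sum(d < 0))
  expect_equal(sum(tiers > 0), sum(d >= 0))
  expect_equal(as.integer(sum(table(tiers))), 500L)
})
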