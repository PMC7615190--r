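coarse_params <- function(...) {
  synthetic_embryo_params(voxel_size_um = c(0.5, 0.5, 0.5), ...)
}

test_that("an empty embryo renders pure noise with empty truth", {
  p <- coarse_params(n_nuclei = 0, n_ysl = 0, n_dfc = 0, noise_sd = 0, seed = 1)
  img <- generate_embryo_image(p)
  expect_equal(nrow(img$truth$centroids_um), 0)
  expect_true(all(img$channels$dapi == 0))
  expect_true(all(img$truth$label_image == 0))

  p2 <- coarse_params(n_nuclei = 0, n_ysl = 0, n_dfc = 0, noise_sd = 50, seed = 1)
  img2 <- generate_embryo_image(p2)
  expect_gt(sd(img2$channels$dapi), 0)
})

test_that("noiseless nuclei render as distinct bright components", {
  p <- coarse_params(n_nuclei = 50, n_ysl = 0, n_dfc = 0, noise_sd = 0, seed = 42)
  img <- generate_embryo_image(p)
  m <- img$channels$dapi > p$dapi_mean / 2
  d <- dim(m)
  lab <- endomargin:::cpp_label_components(as.logical(m), d[1], d[2], d[3], 26L)
  expect_equal(max(lab), 50)
})

test_that("generators are seed-deterministic and honour requested counts", {
  p <- coarse_params(n_nuclei = 12, n_ysl = 5, n_dfc = 3, seed = 7)
  a <- generate_embryo_image(p)
  b <- generate_embryo_image(p)
  expect_identical(a$channels$dapi, b$channels$dapi)
  expect_identical(a$truth$centroids_um, b$truth$centroids_um)
  expect_equal(as.vector(table(a$truth$class)[c("embryonic", "YSL", "DFC")]),
               c(12, 5, 3))
  # classes are mutually exclusive, one entry per planted nucleus
  expect_equal(length(a$truth$class), 20)
  expect_equal(sum(a$truth$sox32), 3)  # only DFCs are sox32-bright in the image
})

test_that("YSL nuclei sit beyond the margin at the lowest Z", {
  p <- coarse_params(n_nuclei = 20, n_ysl = 8, n_dfc = 0, seed = 3)
  img <- generate_embryo_image(p)
  tr <- img$truth
  r <- sqrt((tr$centroids_um[, 1] - tr$center_um[1])^2 +
              (tr$centroids_um[, 2] - tr$center_um[2])^2)
  expect_true(all(r[tr$class == "YSL"] > p$margin_radius_um))
  expect_true(all(r[tr$class == "embryonic"] < p$margin_radius_um))
  expect_lt(max(tr$centroids_um[tr$class == "YSL", 3]),
            min(tr$centroids_um[tr$class == "embryonic", 3]) - 5)
})

test_that("cell-table hazard limits are exact", {
  emb <- synthetic_embryo_params(n_nuclei = 200, seed = 1)
  off <- generate_cell_table(emb, synthetic_signaling_params(
    hazard_intercept = -Inf, hazard_smad2_coef = 0, hazard_erk_coef = 0,
    seed = 1))
  expect_equal(sum(off$table$sox32_pos), 0)
  on <- generate_cell_table(emb, synthetic_signaling_params(
    hazard_intercept = Inf, hazard_smad2_coef = 0, hazard_erk_coef = 0,
    n_steps = 1, seed = 1))
  expect_true(all(on$table$sox32_pos))
})

test_that("constant hazard reproduces the closed-form positive fraction", {
  h <- 0.01
  n_steps <- 20
  emb <- synthetic_embryo_params(n_nuclei = 10000, seed = 2)
  gen <- generate_cell_table(emb, synthetic_signaling_params(
    hazard_intercept = qlogis(h), hazard_smad2_coef = 0, hazard_erk_coef = 0,
    n_steps = n_steps, seed = 2))
  p_expected <- 1 - (1 - h)^n_steps
  se <- sqrt(p_expected * (1 - p_expected) / 10000)
  expect_lt(abs(mean(gen$table$sox32_pos) - p_expected), 3 * se)
  expect_equal(unique(gen$table$true_hazard), h, tolerance = 1e-12)
})

test_that("cell tables record the generating truth and tier layout", {
  gen <- generate_cell_table(synthetic_embryo_params(n_nuclei = 500, seed = 4),
                             synthetic_signaling_params(seed = 4))
  tab <- gen$table
  expect_equal(gen$truth$hazard_smad2_coef, 8e-4)
  expect_true(all(tab$tier == floor(tab$dist_to_margin_um / 15) + 1))
  expect_true(all(tab$smad2 > 0) && all(tab$erk > 0))
  # P-Smad2 decays with distance from the margin
  expect_gt(mean(tab$smad2[tab$tier <= 2]), 3 * mean(tab$smad2[tab$tier >= 9]))
})

test_that("gut profiles share the template and respond to dose", {
  clean <- generate_gut_profiles(n_embryos = 3, doses = c(0, 1),
                                 dose_effect = function(d) 1,
                                 noise_sd = 0, seed = 1)
  tmpl <- gut_profile_template(seq(0, 1, length.out = 100))
  for (e in unique(clean$embryo))
    expect_equal(clean$intensity[clean$embryo == e], tmpl)

  a <- generate_gut_profiles(seed = 5)
  b <- generate_gut_profiles(seed = 5)
  expect_identical(a, b)

  # halved amplitude at max dose moves profiles away from the untreated mean
  prof <- generate_gut_profiles(n_embryos = 4, doses = c(0, 1),
                                dose_effect = function(d) 1 - 0.5 * d,
                                noise_sd = 0.02, seed = 9)
  dev <- dose_deviations(prof)
  expect_gt(mean(dev$deviation[dev$dose == 1]),
            mean(dev$deviation[dev$dose == 0]))
})

test_that("parameter validation rejects impossible embryos", {
  expect_error(synthetic_embryo_params(n_nuclei = -1), ">=")
  expect_error(synthetic_embryo_params(voxel_size_um = c(0.1, 0.1)), "three")
  expect_error(synthetic_embryo_params(nucleus_radius_um = 50,
                                       margin_radius_um = 40), "smaller")
  # overcrowded placement signals generation failure
  p <- coarse_params(n_nuclei = 400, n_ysl = 0, n_dfc = 0,
                     margin_radius_um = 20, band_width_um = 5, seed = 1)
  expect_error(generate_embryo_image(p), "failed")
})
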