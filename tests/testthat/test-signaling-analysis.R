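test_that("background thresholds use the interpolated quantile convention", {
  set.seed(1)
  tab <- data.frame(tier = rep(c(1, 9, 10), each = 50),
                    smad2 = c(rnorm(50, 5000, 100), rep(7, 100)))
  expect_equal(background_threshold(tab), 7)

  tab2 <- data.frame(tier = rep(10, 100), smad2 = 1:100)
  expect_equal(background_threshold(tab2), 99.01)
  expect_equal(background_threshold(tab2, percentile = 100), 100)
  expect_error(background_threshold(data.frame(tier = 1, smad2 = 1)),
               "no cells")
})

test_that("elevated fractions count strict exceedances in tiers 1-2", {
  tab <- data.frame(tier = rep(c(1, 2, 5), c(5, 5, 10)),
                    smad2 = c(1:10, rep(100, 10)))
  expect_equal(elevated_fraction(tab, threshold = 0), 1)
  expect_equal(elevated_fraction(tab, threshold = 1e6), 0)
  expect_equal(elevated_fraction(tab, threshold = 7), 0.3)
  # per-embryo thresholds averaged across embryos
  tab$embryo <- rep(1:2, 10)
  tab$tier <- 10
  th <- mean_background_threshold(tab, percentile = 100)
  expect_equal(th, mean(c(max(tab$smad2[tab$embryo == 1]),
                          max(tab$smad2[tab$embryo == 2]))))
})

test_that("sliding proportions match the brute-force oracle exactly", {
  pr <- sliding_proportion(c(0, 100), c(FALSE, TRUE), query_levels = c(0, 100))
  expect_equal(pr$proportion, c(0, 1))

  set.seed(3)
  all_pos <- sliding_proportion(runif(50), rep(TRUE, 50))
  expect_true(all(all_pos$proportion[!is.na(all_pos$proportion)] == 1))

  # empty window reports NA, not zero
  gap <- sliding_proportion(c(0, 0.1, 100), c(TRUE, TRUE, FALSE),
                            window_frac = 0.01, query_levels = 50)
  expect_true(is.na(gap$proportion))
  expect_equal(gap$n_in_window, 0L)

  set.seed(8)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    v <- runif(n, 0, sample(c(1, 100, 1e4), 1))
    pos <- runif(n) < 0.4
    wf <- runif(1, 0.02, 0.2)
    q <- runif(12, min(v) - 5, max(v) + 5)
    got <- sliding_proportion(v, pos, wf, q)
    expect_identical(got$proportion, oracle_sliding_proportion(v, pos, wf, q))
  }
  expect_warning(sliding_proportion(rep(3, 5), rep(TRUE, 5)), "halfwidth")
})

test_that("stratified profiles restrict then slide", {
  set.seed(2)
  tab <- data.frame(erk = runif(30), smad2 = runif(30),
                    sox32_pos = rep(c(TRUE, FALSE), 15))
  none <- conditional_profile_stratified(tab, "erk", rep(FALSE, 30))
  expect_equal(nrow(none), 0)
  all_q <- seq(0, 1, length.out = 20)
  full <- conditional_profile_stratified(tab, "erk", rep(TRUE, 30),
                                         query_levels = all_q)
  plain <- sliding_proportion(tab$erk, tab$sox32_pos, query_levels = all_q)
  expect_equal(full$proportion, plain$proportion)
})

test_that("the joint signaling map reflects the generating hazard", {
  gen <- generate_cell_table(synthetic_embryo_params(n_nuclei = 8000, seed = 13),
                             synthetic_signaling_params(seed = 13))
  tab <- gen$table
  jm <- joint_signaling_map(tab, n_bins = 20)
  expect_true(all(jm$proportion >= 0 & jm$proportion <= 1, na.rm = TRUE))
  expect_true(any(is.na(jm$proportion)) || all(jm$n_per_cell > 0))
  # increasing along P-Smad2 (rows), decreasing along P-Erk (columns):
  # population-weighted means of the low vs high populated thirds
  wmean <- function(prop, w) sum(prop * w, na.rm = TRUE) / sum(w[!is.na(prop)])
  rows <- which(rowSums(jm$n_per_cell) >= 100)
  r3 <- max(2, floor(length(rows) / 3))
  lo_r <- rows[seq_len(r3)]; hi_r <- rows[(length(rows) - r3 + 1):length(rows)]
  expect_gt(wmean(jm$proportion[hi_r, ], jm$n_per_cell[hi_r, ]),
            wmean(jm$proportion[lo_r, ], jm$n_per_cell[lo_r, ]))
  cols <- which(colSums(jm$n_per_cell) >= 100)
  c3 <- max(2, floor(length(cols) / 3))
  lo_c <- cols[seq_len(c3)]; hi_c <- cols[(length(cols) - c3 + 1):length(cols)]
  expect_lt(wmean(jm$proportion[, hi_c], jm$n_per_cell[, hi_c]),
            wmean(jm$proportion[, lo_c], jm$n_per_cell[, lo_c]))

  # all-positive table maps to 1 wherever defined
  tab2 <- tab[1:500, ]; tab2$sox32_pos <- TRUE
  jm2 <- joint_signaling_map(tab2, n_bins = 10)
  expect_true(all(jm2$proportion == 1, na.rm = TRUE))
})

test_that("marginalising the joint map recovers the 1D profile", {
  gen <- generate_cell_table(synthetic_embryo_params(n_nuclei = 6000, seed = 17),
                             synthetic_signaling_params(seed = 17))
  tab <- gen$table
  jm <- joint_signaling_map(tab, n_bins = 25)
  marg <- vapply(seq_along(jm$smad2_levels), function(i) {
    w <- jm$n_per_cell[i, ]
    if (sum(w) == 0) NA_real_
    else sum(jm$proportion[i, ] * w, na.rm = TRUE) / sum(w)
  }, numeric(1))
  p1d <- sliding_proportion(tab$smad2, tab$sox32_pos,
                            query_levels = jm$smad2_levels)
  expect_lt(mean(abs(marg - p1d$proportion), na.rm = TRUE), 0.03)
})

test_that("the cumulative-hazard fit recovers the generating coefficients", {
  gen <- generate_cell_table(synthetic_embryo_params(n_nuclei = 10000, seed = 5),
                             synthetic_signaling_params(seed = 5))
  fit <- fit_induction_hazard(gen$table, n_steps = gen$truth$n_steps)
  expect_true(fit$converged)
  expect_gt(fit$smad2_coef, 0)
  expect_lt(fit$erk_coef, 0)
  expect_lt(abs(fit$smad2_coef - gen$truth$hazard_smad2_coef) /
              gen$truth$hazard_smad2_coef, 0.2)
  expect_lt(abs(fit$erk_coef - gen$truth$hazard_erk_coef) /
              abs(gen$truth$hazard_erk_coef), 0.2)
})
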