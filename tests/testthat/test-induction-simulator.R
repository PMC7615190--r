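test_that("default scheme doubles the founder array with one division per rank", {
  res <- run_simulation(sim_params(seed = 11))
  expect_equal(res$total_final, 1000)
  expect_equal(length(res$positive_count_by_step), 500)
  expect_false(is.unsorted(res$positive_count_by_step))
  # every rank divides exactly once: each lineage contributes 2 final cells
  expect_true(all(table(res$final_cells$lineage_rank) == 2))
  # angles equally spaced around the circle with the ends at 0
  ang <- res$final_cells$angle_deg
  expect_equal(sort(unique(round(diff(ang[order(ang)]), 9))), 0.36)
})

test_that("degenerate induction probabilities behave as limits", {
  res0 <- run_simulation(sim_params(p_induction = 0, seed = 1))
  expect_true(all(res0$positive_count_by_step == 0))
  expect_false(any(res0$final_cells$sox32))

  res1 <- run_simulation(sim_params(p_induction = 1, seed = 1))
  # after step 1 every current cell is on; counts track the array census
  expect_equal(res1$positive_count_by_step[1], 501)
  expect_true(all(res1$final_cells$sox32))
  expect_equal(expected_positive_count(sim_params(p_induction = 0)), 0)
  expect_equal(expected_positive_count(sim_params(p_induction = 1)), 1000)
})

test_that("runs are seeded-deterministic and ensembles share the stream", {
  a <- run_simulation(sim_params(seed = 99))
  b <- run_simulation(sim_params(seed = 99))
  expect_identical(a$final_cells, b$final_cells)
  expect_identical(a$positive_count_by_step, b$positive_count_by_step)

  ens <- simulate_ensemble(sim_params(seed = 99), n_runs = 1)
  expect_identical(ens$results[[1]]$final_cells, a$final_cells)
  expect_equal(ens$summaries$n_positive, sum(a$final_cells$sox32))
})

test_that("Monte-Carlo positives match the closed-form oracle", {
  p <- sim_params(n_founders = 100, n_steps = 100, p_induction = 0.002,
                  seed = 5)
  ens <- simulate_ensemble(p, n_runs = 200)
  m <- mean(ens$summaries$n_positive)
  se <- sd(ens$summaries$n_positive) / sqrt(200)
  expect_lt(abs(m - expected_positive_count(p)), 3 * se)
})

test_that("induction order within a step does not shift the positive count", {
  pa <- sim_params(n_founders = 200, n_steps = 200, p_induction = 0.001,
                   seed = 2, order = "induce_then_divide")
  pb <- sim_params(n_founders = 200, n_steps = 200, p_induction = 0.001,
                   seed = 2, order = "divide_then_induce")
  na <- mean(simulate_ensemble(pa, 150)$summaries$n_positive)
  nb <- mean(simulate_ensemble(pb, 150)$summaries$n_positive)
  mu <- expected_positive_count(pa)
  # both orders give each lineage exactly n_steps trials
  expect_lt(abs(na - mu), 3 * sqrt(mu) / sqrt(150) * 1.5)
  expect_lt(abs(nb - mu), 3 * sqrt(mu) / sqrt(150) * 1.5)
})

test_that("induction events collapse inherited sibling pairs", {
  res <- run_simulation(sim_params(seed = 21))
  fc <- res$final_cells
  ev <- induction_event_angles(res)
  expect_lte(length(ev), sum(fc$sox32))
  expect_equal(length(ev), length(unique(fc$event_id[fc$sox32])))
  # every positive cell has an event; negatives have none
  expect_false(anyNA(fc$event_id[fc$sox32]))
  expect_true(all(is.na(fc$event_id[!fc$sox32])))
  # cells sharing an event are adjacent siblings of one lineage
  shared <- names(which(table(fc$event_id) == 2))
  for (e in shared) {
    rows <- which(fc$event_id == as.integer(e))
    expect_equal(diff(rows), 1)
    expect_equal(length(unique(fc$lineage_rank[rows])), 1)
  }
})

test_that("sibling inheritance inflates cell-level Watson rejection above event level", {
  ens <- simulate_ensemble(sim_params(seed = 31), n_runs = 300)
  set.seed(31)
  cell_p <- vapply(ens$results, function(r) {
    ang <- r$final_cells$angle_deg[r$final_cells$sox32]
    if (length(ang) < 8) return(NA_real_)
    watson_u2(ang)$p_value
  }, numeric(1))
  event_p <- vapply(ens$results, function(r) {
    ang <- induction_event_angles(r)
    if (length(ang) < 8) return(NA_real_)
    watson_u2(ang)$p_value
  }, numeric(1))
  cell_rate <- mean(cell_p < 0.05, na.rm = TRUE)
  event_rate <- mean(event_p < 0.05, na.rm = TRUE)
  expect_gt(cell_rate, event_rate + 0.03)
  expect_lt(event_rate, 0.10)
})
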