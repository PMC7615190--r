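# Signaling-conditional analysis: how nuclear P-Smad2 / P-Erk levels relate
# to sox32 status. Background thresholds from deep cell tiers, elevated
# fractions at the margin, sliding-window conditional proportions, the joint
# 2D signaling map, and a cumulative-hazard logistic fit that recovers the
# generating coefficients from synthetic tables.

#' Background intensity threshold from deep cell tiers
#'
#' The stated percentile (99th by default) of a channel over cells in the
#' background tiers (9-10 by default), used to define "elevated" signaling
#' at the margin. Quantiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param table cell table with `tier` and the channel column.
#' @param channel channel column name; `"smad2"` by default.
#' @param tiers background tiers; `c(9, 10)` by default.
#' @param percentile percentile in `[0, 100]`; 99 by default.
#' @return Intensity threshold (scalar).
#' @export
background_threshold <- function(table, channel = "smad2", tiers = c(9, 10),
                                 percentile = 99) {
  if (!all(c("tier", channel) %in% names(table)))
    stop("`table` needs `tier` and the channel column", call. = FALSE)
  stopifnot_scalar(percentile, "percentile")
  if (percentile < 0 || percentile > 100)
    stop("`percentile` must be in [0, 100]", call. = FALSE)
  v <- table[[channel]][table$tier %in% tiers]
  if (length(v) == 0)
    stop("no cells in the background tiers", call. = FALSE)
  unname(quantile(v, percentile / 100, type = 7, names = FALSE))
}

#' Fraction of marginal cells with elevated signal
#'
#' Fraction of cells in the stated tiers (1-2 by default) whose channel
#' intensity exceeds the threshold. For multi-embryo datasets the threshold
#' is typically the mean of per-embryo background thresholds; see
#' [mean_background_threshold()].
#'
#' @param table cell table with `tier` and the channel column.
#' @param threshold intensity threshold (strictly exceeded = elevated).
#' @param channel channel column name.
#' @param tiers marginal tiers; `c(1, 2)` by default.
#' @return Fraction in `[0, 1]` (`NA` if no cells in the tiers).
#' @export
elevated_fraction <- function(table, threshold, channel = "smad2",
                              tiers = c(1, 2)) {
  if (!all(c("tier", channel) %in% names(table)))
    stop("`table` needs `tier` and the channel column", call. = FALSE)
  stopifnot_scalar(threshold, "threshold")
  v <- table[[channel]][table$tier %in% tiers]
  if (length(v) == 0) return(NA_real_)
  mean(v > threshold)
}

#' Mean of per-embryo background thresholds
#'
#' Computes [background_threshold()] separately per embryo and averages,
#' defining one "elevated" cutoff shared by all embryos of a dataset.
#'
#' @param table cell table with an `embryo` column plus what
#'   [background_threshold()] needs.
#' @param ... passed to [background_threshold()].
#' @return Mean threshold (scalar).
#' @export
mean_background_threshold <- function(table, ...) {
  if (!"embryo" %in% names(table))
    stop("`table` needs an `embryo` column", call. = FALSE)
  ths <- vapply(split(table, table$embryo), background_threshold,
                numeric(1), ...)
  mean(ths)
}

#' Sliding-window conditional proportion positive
#'
#' For each query level, the proportion of positive cells among all cells
#' whose value lies within `window_frac` of the total observed range
#' (a +/- 5% window by default). Queries with an empty window report `NA`,
#' never zero.
#'
#' @param values numeric vector of signaling levels.
#' @param positive logical vector of the same length.
#' @param window_frac half-width of the window as a fraction of
#'   `max(values) - min(values)`; 0.05 by default.
#' @param query_levels levels at which to evaluate; defaults to 100 evenly
#'   spaced points across the observed range.
#' @return An object of class `conditional_profile`: data.frame with
#'   `query`, `proportion`, `n_in_window`, and attributes
#'   `window_halfwidth`, `window_frac`.
#' @export
sliding_proportion <- function(values, positive, window_frac = 0.05,
                               query_levels = NULL) {
  if (length(values) < 1L || length(values) != length(positive))
    stop("`values` and `positive` must be non-empty and equal length", call. = FALSE)
  stopifnot_scalar(window_frac, "window_frac", positive = TRUE)
  positive <- as.logical(positive)
  rng <- range(values)
  halfwidth <- window_frac * diff(rng)
  if (diff(rng) == 0)
    warning("all values identical: window halfwidth is 0", call. = FALSE)
  if (is.null(query_levels))
    query_levels <- seq(rng[1], rng[2], length.out = 100L)
  prop <- rep(NA_real_, length(query_levels))
  n_in <- integer(length(query_levels))
  for (i in seq_along(query_levels)) {
    sel <- abs(values - query_levels[i]) <= halfwidth
    n_in[i] <- sum(sel)
    if (n_in[i] > 0) prop[i] <- mean(positive[sel])
  }
  structure(
    data.frame(query = query_levels, proportion = prop, n_in_window = n_in),
    window_halfwidth = halfwidth, window_frac = window_frac,
    class = c("conditional_profile", "data.frame")
  )
}

#' Conditional proportion profile stratified by a condition
#'
#' Restricts the table to cells passing `condition` (e.g. elevated P-Smad2
#' in tiers 1-2), then computes the sliding-window proportion of
#' sox32-positive cells along `channel`.
#'
#' @param table cell table.
#' @param channel channel whose level the profile runs along; `"erk"` by
#'   default.
#' @param condition logical vector (recycled from the table rows) selecting
#'   the stratum.
#' @param positive_col logical column defining positivity
#'   (`"sox32_pos"` by default).
#' @param ... passed to [sliding_proportion()].
#' @return A `conditional_profile` (empty data.frame if no cell passes).
#' @export
conditional_profile_stratified <- function(table, channel = "erk", condition,
                                           positive_col = "sox32_pos", ...) {
  if (!all(c(channel, positive_col) %in% names(table)))
    stop("missing channel or positive column", call. = FALSE)
  condition <- as.logical(condition)
  sub <- table[condition & !is.na(condition), , drop = FALSE]
  if (nrow(sub) == 0) {
    return(structure(
      data.frame(query = numeric(0), proportion = numeric(0),
                 n_in_window = integer(0)),
      window_halfwidth = NA_real_, window_frac = NA_real_,
      class = c("conditional_profile", "data.frame")
    ))
  }
  sliding_proportion(sub[[channel]], sub[[positive_col]], ...)
}

#' Joint 2D signaling map of proportion positive
#'
#' Proportion of positive cells over a grid of (P-Smad2, P-Erk) levels,
#' using a product window: at each grid point, all cells within the +/- 5%
#' -of-range window on both axes. Marginalising the map over the second
#' axis (weighted by counts) reproduces the 1D profile up to
#' window-discretisation error.
#'
#' @param table cell table with both channels and the positive flag.
#' @param smad2_col,erk_col channel column names.
#' @param positive_col logical positive column.
#' @param n_bins grid points per axis (default 50).
#' @param window_frac per-axis window half-width as fraction of that
#'   channel's range (default 0.05).
#' @return An object of class `joint_signaling_map`: list with
#'   `smad2_levels`, `erk_levels`, `proportion` (matrix, `NA` where no
#'   cells) and `n_per_cell`.
#' @export
joint_signaling_map <- function(table, smad2_col = "smad2", erk_col = "erk",
                                positive_col = "sox32_pos", n_bins = 50L,
                                window_frac = 0.05) {
  for (cl in c(smad2_col, erk_col, positive_col))
    if (!cl %in% names(table))
      stop(sprintf("missing column `%s`", cl), call. = FALSE)
  n_bins <- stopifnot_count(n_bins, "n_bins", min = 2L)
  s <- table[[smad2_col]]; e <- table[[erk_col]]
  pos <- as.logical(table[[positive_col]])
  s_lv <- seq(min(s), max(s), length.out = n_bins)
  e_lv <- seq(min(e), max(e), length.out = n_bins)
  hs <- window_frac * diff(range(s))
  he <- window_frac * diff(range(e))
  prop <- matrix(NA_real_, n_bins, n_bins)
  cnt <- matrix(0L, n_bins, n_bins)
  for (i in seq_len(n_bins)) {
    in_s <- abs(s - s_lv[i]) <= hs
    if (!any(in_s)) next
    es <- e[in_s]; ps <- pos[in_s]
    for (j in seq_len(n_bins)) {
      sel <- abs(es - e_lv[j]) <= he
      nij <- sum(sel)
      cnt[i, j] <- nij
      if (nij > 0) prop[i, j] <- mean(ps[sel])
    }
  }
  structure(list(smad2_levels = s_lv, erk_levels = e_lv,
                 proportion = prop, n_per_cell = cnt,
                 window_halfwidth = c(smad2 = hs, erk = he)),
            class = "joint_signaling_map")
}

#' Fit the per-step induction hazard from a cell table
#'
#' Maximum-likelihood fit of the cumulative-hazard model
#' \eqn{P(sox32+) = 1 - (1 - logit^{-1}(a + b\,Smad2 + c\,Erk))^{T}}
#' to observed sox32 status, i.e. the per-step logistic hazard integrated
#' over `n_steps` competency steps. Started from a complementary-log-log
#' GLM (exact in the small-hazard limit) and refined by BFGS.
#'
#' @param table cell table with the two channels and the positive flag.
#' @param n_steps number of competency steps `T` the cells experienced.
#' @param smad2_col,erk_col,positive_col column names.
#' @return List with `intercept`, `smad2_coef`, `erk_coef`,
#'   `log_likelihood`, `converged`.
#' @export
fit_induction_hazard <- function(table, n_steps, smad2_col = "smad2",
                                 erk_col = "erk", positive_col = "sox32_pos") {
  n_steps <- stopifnot_count(n_steps, "n_steps", min = 1L)
  s <- table[[smad2_col]]; e <- table[[erk_col]]
  y <- as.numeric(table[[positive_col]])
  # scale covariates for a well-conditioned optimisation
  ss <- sd(s); se <- sd(e)
  if (ss == 0 || se == 0) stop("degenerate covariates", call. = FALSE)
  zs <- (s - mean(s)) / ss
  ze <- (e - mean(e)) / se
  nll <- function(par) {
    h <- plogis(par[1] + par[2] * zs + par[3] * ze)
    pr <- 1 - (1 - h)^n_steps
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(y * log(pr) + (1 - y) * log(1 - pr))
  }
  start <- tryCatch({
    g <- suppressWarnings(glm(y ~ zs + ze, family = binomial(link = "cloglog")))
    cf <- coef(g)
    c(cf[1] - log(n_steps), cf[2], cf[3])
  }, error = function(err) c(-log(n_steps) - 2, 0, 0))
  fit <- optim(start, nll, method = "BFGS", control = list(maxit = 500))
  b_s <- fit$par[2] / ss
  b_e <- fit$par[3] / se
  a <- fit$par[1] - b_s * mean(s) - b_e * mean(e)
  list(intercept = unname(a), smad2_coef = unname(b_s),
       erk_coef = unname(b_e), log_likelihood = -fit$value,
       converged = fit$convergence == 0)
}
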