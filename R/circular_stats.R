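# Circular statistics for marginal positions: per-embryo direction vectors,
# direction bias (mean resultant length), angular histograms, and Watson's
# U2 test of circular uniformity.

#' Summarise a set of marginal angles as a direction vector
#'
#' Sums the unit vectors pointing at each angle. The direction bias is the
#' mean resultant length \eqn{|\sum_i u_i| / n}: 1 when all cells share one
#' angle, approaching 0 for a uniform spread. When the resultant is
#' numerically zero (e.g. antipodal pairs) the mean angle is undefined and
#' reported as `NA`.
#'
#' @param angles_deg numeric vector of angles in degrees (any wrap).
#' @return An object of class `direction_summary`: a list with
#'   `mean_angle_deg`, `bias` (in `[0, 1]`), `resultant_length`
#'   (unnormalised \eqn{|\sum u_i|}) and `n`.
#' @export
#' @examples
#' direction_summary(c(0, 90))  # mean 45 degrees, bias sqrt(2)/2
direction_summary <- function(angles_deg) {
  if (length(angles_deg) < 1L || anyNA(angles_deg))
    stop("direction_summary() needs at least one non-missing angle", call. = FALSE)
  th <- deg2rad(angles_deg)
  C <- sum(cos(th)); S <- sum(sin(th))
  n <- length(th)
  R <- sqrt(C^2 + S^2)
  mean_angle <- if (R / n < 1e-10) NA_real_ else wrap_angle_deg(rad2deg(atan2(S, C)))
  structure(
    list(mean_angle_deg = mean_angle, bias = R / n, resultant_length = R, n = n),
    class = "direction_summary"
  )
}

#' @export
print.direction_summary <- function(x, ...) {
  cat(sprintf("Direction summary: n = %d, bias = %.4f, mean angle = %s deg\n",
              x$n, x$bias,
              if (is.na(x$mean_angle_deg)) "NA" else sprintf("%.2f", x$mean_angle_deg)))
  invisible(x)
}

# Watson's U2 statistic for values already mapped to [0, 1), given as the
# columns of a matrix (each column one sample). Returns one U2 per column.
.watson_stat <- function(u) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 1L)
  n <- nrow(u)
  # sort within columns
  u <- matrix(u[order(col(u), u)], nrow = n)
  i <- (2 * seq_len(n) - 1) / (2 * n)
  d <- u - i
  colSums(d^2) - n * (colMeans(u) - 0.5)^2 + 1 / (12 * n)
}

# Asymptotic tail probability with Stephens' finite-n modification.
.watson_p_asymptotic <- function(u2, n) {
  ustar <- (u2 - 0.1 / n + 0.1 / n^2) * (1 + 0.8 / n)
  k <- seq_len(20)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * ustar))
  min(max(p, 0), 1)
}

#' Watson's U2 test of circular uniformity
#'
#' Tests whether angles are uniformly distributed around the circle. The
#' statistic is rotation-invariant. P-values come either from Stephens'
#' modified asymptotic series (accurate for moderate and large samples) or
#' from a Monte-Carlo null of uniform resamples; `method = "auto"` uses the
#' Monte-Carlo null below 50 angles and the asymptotic series from 50 up.
#'
#' @param angles_deg numeric vector of angles in degrees; at least 2.
#' @param method `"auto"`, `"asymptotic"` (requires `n >= 8`) or
#'   `"permutation"` (Monte-Carlo uniform null; any `n >= 2`).
#' @param n_perm number of Monte-Carlo resamples for the permutation null.
#' @return An object of class `watson_u2`: list with `u2`, `p_value`, `n`,
#'   `method`.
#' @export
watson_u2 <- function(angles_deg, method = c("auto", "asymptotic", "permutation"),
                      n_perm = 2000L) {
  method <- match.arg(method)
  if (length(angles_deg) < 2L || anyNA(angles_deg))
    stop("watson_u2() needs at least 2 non-missing angles", call. = FALSE)
  n <- length(angles_deg)
  if (method == "auto") method <- if (n >= 50L) "asymptotic" else "permutation"
  if (method == "asymptotic" && n < 8L)
    stop("asymptotic p-value requires n >= 8; use method = \"permutation\"", call. = FALSE)
  u <- (angles_deg %% 360) / 360
  u2 <- .watson_stat(u)
  if (method == "asymptotic") {
    p <- .watson_p_asymptotic(u2, n)
  } else {
    null_u <- matrix(runif(n * n_perm), nrow = n)
    null_stats <- .watson_stat(null_u)
    p <- (1 + sum(null_stats >= u2)) / (n_perm + 1)
  }
  structure(list(u2 = unname(u2), p_value = p, n = n, method = method),
            class = "watson_u2")
}

#' @export
print.watson_u2 <- function(x, ...) {
  cat(sprintf("Watson U2 test: U2 = %.4f, p = %.4g (n = %d, %s)\n",
              x$u2, x$p_value, x$n, x$method))
  invisible(x)
}

#' Histogram of angles in fixed-width circular bins
#'
#' Bins angles over `[-180, 180)` in half-open bins `[lo, hi)`; the bin
#' width must divide 360.
#'
#' @param angles_deg numeric vector of angles (any wrap); may be empty.
#' @param bin_width_deg bin width in degrees, default 15.
#' @return data.frame with `bin_lo`, `bin_hi`, `bin_mid`, `count`;
#'   counts sum to `length(angles_deg)`.
#' @export
bin_angles <- function(angles_deg, bin_width_deg = 15) {
  stopifnot_scalar(bin_width_deg, "bin_width_deg", positive = TRUE)
  if (360 %% bin_width_deg != 0)
    stop("`bin_width_deg` must divide 360", call. = FALSE)
  n_bins <- as.integer(360 / bin_width_deg)
  lo <- -180 + bin_width_deg * (seq_len(n_bins) - 1)
  counts <- integer(n_bins)
  if (length(angles_deg)) {
    w <- wrap_angle_deg(angles_deg)
    idx <- pmin(floor((w + 180) / bin_width_deg) + 1, n_bins)
    counts <- tabulate(idx, nbins = n_bins)
  }
  data.frame(bin_lo = lo, bin_hi = lo + bin_width_deg,
             bin_mid = lo + bin_width_deg / 2, count = counts)
}

#' Pair direction bias with progenitor count across embryos
#'
#' @param summaries a list of [direction_summary()] objects (one per embryo),
#'   optionally named.
#' @return data.frame with `embryo`, `n`, `bias`, one row per summary.
#' @export
bias_vs_count <- function(summaries) {
  if (inherits(summaries, "direction_summary")) summaries <- list(summaries)
  if (length(summaries) < 1L)
    stop("bias_vs_count() needs at least one summary", call. = FALSE)
  ids <- names(summaries)
  if (is.null(ids)) ids <- as.character(seq_along(summaries))
  data.frame(
    embryo = ids,
    n = vapply(summaries, function(s) s$n, numeric(1)),
    bias = vapply(summaries, function(s) s$bias, numeric(1)),
    row.names = NULL
  )
}
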