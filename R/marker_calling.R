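# Marker-positive calling: threshold nuclei on per-channel staining
# intensity (fixed, log-scale, or mean+SD combination thresholds) and
# compute mitotic fractions per progenitor population.

#' Specify a marker intensity threshold
#'
#' Thresholds are per dataset: staining batches are imaged independently,
#' so intensity values are only comparable within one dataset and each
#' dataset carries its own spec.
#'
#' @param channel channel (column) name the threshold applies to.
#' @param mode `"fixed"` (intensity scale), `"log_fixed"` (threshold on
#'   `log(intensity)`; natural log by default) or `"mean_sd_combo"`
#'   (positive requires mean intensity above `value` AND intensity SD above
#'   `sd_cutoff`; used for spotty nuclear stains such as RNAscope sox32).
#' @param value threshold on the mean intensity (or its log).
#' @param sd_cutoff SD cutoff for `mode = "mean_sd_combo"`; the SD column is
#'   `paste0(channel, "_sd")`.
#' @param strict use strict `>` at the threshold (default TRUE).
#' @param log_base base for `log_fixed`; `exp(1)` by default.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(channel, mode = c("fixed", "log_fixed", "mean_sd_combo"),
                           value, sd_cutoff = NULL, strict = TRUE,
                           log_base = exp(1)) {
  mode <- match.arg(mode)
  stopifnot_scalar(value, "value")
  if (mode == "mean_sd_combo") {
    if (is.null(sd_cutoff))
      stop("`sd_cutoff` is required for mode \"mean_sd_combo\"", call. = FALSE)
    stopifnot_scalar(sd_cutoff, "sd_cutoff")
    if (sd_cutoff < 0) stop("`sd_cutoff` must be >= 0", call. = FALSE)
  }
  structure(list(channel = channel, mode = mode, value = value,
                 sd_cutoff = sd_cutoff, strict = isTRUE(strict),
                 log_base = log_base),
            class = "threshold_spec")
}

#' Call cells positive for a marker
#'
#' Appends a logical `<channel>_pos` column according to the threshold
#' spec. Comparison is strict `>` by default, so a cell exactly at the
#' threshold is negative.
#'
#' @param table cell table with a column named after `spec$channel` (and
#'   `<channel>_sd` for the mean+SD mode).
#' @param spec a [threshold_spec()].
#' @return `table` with the flag column added.
#' @export
#' @examples
#' tab <- data.frame(sox32 = exp(c(8.4, 8.6)))
#' call_positive(tab, threshold_spec("sox32", "log_fixed", 8.5))$sox32_pos
call_positive <- function(table, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  ch <- spec$channel
  if (!ch %in% names(table))
    stop(sprintf("channel `%s` not present in table", ch), call. = FALSE)
  gt <- if (spec$strict) `>` else `>=`
  v <- table[[ch]]
  flag <- switch(spec$mode,
    fixed = gt(v, spec$value),
    log_fixed = gt(log(v, base = spec$log_base), spec$value),
    mean_sd_combo = {
      sd_col <- paste0(ch, "_sd")
      if (!sd_col %in% names(table))
        stop(sprintf("column `%s` required for mean_sd_combo", sd_col), call. = FALSE)
      gt(v, spec$value) & gt(table[[sd_col]], spec$sd_cutoff)
    }
  )
  table[[paste0(ch, "_pos")]] <- flag
  table
}

#' Mitotic fractions per progenitor population
#'
#' Fraction of P-H3-positive cells among (i) sox32+ tbx16+ cells,
#' (ii) sox32- tbx16+ cells, and (iii) all sox32- cells. An empty group
#' yields `NA`, not zero.
#'
#' @param table cell table with logical columns `sox32_pos`, `tbx16_pos`,
#'   `ph3_pos` (names configurable via arguments).
#' @param sox32_col,tbx16_col,ph3_col flag column names.
#' @return data.frame with `group`, `n`, `n_ph3`, `fraction`.
#' @export
mitotic_fractions <- function(table, sox32_col = "sox32_pos",
                              tbx16_col = "tbx16_pos", ph3_col = "ph3_pos") {
  for (cl in c(sox32_col, tbx16_col, ph3_col))
    if (!cl %in% names(table))
      stop(sprintf("missing flag column `%s`", cl), call. = FALSE)
  sox <- as.logical(table[[sox32_col]])
  tbx <- as.logical(table[[tbx16_col]])
  ph3 <- as.logical(table[[ph3_col]])
  groups <- list(
    "sox32+tbx16+" = sox & tbx,
    "sox32-tbx16+" = !sox & tbx,
    "sox32-"       = !sox
  )
  res <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    n <- sum(sel)
    data.frame(group = g, n = n, n_ph3 = sum(ph3 & sel),
               fraction = if (n > 0) sum(ph3 & sel) / n else NA_real_)
  })
  do.call(rbind, res)
}
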