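# Late-endoderm robustness metrics: gut staining intensity profiles,
# deviation from the untreated mean profile, and early-versus-late
# robustness classification across a dose series.

#' Resample intensity profiles onto a common grid
#'
#' Linear interpolation of each embryo's profile onto `n_points` evenly
#' spaced positions in `[0, 1]`.
#'
#' @param profiles data.frame with `embryo`, `position`, `intensity` (and
#'   optionally `dose`).
#' @param n_points grid size (default 100).
#' @return data.frame in the same long format on the common grid.
#' @export
resample_profiles <- function(profiles, n_points = 100L) {
  n_points <- stopifnot_count(n_points, "n_points", min = 2L)
  grid <- seq(0, 1, length.out = n_points)
  parts <- lapply(split(profiles, profiles$embryo), function(p) {
    p <- p[order(p$position), , drop = FALSE]
    if (any(duplicated(p$position)) || is.unsorted(p$position, strictly = TRUE))
      stop("profile positions must be strictly increasing per embryo", call. = FALSE)
    out <- data.frame(embryo = p$embryo[1], position = grid,
                      intensity = approx(p$position, p$intensity, xout = grid,
                                         rule = 2)$y)
    if ("dose" %in% names(p)) out$dose <- p$dose[1]
    out
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Mean reference profile across embryos
#'
#' Pointwise mean intensity across embryos on a common position grid
#' (typically the untreated group).
#'
#' @param profiles long data.frame with `embryo`, `position`, `intensity`,
#'   all embryos on the same grid (see [resample_profiles()]).
#' @return data.frame with `position`, `intensity`.
#' @export
mean_reference_profile <- function(profiles) {
  if (nrow(profiles) == 0) stop("no profiles given", call. = FALSE)
  pos <- sort(unique(profiles$position))
  per <- split(profiles$intensity, profiles$embryo)
  if (!all(vapply(per, length, integer(1)) == length(pos)))
    stop("profiles are not on a common grid; resample first", call. = FALSE)
  m <- rowMeans(do.call(cbind, lapply(split(profiles, profiles$embryo),
                                      function(p) p$intensity[order(p$position)])))
  data.frame(position = pos, intensity = m)
}

#' Deviation of a profile from a reference
#'
#' Root-mean-square (default) or mean-absolute pointwise difference between
#' two profiles on the same grid. Zero iff identical; symmetric.
#'
#' @param profile,reference data.frames with `position`, `intensity` on a
#'   common grid.
#' @param metric `"rms"` (default) or `"mean_abs"`.
#' @return Scalar deviation, `>= 0`.
#' @export
profile_deviation <- function(profile, reference, metric = c("rms", "mean_abs")) {
  metric <- match.arg(metric)
  a <- profile[order(profile$position), ]
  b <- reference[order(reference$position), ]
  if (nrow(a) != nrow(b) || max(abs(a$position - b$position)) > 1e-8)
    stop("profiles must share the same position grid", call. = FALSE)
  d <- a$intensity - b$intensity
  switch(metric, rms = sqrt(mean(d^2)), mean_abs = mean(abs(d)))
}

#' Per-embryo deviations from the untreated mean, by dose
#'
#' @param profiles long data.frame with `embryo`, `dose`, `position`,
#'   `intensity` on a common grid.
#' @param untreated_dose dose label of the untreated group (default 0).
#' @param metric passed to [profile_deviation()].
#' @return data.frame with `embryo`, `dose`, `deviation`; the reference is
#'   the mean profile of the untreated embryos.
#' @export
dose_deviations <- function(profiles, untreated_dose = 0, metric = "rms") {
  if (!all(c("dose", "embryo") %in% names(profiles)))
    stop("`profiles` needs `embryo` and `dose` columns", call. = FALSE)
  ref <- mean_reference_profile(profiles[profiles$dose == untreated_dose, ])
  parts <- lapply(split(profiles, profiles$embryo), function(p) {
    data.frame(embryo = p$embryo[1], dose = p$dose[1],
               deviation = profile_deviation(p[, c("position", "intensity")],
                                             ref, metric))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$dose, out$embryo), ]
}

#' Early-versus-late robustness curve
#'
#' Min-max normalises an early and a late per-dose metric between the
#' untreated (0) and fully perturbed (1) anchors, and classifies each dose:
#' robust where the normalised late deviation is smaller than the early
#' one (late development buffers the early perturbation), fragile where it
#' is larger, boundary where equal.
#'
#' @param doses dose labels (must include the untreated and the maximal
#'   dose).
#' @param early_metric,late_metric per-dose scalars (same length as
#'   `doses`), e.g. progenitor-count deficits and gut-profile deviations.
#' @param untreated_dose,full_dose anchor dose labels; default the minimum
#'   and maximum of `doses`.
#' @return data.frame with `dose`, `early_norm`, `late_norm`,
#'   `classification` in {robust, fragile, boundary}.
#' @export
robustness_curve <- function(doses, early_metric, late_metric,
                             untreated_dose = min(doses),
                             full_dose = max(doses)) {
  if (length(doses) != length(early_metric) ||
      length(doses) != length(late_metric))
    stop("`doses`, `early_metric`, `late_metric` must have equal length", call. = FALSE)
  i0 <- match(untreated_dose, doses)
  i1 <- match(full_dose, doses)
  if (is.na(i0) || is.na(i1))
    stop("anchor doses must be present in `doses`", call. = FALSE)
  norm <- function(x) {
    if (x[i1] == x[i0]) stop("degenerate anchors: no dynamic range", call. = FALSE)
    (x - x[i0]) / (x[i1] - x[i0])
  }
  en <- norm(early_metric)
  ln <- norm(late_metric)
  cls <- ifelse(ln < en, "robust", ifelse(ln > en, "fragile", "boundary"))
  data.frame(dose = doses, early_norm = en, late_norm = ln,
             classification = cls)
}
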