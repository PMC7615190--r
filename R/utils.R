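# Shared helpers: angle conventions and argument checks.
# Angles are degrees in [-180, 180) with dorsal at 0 unless stated otherwise.

#' Wrap angles into [-180, 180)
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped to `[-180, 180)`.
#' @export
wrap_angle_deg <- function(deg) {
  out <- (deg + 180) %% 360 - 180
  # (x %% 360) can return 360 - eps; keep the half-open convention exact
  out[out >= 180] <- -180
  out
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

stopifnot_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

assert_array3d <- function(x, name = deparse(substitute(x))) {
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` must contain only finite values", name), call. = FALSE)
  invisible(x)
}

# Seed handling: run code under a local, reproducible RNG state without
# disturbing the caller's stream when a seed is given.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
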