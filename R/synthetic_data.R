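# Synthetic, ground-truthed test data for the whole pipeline: a rendered
# flat-mounted embryo margin (annulus of nuclei + YSL row + dorsal DFC
# cluster) as a multi-channel 3D stack, tabular cell datasets with
# margin-decaying P-Smad2 / P-Erk fields and sox32 drawn from a per-step
# logistic induction hazard, and dose-attenuated gut intensity profiles.
#
# The generators emulate the statistical structure the analysis assumes
# (not optics): smooth ellipsoidal nuclei, additive Gaussian camera noise,
# heavy lognormal cell-to-cell staining variation.

#' Parameters of the synthetic embryo image
#'
#' @param n_nuclei number of embryonic (marginal band) nuclei.
#' @param margin_radius_um radius of the circular margin in micrometres.
#' @param nucleus_radius_um nominal nucleus radius in micrometres.
#' @param voxel_size_um (x, y, z) voxel size in micrometres; the default
#'   `c(0.125, 0.125, 0.250)` matches 20x confocal stacks of flat-mounted
#'   embryos (tests use coarser voxels for speed).
#' @param dapi_mean peak DAPI intensity of a nucleus (16-bit scale).
#' @param noise_sd additive Gaussian noise SD.
#' @param n_ysl number of YSL nuclei (beyond the margin, locally lowest Z).
#' @param n_dfc number of dorsal forerunner cells (sox32-bright cluster at
#'   the dorsal angle).
#' @param dorsal_angle_deg image-frame angle of dorsal.
#' @param band_width_um radial width of the embryonic nuclear band.
#' @param seed optional integer seed.
#' @return An object of class `synthetic_embryo_params`.
#' @export
synthetic_embryo_params <- function(n_nuclei = 80L, margin_radius_um = 45,
                                    nucleus_radius_um = 3,
                                    voxel_size_um = c(0.125, 0.125, 0.250),
                                    dapi_mean = 12000, noise_sd = 400,
                                    n_ysl = 30L, n_dfc = 8L,
                                    dorsal_angle_deg = 0, band_width_um = 15,
                                    seed = NULL) {
  n_nuclei <- stopifnot_count(n_nuclei, "n_nuclei")
  n_ysl <- stopifnot_count(n_ysl, "n_ysl")
  n_dfc <- stopifnot_count(n_dfc, "n_dfc")
  stopifnot_scalar(margin_radius_um, "margin_radius_um", positive = TRUE)
  stopifnot_scalar(nucleus_radius_um, "nucleus_radius_um", positive = TRUE)
  stopifnot_scalar(dapi_mean, "dapi_mean", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd")
  stopifnot_scalar(band_width_um, "band_width_um", positive = TRUE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be three positive values", call. = FALSE)
  if (nucleus_radius_um >= margin_radius_um)
    stop("nucleus radius must be smaller than the margin radius", call. = FALSE)
  if (!is.null(seed)) seed <- stopifnot_count(seed, "seed")
  structure(list(n_nuclei = n_nuclei, margin_radius_um = margin_radius_um,
                 nucleus_radius_um = nucleus_radius_um,
                 voxel_size_um = as.numeric(voxel_size_um),
                 dapi_mean = dapi_mean, noise_sd = noise_sd,
                 n_ysl = n_ysl, n_dfc = n_dfc,
                 dorsal_angle_deg = dorsal_angle_deg,
                 band_width_um = band_width_um, seed = seed),
            class = "synthetic_embryo_params")
}

# place n points with pairwise 3D separation >= min_sep by rejection
# sampling against already-accepted points; returns matrix + failure count
.place_points <- function(n, sampler, existing, min_sep, max_retries = 200L) {
  out <- matrix(numeric(0), ncol = 3)
  failures <- 0L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- sampler()
      all_pts <- rbind(existing, out)
      if (nrow(all_pts) == 0 ||
          min(sqrt(colSums((t(all_pts) - cand)^2))) >= min_sep) {
        out <- rbind(out, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      failures <- failures + 1L
      out <- rbind(out, cand)  # keep the overlapping placement, but count it
    }
  }
  list(points = out, failures = failures)
}

#' Render a synthetic flat-mounted embryo margin stack
#'
#' Nuclei are smooth Gaussian-profile ellipsoids (isotropic in micrometres,
#' anisotropic in voxels): embryonic nuclei in an annular band inside the
#' circular margin, YSL nuclei beyond the margin at the locally lowest Z,
#' and a sox32-bright DFC cluster at the dorsal angle. Channels are DAPI
#' and sox32; additive Gaussian noise is applied to both.
#'
#' @param params a [synthetic_embryo_params()] object.
#' @return List with `channels` (named list of 3D arrays: `dapi`, `sox32`),
#'   `truth` (list: `centroids_um` matrix, `angles_deg`, `class` in
#'   {embryonic, YSL, DFC}, `sox32`, `label_image`, `params`) and
#'   `voxel_size_um`.
#' @export
generate_embryo_image <- function(params = synthetic_embryo_params()) {
  stopifnot(inherits(params, "synthetic_embryo_params"))
  with_seed(params$seed, {
    p <- params
    r_n <- p$nucleus_radius_um
    R <- p$margin_radius_um
    ysl_gap <- 1.5 * r_n
    pad <- 3 * r_n
    half <- R + ysl_gap + 2 * r_n + pad
    depth <- 24
    ysl_z <- 5
    emb_z <- c(11, 18)
    cx <- half; cy <- half
    nx <- ceiling(2 * half / p$voxel_size_um[1])
    ny <- ceiling(2 * half / p$voxel_size_um[2])
    nz <- ceiling(depth / p$voxel_size_um[3])

    sample_band <- function() {
      th <- runif(1, -pi, pi)
      rr <- sqrt(runif(1, max(0, (R - p$band_width_um))^2, (R - 0.9 * r_n)^2))
      c(cx + rr * cos(th), cy + rr * sin(th), runif(1, emb_z[1], emb_z[2]))
    }
    sample_ysl <- function() {
      th <- runif(1, -pi, pi)
      rr <- runif(1, R + ysl_gap, R + ysl_gap + 1.5 * r_n)
      c(cx + rr * cos(th), cy + rr * sin(th), ysl_z + runif(1, -0.5, 0.5))
    }
    dorsal_rad <- deg2rad(p$dorsal_angle_deg)
    sample_dfc <- function() {
      th <- dorsal_rad + runif(1, -pi / 12, pi / 12)
      rr <- sqrt(runif(1, max(0, (R - p$band_width_um))^2, (R - 0.9 * r_n)^2))
      c(cx + rr * cos(th), cy + rr * sin(th), runif(1, emb_z[1], emb_z[2]))
    }

    min_sep <- 2 * r_n
    emb <- .place_points(p$n_nuclei, sample_band, matrix(numeric(0), ncol = 3), min_sep)
    dfc <- .place_points(p$n_dfc, sample_dfc, emb$points, min_sep)
    ysl <- .place_points(p$n_ysl, sample_ysl, rbind(emb$points, dfc$points), min_sep)
    n_total <- p$n_nuclei + p$n_dfc + p$n_ysl
    n_fail <- emb$failures + dfc$failures + ysl$failures
    if (n_total > 0 && n_fail > 0.5 * n_total)
      stop("synthetic embryo generation failed: more than half of the nuclei could not be placed without overlap",
           call. = FALSE)

    centroids <- rbind(emb$points, dfc$points, ysl$points)
    classes <- rep(c("embryonic", "DFC", "YSL"),
                   c(p$n_nuclei, p$n_dfc, p$n_ysl))
    sox32_true <- classes == "DFC"

    dapi <- array(0, dim = c(nx, ny, nz))
    sox <- array(0, dim = c(nx, ny, nz))
    labels <- array(0L, dim = c(nx, ny, nz))
    sigma_um <- r_n / 2
    if (n_total > 0) {
      # squared distance (um^2) from each voxel centre in a local box
      vx <- p$voxel_size_um
      ext <- ceiling(3 * sigma_um / vx)
      for (k in seq_len(n_total)) {
        c_vox <- centroids[k, ] / vx + 0.5   # voxel-centre coordinates
        i0 <- pmax(1, floor(c_vox - ext)); i1 <- pmin(c(nx, ny, nz), ceiling(c_vox + ext))
        if (any(i0 > i1)) next
        ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
        dx2 <- ((ix - c_vox[1]) * vx[1])^2
        dy2 <- ((iy - c_vox[2]) * vx[2])^2
        dz2 <- ((iz - c_vox[3]) * vx[3])^2
        d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
        blob <- exp(-d2 / (2 * sigma_um^2))
        dapi[ix, iy, iz] <- dapi[ix, iy, iz] + p$dapi_mean * blob
        if (sox32_true[k])
          sox[ix, iy, iz] <- sox[ix, iy, iz] + 0.8 * p$dapi_mean * blob
        inside <- d2 <= r_n^2
        lab_box <- labels[ix, iy, iz]
        lab_box[inside & lab_box == 0L] <- k
        labels[ix, iy, iz] <- lab_box
      }
    }
    if (p$noise_sd > 0) {
      dapi <- pmax(dapi + rnorm(length(dapi), 0, p$noise_sd), 0)
      sox <- pmax(sox + rnorm(length(sox), 0, p$noise_sd), 0)
      dim(dapi) <- c(nx, ny, nz); dim(sox) <- c(nx, ny, nz)
    }
    ang <- if (n_total > 0)
      wrap_angle_deg(rad2deg(atan2(centroids[, 2] - cy, centroids[, 1] - cx)) -
                       p$dorsal_angle_deg)
    else numeric(0)
    colnames(centroids) <- c("x_um", "y_um", "z_um")
    list(
      channels = list(dapi = dapi, sox32 = sox),
      truth = list(centroids_um = centroids, angles_deg = ang,
                   class = classes, sox32 = sox32_true,
                   label_image = labels, center_um = c(cx, cy),
                   params = p),
      voxel_size_um = p$voxel_size_um
    )
  })
}

#' Sparse boundary points of the synthetic margin
#'
#' Returns ordered pixel-coordinate points on the known circular margin of
#' a synthetic embryo (as a hand-marked boundary would be), plus the dorsal
#' hint, ready for [fit_margin_spline()].
#'
#' @param params the [synthetic_embryo_params()] used for the image.
#' @param n_points number of boundary points.
#' @return List with `points_px` (n x 2), `dorsal_hint_px`,
#'   `pixel_size_um`.
#' @export
synthetic_margin_points <- function(params, n_points = 36L) {
  stopifnot(inherits(params, "synthetic_embryo_params"))
  n_points <- stopifnot_count(n_points, "n_points", min = 4L)
  r_n <- params$nucleus_radius_um
  half <- params$margin_radius_um + 1.5 * r_n + 2 * r_n + 3 * r_n
  px <- params$voxel_size_um[1]
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)] +
    deg2rad(params$dorsal_angle_deg)
  pts <- cbind(x = (half + params$margin_radius_um * cos(th)) / px,
               y = (half + params$margin_radius_um * sin(th)) / px)
  list(points_px = pts,
       dorsal_hint_px = pts[1, ],
       pixel_size_um = px)
}

#' Parameters of the synthetic signaling / induction cell-table generator
#'
#' P-Smad2 decays exponentially with distance from the margin with heavy
#' lognormal cell-to-cell variation; P-Erk is flat (optionally suppressed in
#' the first tiers); sox32 status is drawn by iterating a per-step logistic
#' induction hazard over the competency window. The hazard's logistic link
#' is a modelling choice of this generator (the biology constrains only its
#' monotonicity), kept identifiable so recovery can be tested.
#'
#' @param smad2_margin_mean mean nuclear P-Smad2 at the margin (intensity).
#' @param smad2_decay_um exponential decay length of the P-Smad2 field.
#' @param smad2_noise_cv lognormal cell-to-cell coefficient of variation.
#' @param erk_margin_mean mean nuclear P-Erk (intensity).
#' @param erk_suppression_tiers number of first tiers in which P-Erk is
#'   suppressed (to 40% of its mean); 0 disables suppression.
#' @param hazard_intercept,hazard_smad2_coef,hazard_erk_coef logistic
#'   per-step hazard: `plogis(intercept + b_s * smad2 + b_e * erk)`.
#' @param n_steps competency steps over which the hazard is iterated.
#' @param seed optional integer seed.
#' @return An object of class `synthetic_signaling_params`.
#' @export
synthetic_signaling_params <- function(smad2_margin_mean = 3000,
                                       smad2_decay_um = 30,
                                       smad2_noise_cv = 0.5,
                                       erk_margin_mean = 2000,
                                       erk_suppression_tiers = 0L,
                                       hazard_intercept = -7,
                                       hazard_smad2_coef = 8e-4,
                                       hazard_erk_coef = -8e-4,
                                       n_steps = 100L, seed = NULL) {
  stopifnot_scalar(smad2_margin_mean, "smad2_margin_mean", positive = TRUE)
  stopifnot_scalar(smad2_decay_um, "smad2_decay_um", positive = TRUE)
  stopifnot_scalar(smad2_noise_cv, "smad2_noise_cv")
  if (smad2_noise_cv < 0) stop("`smad2_noise_cv` must be >= 0", call. = FALSE)
  stopifnot_scalar(erk_margin_mean, "erk_margin_mean", positive = TRUE)
  erk_suppression_tiers <- stopifnot_count(erk_suppression_tiers,
                                           "erk_suppression_tiers")
  n_steps <- stopifnot_count(n_steps, "n_steps", min = 1L)
  if (!is.null(seed)) seed <- stopifnot_count(seed, "seed")
  structure(list(smad2_margin_mean = smad2_margin_mean,
                 smad2_decay_um = smad2_decay_um,
                 smad2_noise_cv = smad2_noise_cv,
                 erk_margin_mean = erk_margin_mean,
                 erk_suppression_tiers = erk_suppression_tiers,
                 hazard_intercept = hazard_intercept,
                 hazard_smad2_coef = hazard_smad2_coef,
                 hazard_erk_coef = hazard_erk_coef,
                 n_steps = n_steps, seed = seed),
            class = "synthetic_signaling_params")
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a ground-truthed synthetic cell table
#'
#' Places `n_nuclei` cells uniformly in angle and in distance from the
#' margin over `n_tiers` tiers, draws the two signaling channels, and
#' assigns sox32 by iterating the per-step logistic hazard (status is
#' maintained once on).
#'
#' @param embryo a [synthetic_embryo_params()] (supplies `n_nuclei` and the
#'   seed used when `signaling$seed` is `NULL`).
#' @param signaling a [synthetic_signaling_params()].
#' @param tier_width_um tier width used for the layout (15 um default).
#' @param n_tiers radial extent of the table in tiers (10 default).
#' @return List with `table` (data.frame: `cell`, `embryo`, `phi_deg`,
#'   `dist_to_margin_um`, `tier`, `smad2`, `erk`, `true_hazard`,
#'   `sox32_pos`, `is_ysl`, `is_dfc`) and `truth` (generating parameters).
#' @export
generate_cell_table <- function(embryo = synthetic_embryo_params(),
                                signaling = synthetic_signaling_params(),
                                tier_width_um = 15, n_tiers = 10L) {
  stopifnot(inherits(embryo, "synthetic_embryo_params"))
  stopifnot(inherits(signaling, "synthetic_signaling_params"))
  n_tiers <- stopifnot_count(n_tiers, "n_tiers", min = 1L)
  seed <- if (!is.null(signaling$seed)) signaling$seed else embryo$seed
  with_seed(seed, {
    n <- embryo$n_nuclei
    phi <- wrap_angle_deg(runif(n, -180, 180))
    d <- runif(n, 0, n_tiers * tier_width_um)
    tier <- as.integer(floor(d / tier_width_um) + 1L)
    smad2 <- rlnorm_mean_cv(n, signaling$smad2_margin_mean *
                              exp(-d / signaling$smad2_decay_um),
                            signaling$smad2_noise_cv)
    erk_mean <- rep(signaling$erk_margin_mean, n)
    if (signaling$erk_suppression_tiers > 0)
      erk_mean[tier <= signaling$erk_suppression_tiers] <-
        0.4 * signaling$erk_margin_mean
    erk <- rlnorm_mean_cv(n, erk_mean, signaling$smad2_noise_cv)
    h <- plogis(signaling$hazard_intercept +
                  signaling$hazard_smad2_coef * smad2 +
                  signaling$hazard_erk_coef * erk)
    pos <- logical(n)
    for (t in seq_len(signaling$n_steps))
      pos <- pos | (runif(n) < h)
    table <- data.frame(cell = seq_len(n), embryo = 1L, phi_deg = phi,
                        dist_to_margin_um = d, tier = tier,
                        smad2 = smad2, erk = erk, true_hazard = h,
                        sox32_pos = pos, is_ysl = FALSE, is_dfc = FALSE)
    list(table = table,
         truth = list(hazard_intercept = signaling$hazard_intercept,
                      hazard_smad2_coef = signaling$hazard_smad2_coef,
                      hazard_erk_coef = signaling$hazard_erk_coef,
                      n_steps = signaling$n_steps,
                      embryo_params = embryo, signaling_params = signaling))
  })
}

#' Template shape of the synthetic gut intensity profile
#'
#' Three smooth bumps (foregut, midgut, hindgut-like) on a baseline along
#' normalised gut arc length.
#'
#' @param positions positions in `[0, 1]`.
#' @param attenuation multiplier in `[0, 1]` applied to the bump amplitudes
#'   (1 = untreated shape).
#' @return Intensity values.
#' @export
gut_profile_template <- function(positions, attenuation = 1) {
  base <- 0.2
  bumps <- 1.0 * exp(-(positions - 0.15)^2 / (2 * 0.05^2)) +
    0.8 * exp(-(positions - 0.45)^2 / (2 * 0.08^2)) +
    0.9 * exp(-(positions - 0.80)^2 / (2 * 0.06^2))
  base + attenuation * bumps
}

#' Generate synthetic gut intensity profiles across doses
#'
#' All profiles share the template shape; the dose attenuates the bump
#' amplitudes through `dose_effect`, and Gaussian noise is added.
#'
#' @param n_embryos embryos per dose.
#' @param doses numeric dose labels.
#' @param dose_effect function mapping a dose to a bump-amplitude
#'   multiplier in `[0, 1]`; default halves the amplitude linearly up to
#'   the maximum dose.
#' @param profile_length points per profile.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed optional integer seed.
#' @return data.frame with `embryo`, `dose`, `position`, `intensity`.
#' @export
generate_gut_profiles <- function(n_embryos = 5L, doses = c(0, 0.25, 0.5, 1),
                                  dose_effect = NULL, profile_length = 100L,
                                  noise_sd = 0.05, seed = NULL) {
  n_embryos <- stopifnot_count(n_embryos, "n_embryos", min = 1L)
  profile_length <- stopifnot_count(profile_length, "profile_length", min = 2L)
  stopifnot_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(dose_effect)) {
    dmax <- max(doses)
    dose_effect <- if (dmax > 0) function(dose) 1 - 0.5 * dose / dmax
                   else function(dose) 1
  }
  if (!is.null(seed)) seed <- stopifnot_count(seed, "seed")
  with_seed(seed, {
    pos <- seq(0, 1, length.out = profile_length)
    out <- list()
    id <- 0L
    for (dose in doses) {
      att <- dose_effect(dose)
      for (e in seq_len(n_embryos)) {
        id <- id + 1L
        intensity <- gut_profile_template(pos, att)
        if (noise_sd > 0) intensity <- intensity + rnorm(profile_length, 0, noise_sd)
        out[[id]] <- data.frame(embryo = id, dose = dose, position = pos,
                                intensity = intensity)
      }
    }
    do.call(rbind, out)
  })
}
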