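# End-to-end orchestration: run the synthetic-data -> segmentation ->
# margin-geometry -> marker-calling -> circular-statistics chain (plus
# optional simulator, signaling and gut-profile stages) from one config,
# writing per-stage outputs and a provenance manifest into a run directory.

.known_stages <- c("generate", "segment", "positions", "call", "circstats",
                   "simulate", "signaling", "profiles")

#' Demo pipeline configuration
#'
#' A small, fully synthetic configuration exercising image generation,
#' segmentation, margin geometry, sox32 calling and circular statistics.
#'
#' @param run_dir output directory.
#' @param seed global seed propagated to every stochastic stage.
#' @return Config list accepted by [run_pipeline()].
#' @export
demo_config <- function(run_dir = tempfile("endomargin_run_"), seed = 1L) {
  list(
    run_dir = run_dir,
    seed = seed,
    stages = c("generate", "segment", "positions", "call", "circstats"),
    generate = list(n_nuclei = 60, n_ysl = 12, n_dfc = 4,
                    margin_radius_um = 40, nucleus_radius_um = 3,
                    voxel_size_um = c(0.5, 0.5, 0.5), noise_sd = 300),
    segmentation = list(local_window_px = 25, gaussian_sigma_px = 2),
    positions = list(tier_width_um = 15, z_window_um = 5,
                     local_radius_um = 30, dfc_half_width_deg = 36),
    call = list(sox32 = list(mode = "fixed", value = 3000)),
    circstats = list(bin_width_deg = 15)
  )
}

validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("pipeline_validation_error", "error")))
}
dependency_error <- function(stage, missing) {
  stop(errorCondition(
    sprintf("stage `%s` is missing upstream output: %s", stage, missing),
    class = c("pipeline_dependency_error", "error")))
}

#' Run the analysis pipeline
#'
#' Runs the configured stages in dependency order inside `config$run_dir`,
#' writing every intermediate as CSV/TIFF and ending with a provenance
#' manifest (`manifest.json`: config hash, seed, package version, output
#' checksums). A rerun with the same config reproduces stochastic outputs
#' bit-identically.
#'
#' @param config config list (see [demo_config()]) or path to a YAML file.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$run_dir)) validation_error("config needs `run_dir`")
  if (is.null(config$stages) || !length(config$stages))
    validation_error("config needs a non-empty `stages` list")
  unknown <- setdiff(config$stages, .known_stages)
  if (length(unknown))
    validation_error(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$run_dir, recursive = TRUE, showWarnings = FALSE)
  rd <- function(...) file.path(config$run_dir, ...)
  log_msg <- function(stage, fmt, ...) {
    message(sprintf("[endomargin] %s: %s", stage, sprintf(fmt, ...)))
  }
  outputs <- character(0)
  timings <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    fun()
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    log_msg(stage, "done in %.2f s", timings[[stage]])
  }

  for (stage in config$stages) {
    switch(stage,
      generate = run_stage("generate", function() {
        gp <- do.call(synthetic_embryo_params,
                      modifyList(list(seed = seed), config$generate %||% list()))
        img <- generate_embryo_image(gp)
        state$image <- img
        state$params <- gp
        write_stack_tiff(img$channels$dapi, rd("dapi.tif"))
        write_stack_tiff(img$channels$sox32, rd("sox32.tif"))
        write_labels_tiff(img$truth$label_image, rd("truth_labels.tif"))
        truth_df <- data.frame(img$truth$centroids_um,
                               class = img$truth$class,
                               angle_deg = img$truth$angles_deg,
                               sox32 = img$truth$sox32)
        write.csv(truth_df, rd("truth_cells.csv"), row.names = FALSE)
        mp <- synthetic_margin_points(gp)
        write.csv(data.frame(x = mp$points_px[, 1], y = mp$points_px[, 2]),
                  rd("margin_points.csv"), row.names = FALSE)
        yaml::write_yaml(list(dorsal_hint_px = as.numeric(mp$dorsal_hint_px),
                              pixel_size_um = mp$pixel_size_um,
                              voxel_size_um = gp$voxel_size_um),
                         rd("margin_meta.yaml"))
        outputs <<- c(outputs, rd(c("dapi.tif", "sox32.tif", "truth_labels.tif",
                                    "truth_cells.csv", "margin_points.csv",
                                    "margin_meta.yaml")))
      }),
      segment = run_stage("segment", function() {
        if (is.null(state$image)) {
          if (!file.exists(rd("dapi.tif")))
            dependency_error("segment", "dapi.tif (run `generate` first)")
          state$image <- list(channels = list(
            dapi = read_stack_tiff(rd("dapi.tif")),
            sox32 = read_stack_tiff(rd("sox32.tif"))))
          meta <- yaml::read_yaml(rd("margin_meta.yaml"))
          state$image$voxel_size_um <- as.numeric(meta$voxel_size_um)
        }
        cfg <- do.call(segmentation_config, config$segmentation %||% list())
        vox <- state$image$voxel_size_um %||% state$params$voxel_size_um
        seg <- segment_nuclei(state$image$channels, cfg, vox)
        state$cells <- seg$cells
        write_labels_tiff(seg$labels, rd("labels.tif"))
        write_cell_table(seg$cells, rd("cells.csv"))
        outputs <<- c(outputs, rd(c("labels.tif", "cells.csv")))
      }),
      positions = run_stage("positions", function() {
        if (is.null(state$cells)) {
          if (!file.exists(rd("cells.csv")))
            dependency_error("positions", "cells.csv (run `segment` first)")
          state$cells <- read_cell_table(rd("cells.csv"))
        }
        if (!file.exists(rd("margin_points.csv")))
          dependency_error("positions", "margin_points.csv")
        meta <- yaml::read_yaml(rd("margin_meta.yaml"))
        pcfg <- config$positions %||% list()
        margin <- fit_margin_spline(read_margin_points(rd("margin_points.csv")),
                                    meta$pixel_size_um,
                                    as.numeric(meta$dorsal_hint_px))
        tab <- assign_marginal_position(state$cells, margin)
        tab <- flag_ysl(tab, pcfg$z_window_um %||% 5,
                        pcfg$local_radius_um %||% 30)
        tab <- assign_tiers(tab, pcfg$tier_width_um %||% 15)
        state$cells <- tab
        state$pcfg <- pcfg
        write_cell_table(tab, rd("cells_positions.csv"))
        outputs <<- c(outputs, rd("cells_positions.csv"))
      }),
      call = run_stage("call", function() {
        if (is.null(state$cells) || is.null(state$cells$phi_deg))
          dependency_error("call", "positioned cell table (run `positions` first)")
        tab <- state$cells
        for (ch in names(config$call %||% list())) {
          sc <- config$call[[ch]]
          spec <- threshold_spec(ch, sc$mode %||% "fixed", sc$value,
                                 sd_cutoff = sc$sd_cutoff,
                                 strict = sc$strict %||% TRUE)
          tab <- call_positive(tab, spec)
        }
        if (!is.null(tab$sox32_pos)) {
          pcfg <- state$pcfg %||% list()
          tab <- exclude_and_rescale_dfc(tab, pcfg$dfc_half_width_deg %||% 36)
        }
        state$cells <- tab
        write_cell_table(tab, rd("cells_called.csv"))
        outputs <<- c(outputs, rd("cells_called.csv"))
      }),
      circstats = run_stage("circstats", function() {
        tab <- state$cells
        if (is.null(tab) || is.null(tab$sox32_pos))
          dependency_error("circstats", "called cell table (run `call` first)")
        keep <- tab$sox32_pos & !tab$is_ysl & !tab$is_dfc
        ang <- tab$psi_deg[keep]
        ang <- ang[!is.na(ang)]
        ccfg <- config$circstats %||% list()
        summary <- if (length(ang) >= 1) direction_summary(ang) else NULL
        test <- if (length(ang) >= 2)
          with_seed(seed, watson_u2(ang)) else NULL
        hist <- bin_angles(ang, ccfg$bin_width_deg %||% 15)
        write.csv(hist, rd("angle_histogram.csv"), row.names = FALSE)
        js <- list(n_progenitors = length(ang))
        if (!is.null(summary))
          js <- c(js, summary[c("mean_angle_deg", "bias", "resultant_length")])
        if (!is.null(test)) js <- c(js, list(watson_u2 = test$u2,
                                             watson_p = test$p_value))
        jsonlite::write_json(js, rd("circular_summary.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
        outputs <<- c(outputs, rd(c("angle_histogram.csv", "circular_summary.json")))
      }),
      simulate = run_stage("simulate", function() {
        scfg <- config$simulate %||% list()
        params <- sim_params(n_founders = scfg$n_founders %||% 500,
                             n_steps = scfg$n_steps %||% 500,
                             p_induction = scfg$p_induction %||% 0.00015,
                             seed = seed)
        ens <- simulate_ensemble(params, scfg$n_runs %||% 20)
        write.csv(ens$summaries, rd("simulation_summaries.csv"),
                  row.names = FALSE)
        write.csv(ens$results[[1]]$final_cells, rd("simulation_run1_cells.csv"),
                  row.names = FALSE)
        outputs <<- c(outputs, rd(c("simulation_summaries.csv",
                                    "simulation_run1_cells.csv")))
      }),
      signaling = run_stage("signaling", function() {
        scfg <- config$signaling %||% list()
        gen <- generate_cell_table(
          synthetic_embryo_params(n_nuclei = scfg$n_cells %||% 5000, seed = seed),
          do.call(synthetic_signaling_params, scfg$params %||% list()))
        tab <- gen$table
        th <- background_threshold(tab)
        prof <- sliding_proportion(tab$smad2[tab$tier %in% c(1, 2)],
                                   tab$sox32_pos[tab$tier %in% c(1, 2)])
        write.csv(as.data.frame(prof), rd("smad2_profile.csv"), row.names = FALSE)
        jsonlite::write_json(
          list(background_threshold = th,
               elevated_fraction = elevated_fraction(tab, th)),
          rd("signaling_summary.json"), auto_unbox = TRUE, digits = NA)
        outputs <<- c(outputs, rd(c("smad2_profile.csv", "signaling_summary.json")))
      }),
      profiles = run_stage("profiles", function() {
        pcfg <- config$profiles %||% list()
        prof <- generate_gut_profiles(n_embryos = pcfg$n_embryos %||% 5,
                                      seed = seed)
        dev <- dose_deviations(prof)
        write.csv(prof, rd("gut_profiles.csv"), row.names = FALSE)
        write.csv(dev, rd("gut_deviations.csv"), row.names = FALSE)
        outputs <<- c(outputs, rd(c("gut_profiles.csv", "gut_deviations.csv")))
      })
    )
  }

  cfg_file <- rd("config.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("endomargin")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    stages = config$stages,
    timings_s = timings,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs)))
  )
  jsonlite::write_json(manifest, rd("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
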