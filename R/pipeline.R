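#' Pipeline configuration
#'
#' Bundles the simulation and analysis parameters. Two profiles are
#' shipped: `"fast"` (a reduced problem size for desk-scale runs: 4
#' animals, 15 days, subsamples of 2000 rows, 10-20 repetitions) and
#' `"paper"` (the study-scale settings: 14 animals, ~6 months,
#' subsamples of 7000 rows, 100 structure repetitions, 30 selection
#' repetitions, 100 bootstrap refits).
#'
#' @param profile `"fast"` or `"paper"`.
#' @param sim overrides passed to [sim_config()].
#' @param ... scalar overrides of analysis parameters (e.g. `r`, `t`,
#'   `n_sub`, `hfi`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("fast", "paper"), sim = list(),
                            ...) {
  profile <- match.arg(profile)
  base <- list(max_error = 50, sea_gap = 24, haul_gap = 48,
               min_bout = 3, dt = 1200, r = 400, t = 1, window_h = 6,
               range_km = 2, shallow_threshold = 5.6,
               hfi = "neg_HS",
               alpha_random = 0.01, alpha_fixed = 0.05,
               keep_frac = 1 / 3)
  scale <- if (profile == "fast")
    list(s = 20, sel_reps = 10, n_sub = 2000, boot_reps = 20)
  else list(s = 100, sel_reps = 30, n_sub = 7000, boot_reps = 100)
  sim_args <- if (profile == "fast")
    modifyList(list(n_animals = 4, days = 15), sim)
  else sim
  cfg <- modifyList(c(base, scale), list(...))
  cfg$sim_args <- sim_args
  cfg$profile <- profile
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulate, process dives and tracks, classify behaviour, assemble the
#' per-segment covariate table and (optionally) fit the resampled mixed
#' models, writing each stage's output as CSV plus a JSON run manifest
#' (seeds, configuration snapshot, per-filter row counts, file
#' checksums). Re-running with the same configuration and seed
#' reproduces the outputs byte for byte.
#'
#' @param config a [pipeline_config()] or the path to a YAML file with
#'   fields `profile`, `sim` and scalar overrides.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param seed integer master seed; all stage streams derive from it.
#' @param fit_models fit the mixed models (default `TRUE`).
#' @return A list with the stage outputs (`data`, `metrics`,
#'   `reg_track`, `segments`, `model_table`, `exclusions`, `mixture`,
#'   `structure`, `selection`, `final`) and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config("fast"),
                         out_dir = NULL, seed = 1L, fit_models = TRUE) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    config <- do.call(pipeline_config,
                      c(list(profile = y$profile %||% "fast",
                             sim = y$sim %||% list()),
                        y[setdiff(names(y), c("profile", "sim"))]))
  }
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  scfg <- do.call(sim_config, c(cfg$sim_args, list(seed = seed)))
  data <- simulate_dataset(scfg)
  if (is.null(data$dives) || !nrow(data$dives))
    stop("simulation produced no dives")

  # vertical metrics
  metrics <- dive_metrics(data$dives,
                          shallow_threshold = cfg$shallow_threshold)

  # horizontal processing
  pts <- filter_and_cut(data$track, data$haulouts,
                        max_error = cfg$max_error,
                        sea_gap = cfg$sea_gap, haul_gap = cfg$haul_gap,
                        min_bout = cfg$min_bout)
  reg <- regularize_track(pts, dt = cfg$dt)
  reg <- classify_movement_type(reg, data$haulouts)
  reg$RT <- residence_time(reg, r = cfg$r, t = cfg$t,
                           sites = data$sites)
  reg$Direction <- classify_trip_direction(reg, data$haulouts,
                                           window_h = cfg$window_h,
                                           range_km = cfg$range_km)

  # behavioural classification
  metrics$bottom_dist <- bottom_distance(metrics, pts, data$bathymetry)
  usable <- metrics$qc == "ok"
  mix <- fit_benthic_mixture(metrics$bottom_dist[usable])
  metrics$benthic <- NA
  metrics$benthic[usable] <- mix$benthic
  metrics <- metrics[order(metrics$animal, metrics$start), ]
  rest <- detect_resting(metrics$SK, metrics$animal)
  metrics$resting <- rest$resting

  # covariate assembly
  segs <- build_segments(reg, data$sites)
  segs <- aggregate_dives(segs, metrics, data$haulouts)
  excl <- apply_exclusions(segs, r = cfg$r)
  model_table <- build_model_table(excl$retained)

  structure_sel <- selection <- final <- NULL
  if (fit_models && nrow(model_table) > 100 &&
      length(unique(model_table$animal)) >= 2) {
    structure_sel <- select_random_structure(
      model_table, cfg$hfi, s = cfg$s, n = cfg$n_sub,
      alpha = cfg$alpha_random, seed = derive_seed(seed, 31))
    selection <- forward_select_fixed(
      model_table, cfg$hfi, random = structure_sel$structure,
      reps = cfg$sel_reps, n = cfg$n_sub, alpha = cfg$alpha_fixed,
      keep_frac = cfg$keep_frac, seed = derive_seed(seed, 32))
    final <- fit_final(model_table, cfg$hfi, selection$terms,
                       random = structure_sel$structure,
                       boot_reps = cfg$boot_reps, n = cfg$n_sub,
                       seed = derive_seed(seed, 33))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("forage3d")),
    seed = seed, profile = cfg$profile,
    config = cfg[setdiff(names(cfg), "sim_args")],
    sim_args = cfg$sim_args,
    counts = list(
      n_dives = nrow(data$dives),
      n_dives_ok = sum(metrics$qc == "ok"),
      n_fixes = nrow(data$track),
      n_fixes_kept = nrow(pts),
      n_nodes = nrow(reg),
      n_segments = nrow(segs),
      n_retained = nrow(excl$retained),
      n_excluded = nrow(excl$excluded),
      exclusion_reasons = as.list(excl$counts),
      pct_excluded = round(100 * nrow(excl$excluded) / nrow(segs), 1)))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      write_stage_csv(data$track, out_dir, "track"),
      write_stage_csv(data$dives, out_dir, "dives"),
      write_stage_csv(data$haulouts, out_dir, "haulouts"),
      write_stage_csv(data$truth, out_dir, "ground_truth"),
      write_stage_csv(metrics, out_dir, "dive_metrics"),
      write_stage_csv(reg, out_dir, "regular_track"),
      write_stage_csv(model_table, out_dir, "model_table"),
      write_stage_csv(excl$excluded, out_dir, "exclusions"))
    write_esri_ascii(data$bathymetry, file.path(out_dir, "bathy.asc"))
    files <- c(files, file.path(out_dir, "bathy.asc"))
    if (!is.null(final)) {
      files <- c(files,
                 write_stage_csv(final$coefficients, out_dir,
                                 "coefficients"),
                 write_stage_csv(
                   data.frame(term = names(selection$frequency),
                              frequency = unname(selection$frequency)),
                   out_dir, "selection_trace"))
    }
    manifest$files <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(data = data, metrics = metrics, reg_track = reg,
       segments = segs, exclusions = excl, model_table = model_table,
       mixture = mix, structure = structure_sel,
       selection = selection, final = final, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
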