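# End-to-end orchestration: simulate -> diversity -> mask -> texture ->
# features -> regress -> compare, with a serialisable config and a manifest
# of every written artifact.

#' Pipeline run configuration
#'
#' Collects every knob of the pipeline into one serialisable list. Defaults
#' mirror the survey setup the package emulates: 0.5 m pixels, 20 m plot
#' radius, segment-mean vegetation-index threshold 0.4 (inclusive), windows
#' 3/5/7, 64 gray levels, 7 bands.
#'
#' @param seed Integer master seed; all stochastic stages derive from it.
#' @param scene [scene_params()] list or arguments for it.
#' @param plots [plot_design()] list or arguments for it.
#' @param mask_threshold Segment-mean WV-VI cutoff.
#' @param segmentation_scale Spectral cluster count for [segment_scene()].
#' @param ng Gray levels for quantization.
#' @param window_sizes GLCM window edge lengths.
#' @param aggregation Plot aggregation, `"mean"` or `"median"`.
#' @param reference Reference model for [comparison_suite()], `"auto"` or a
#'   group tag.
#' @param shannon_noise_sd,stems_lambda,pool_size Species sampling knobs
#'   (see [generate_species_counts()]).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       scene = list(),
                       plots = list(n_points = 240L, spacing_m = 16,
                                    radius_m = 20),
                       mask_threshold = 0.4,
                       segmentation_scale = 8L,
                       ng = 64L,
                       window_sizes = c(3L, 5L, 7L),
                       aggregation = "mean",
                       reference = "auto",
                       shannon_noise_sd = 0.21,
                       stems_lambda = 30,
                       pool_size = 26L) {
  sp <- if (inherits(scene, "scene_params")) scene else
    do.call(scene_params, c(scene, list(seed = seed)))
  pd <- if (inherits(plots, "plot_design")) plots else do.call(plot_design, plots)
  structure(list(seed = as.integer(seed), scene = sp, plots = pd,
                 mask_threshold = mask_threshold,
                 segmentation_scale = as.integer(segmentation_scale),
                 ng = as.integer(ng), window_sizes = as.integer(window_sizes),
                 aggregation = aggregation, reference = reference,
                 shannon_noise_sd = shannon_noise_sd,
                 stems_lambda = stems_lambda, pool_size = as.integer(pool_size)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip bit-identically: reading back a written file
#' reproduces the same `run_config`.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$scene <- unclass(x$scene)
  x$scene$texture_coupling <- as.list(x$scene$texture_coupling)
  x$scene$base_roughness <- as.list(x$scene$base_roughness)
  x$plots <- unclass(x$plots)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sc <- x$scene
  sc$texture_coupling <- unlist(sc$texture_coupling)
  sc$base_roughness <- unlist(sc$base_roughness)
  sc$diversity_range <- as.numeric(sc$diversity_range)
  scn_par <- do.call(scene_params, sc)
  pd <- do.call(plot_design, x$plots)
  run_config(seed = x$seed, scene = scn_par, plots = pd,
             mask_threshold = x$mask_threshold,
             segmentation_scale = x$segmentation_scale, ng = x$ng,
             window_sizes = x$window_sizes, aggregation = x$aggregation,
             reference = x$reference, shannon_noise_sd = x$shannon_noise_sd,
             stems_lambda = x$stems_lambda, pool_size = x$pool_size)
}

#' Run the full pipeline
#'
#' Executes all stages in order on a synthetic scene and, when `out_dir` is
#' given, writes every intermediate artifact (scene TIFF + sidecar, plots,
#' species counts, diversity table, mask, per-model and best-model report
#' CSVs, comparison CSV) plus a JSON manifest with MD5 checksums.
#' Re-running with the same config reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List of class `texdiv_run`: `config`, `scene`, `plots`, `counts`,
#'   `diversity`, `mask`, `stack`, `features`, `reports`, `comparison`,
#'   `manifest` (when written).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "simulate"
  result <- tryCatch({
    scn <- generate_scene(config$scene)
    plots <- generate_plots(config$plots, scn)
    latent <- plot_layer_mean(scn, plots, scn$latent$diversity)
    counts <- generate_species_counts(
      plots, latent, seed = config$seed + 1000L,
      pool_size = config$pool_size,
      shannon_noise_sd = config$shannon_noise_sd,
      stems_lambda = config$stems_lambda)

    stage <- "diversity"
    div <- diversity_table(counts)

    stage <- "mask"
    seg <- segment_scene(scn, scale = config$segmentation_scale)
    wm <- build_woody_mask(scn, seg, threshold = config$mask_threshold)
    if (!any(wm$mask)) {
      stop_texdiv("woody mask is empty at threshold ", config$mask_threshold,
                  class = "texdiv_empty_mask_error")
    }

    stage <- "texture"
    stack <- texture_stack(scn, wm, ng = config$ng,
                           window_sizes = config$window_sizes)

    stage <- "features"
    features <- extract_plot_features(stack, plots, div,
                                      agg = config$aggregation)

    stage <- "regress"
    reports <- all_subsets_by_group(features)

    stage <- "compare"
    comparison <- comparison_suite(reports, reference = config$reference)

    list(config = config, scene = scn, plots = plots, counts = counts,
         diversity = div, mask = wm, stack = stack, features = features,
         reports = reports, comparison = comparison)
  }, error = function(e) {
    stop_texdiv("pipeline failed at stage '", stage, "': ",
                conditionMessage(e), class = "texdiv_stage_error")
  })

  if (!is.null(out_dir)) {
    result$manifest <- write_run_artifacts(result, out_dir)
  }
  class(result) <- "texdiv_run"
  result
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  cfg <- run$config
  write_run_config(cfg, p("config.yaml"))
  write_scene(run$scene, p("scene.tif"))
  write_plots(run$plots, p("plots.geojson"))
  write_plots(run$plots, p("plots.csv"))
  write_species_counts(run$counts, p("species_counts.csv"))
  utils::write.csv(run$diversity, p("diversity.csv"), row.names = FALSE)
  write_grid(run$mask$mask, p("woody_mask.tif"),
             pixel_size = run$scene$pixel_size, origin = run$scene$origin,
             kind = "woody_mask")
  write_grid(run$mask$segment_ids, p("segments.tif"),
             pixel_size = run$scene$pixel_size, origin = run$scene$origin,
             kind = "segment_ids")
  utils::write.csv(run$features, p("features.csv"), row.names = FALSE)
  utils::write.csv(report_table(run$reports), p("models.csv"), row.names = FALSE)
  utils::write.csv(best_model_table(run$reports), p("best_models.csv"),
                   row.names = FALSE)
  utils::write.csv(run$comparison$table, p("comparisons.csv"), row.names = FALSE)

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    seed = cfg$seed,
    created = "run",  # no timestamp: manifests must be bit-reproducible
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.texdiv_run <- function(x, ...) {
  cat("texdiv_run, seed", x$config$seed, "\n")
  cat(sprintf("  %d plots, %d/%d woody px, %d regression groups\n",
              nrow(x$features), sum(x$mask$mask), length(x$mask$mask),
              length(x$reports)))
  bm <- best_model_table(x$reports)
  b <- bm[which.min(bm$aic), ]
  cat(sprintf("  global best: %s w%d {%s} adjR2=%.3f RMSE=%.3f\n",
              b$statistic, b$window, b$predictors, b$adj_r2, b$rmse))
  invisible(x)
}
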