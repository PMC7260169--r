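#' Order-preserving parallel map over independent sections
#'
#' Applies `fn` to each element of `x`, optionally across forked worker
#' processes. Sections must be independent (as halo-padded chunks are by
#' construction); results are returned in input order and are identical to
#' sequential execution regardless of worker count or completion order. A
#' failing section surfaces its index in the error.
#'
#' @param x List of sections.
#' @param fn Function applied to each section.
#' @param workers Worker count; 1 (or non-unix platforms) runs sequentially.
#' @return List of results, one per section, in order.
#' @export
parallel_map <- function(x, fn, workers = 1) {
  if (length(x) == 0) return(list())
  results <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(x, function(el) tryCatch(fn(el), error = identity),
                       mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(x, function(el) tryCatch(fn(el), error = identity))
  }
  bad <- which(vapply(results, inherits, logical(1), "condition"))
  if (length(bad))
    stop("parallel_map: section ", bad[1], " failed: ",
         conditionMessage(results[[bad[1]]]))
  results
}

#' End-to-end pipeline configuration
#'
#' Composes the synthetic-scale, stitching, segmentation and metrics
#' parameters with one global seed and an output directory. Every defaulted
#' field is materialized, so the configuration serializes losslessly to
#' YAML ([write_run_config()] / [read_run_config()]) and is recorded in the
#' run's provenance.
#'
#' The default geometry is a desk-scale analogue of the acquisition: scans
#' overlap by ~1/5 of the field of view (the 54 um / 10 um ratio) and carry
#' small seeded lateral/z jitter for the registration stage to recover.
#'
#' @param synthetic A [synthetic_scale_config()].
#' @param fov_voxels,overlap_voxels Scan splitting geometry (voxels).
#' @param jitter Bound on the per-scan z and lateral jitter (voxels).
#' @param search_window,lateral_window [find_overlap()] search half-widths.
#' @param segmentation A [segmentation_config()].
#' @param cube_edge,n_cubes,r_max,interior_margin Metrics parameters
#'   (cube sampling and correlation lags; `interior_margin` is the margin
#'   beyond the cuticle shell, voxels).
#' @param seed Global integer seed (propagated to the synthetic and
#'   sampling stages).
#' @param out_dir Default output directory for [run_pipeline()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_scale_config(
                         shape = c(96, 96, 520), seed = seed),
                       fov_voxels = 200, overlap_voxels = 40,
                       jitter = 2,
                       search_window = 10, lateral_window = 4,
                       segmentation = segmentation_config(),
                       cube_edge = 32, n_cubes = 25, r_max = 16,
                       interior_margin = 8,
                       seed = 1, out_dir = "scaletomo_run") {
  synthetic$seed <- as.integer(seed)
  structure(list(synthetic = synthetic,
                 fov_voxels = as.integer(fov_voxels),
                 overlap_voxels = as.integer(overlap_voxels),
                 jitter = as.integer(jitter),
                 search_window = as.integer(search_window),
                 lateral_window = as.integer(lateral_window),
                 segmentation = segmentation,
                 cube_edge = as.integer(cube_edge),
                 n_cubes = as.integer(n_cubes), r_max = as.integer(r_max),
                 interior_margin = as.integer(interior_margin),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(synthetic = unclass(config$synthetic),
                        segmentation = unclass(config$segmentation),
                        pipeline = unclass(config)[
                          !names(config) %in% c("synthetic", "segmentation")]),
                   path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path Path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_scale_config, y$synthetic)
  seg <- do.call(segmentation_config, y$segmentation)
  do.call(run_config, c(list(synthetic = syn, segmentation = seg),
                        y$pipeline))
}

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline: simulate, stitch, segment, measure
#'
#' Executes the stages in order, writing each intermediate volume, a
#' manifest of every emitted file, per-stage logs and a final JSON report
#' (interior fill, cube fill statistics, representative cube, stitch
#' diagnostics) into `out_dir`. Re-running with the same configuration and
#' seed reproduces all binary outputs bit-exactly. A stage failure aborts
#' with the stage name while preserving prior outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (default from the config).
#' @param workers Parallel workers for the denoising pass.
#' @param keep_intermediates Keep the greyscale intermediates (set `FALSE`
#'   to drop them after segmentation).
#' @return The report, invisibly (list with `interior_fill`,
#'   `cube_fill_mean`, `cube_fill_sd`, `representative_cube`,
#'   `stitch_scores`, paths).
#' @export
run_pipeline <- function(config, out_dir = config$out_dir, workers = 1,
                         keep_intermediates = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run_log.jsonl")
  log_line <- function(stage, ...) {
    cat(jsonlite::toJSON(list(time = format(Sys.time()), stage = stage, ...),
                         auto_unbox = TRUE), "\n",
        file = logf, append = TRUE)
  }
  manifest <- list()
  write_run_config(config, file.path(out_dir, "config.yaml"))

  log_line("simulate", status = "start")
  truth <- stage_run("simulate", generate_truth(config$synthetic))
  grey <- stage_run("simulate", render_greyscale(truth, config$synthetic))
  scans <- stage_run("simulate", split_into_scans(
    grey, config$fov_voxels, config$overlap_voxels,
    lateral_jitter = config$jitter, seed = config$seed))
  manifest$truth <- write_packed(truth, file.path(out_dir, "truth.bits"))
  if (keep_intermediates) {
    manifest$grey <- write_volume(grey, file.path(out_dir, "greyscale.npy"))
    for (k in seq_along(scans$scans))
      manifest[[sprintf("scan_%02d", k)]] <- write_volume(
        scans$scans[[k]], file.path(out_dir, sprintf("scan_%02d.npy", k)))
  }
  jsonlite::write_json(list(z_offsets = scans$z_offsets,
                            lateral_shifts = scans$lateral_shifts),
                       file.path(out_dir, "true_offsets.json"),
                       auto_unbox = FALSE)
  log_line("simulate", status = "done", scans = length(scans$scans))

  log_line("stitch", status = "start")
  assembled <- stage_run("stitch", {
    if (length(scans$scans) > 1) {
      matches <- lapply(seq_len(length(scans$scans) - 1), function(k)
        find_overlap(scans$scans[[k]], scans$scans[[k + 1]],
                     nominal_frames = config$overlap_voxels,
                     search_window = config$search_window,
                     lateral_window = config$lateral_window))
      stitch(scans, matches)
    } else scans$scans[[1]]
  })
  plan <- attr(assembled, "stitch_plan")
  if (!is.null(plan))
    jsonlite::write_json(plan, file.path(out_dir, "stitch_diagnostics.json"),
                         auto_unbox = FALSE)
  if (keep_intermediates)
    manifest$assembled <- write_volume(assembled,
                                       file.path(out_dir, "assembled.npy"))
  log_line("stitch", status = "done",
           scores = if (!is.null(plan)) plan$scores else NULL)

  log_line("segment", status = "start")
  mask <- stage_run("segment", segment(assembled, config$segmentation,
                                       workers = workers))
  manifest$mask <- write_packed(mask, file.path(out_dir, "mask.bits"))
  jsonlite::write_json(attr(mask, "provenance"),
                       file.path(out_dir, "segment_provenance.json"),
                       auto_unbox = TRUE)
  log_line("segment", status = "done")

  log_line("metrics", status = "start")
  ct <- config$synthetic$cuticle_thickness_voxels
  m <- config$interior_margin
  margins <- c(ct + m, m, m)
  report <- stage_run("metrics", {
    ifill <- interior_fill_fraction(mask, margins)
    truth_ifill <- interior_fill_fraction(truth, margins)
    cubes <- sample_cubes(mask, edge = config$cube_edge, n = config$n_cubes,
                          seed = config$seed, interior_margin = margins)
    fs <- fill_stats(cubes)
    rep_idx <- representative_cube(cubes, r_max = config$r_max)
    avg <- attr(rep_idx, "avg_curves")
    utils::write.csv(
      data.frame(lag = 0:config$r_max, s2_x = avg$x, s2_y = avg$y,
                 s2_z = avg$z),
      file.path(out_dir, "correlation_curves.csv"), row.names = FALSE)
    list(interior_fill = ifill, truth_interior_fill = truth_ifill,
         cube_fill_mean = fs$mean,
         cube_fill_sd = fs$sd, n_cubes = fs$n,
         representative_cube = as.integer(rep_idx),
         truth_target_fill = 100 * config$synthetic$target_fill,
         stitch_scores = if (!is.null(plan)) plan$scores else numeric(0),
         seed = config$seed)
  })
  utils::write.csv(do.call(rbind, manifest),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("metrics", status = "done", interior_fill = report$interior_fill)
  invisible(report)
}
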