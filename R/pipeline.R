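# End-to-end orchestration: validated YAML configuration, stage-by-stage
# execution in the canonical order (simulate/load -> motion -> baseline ->
# detect -> segment -> statistics), intermediate artifacts, and a manifest
# with parameters, seeds and file checksums. Re-running with the same
# config and seed reproduces identical outputs; the master seed fans out
# to per-stage seeds by stable hashing.

config_defaults <- function() {
  list(
    seed = 1L,
    log_level = "info",
    io = list(output_dir = "astroca_out", input_stem = NULL,
              frame_interval = NULL, save_intermediates = TRUE),
    synthetic = as.list(unclass(movie_params())),
    motion = list(enabled = TRUE, reference = "template", lambda = 40,
                  n_iter = 60, pyramid_levels = 3, rho = 2,
                  subpixel = TRUE, flow = TRUE),
    baseline = list(r = 20, n_iter = 10, p = 0.1, lambda = 1e4,
                    window_frames = 30, window_px = 16),
    detection = as.list(unclass(detection_params())),
    segmentation = as.list(unclass(segmentation_params())),
    events = list(min_duration = 2, min_rel_increase = 0.2,
                  stim_start_frame = NULL, stim_end_frame = NULL)
  )
}

merge_block <- function(defaults, user, path) {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    abort_field(path, "must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste0(path, ".", unknown, collapse = ", ")), call. = FALSE)
  for (k in names(user)) defaults[k] <- list(user[[k]])
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts YAML text, a YAML file path, or a list; fills defaults,
#' rejects unknown keys, and type-checks every stage block against its
#' module's parameter constructor. An empty document yields the full
#' default configuration.
#'
#' @param raw YAML string, path to a YAML file, or a list.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(raw = NULL) {
  user <- if (is.null(raw)) list()
  else if (is.list(raw)) raw
  else if (file.exists(raw)) yaml::read_yaml(raw) %||% list()
  else yaml::yaml.load(raw) %||% list()
  defs <- config_defaults()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- defs
  for (blk in names(defs)) {
    if (is.list(defs[[blk]]))
      cfg[[blk]] <- merge_block(defs[[blk]], user[[blk]], blk)
    else if (!is.null(user[[blk]])) cfg[[blk]] <- user[[blk]]
  }
  check_scalar(cfg$seed, "seed", integerish = TRUE)
  # delegate stage validation to the parameter constructors
  cfg$synthetic <- unclass(do.call(movie_params, cfg$synthetic))
  do.call(detection_params, cfg$detection)
  do.call(segmentation_params, cfg$segmentation)
  check_scalar(cfg$baseline$r, "baseline.r", lower = 1, integerish = TRUE)
  check_scalar(cfg$baseline$p, "baseline.p", lower = 0, upper = 1)
  check_scalar(cfg$motion$lambda, "motion.lambda", lower = 0,
               strict_lower = TRUE)
  check_scalar(cfg$events$min_duration, "events.min_duration", lower = 1,
               integerish = TRUE)
  if (is.null(cfg$io$input_stem) && is.null(cfg$synthetic))
    abort_field("io.input_stem", "either an input movie or a synthetic block is required")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize a configuration back to YAML
#'
#' `validate_config(serialize_config(cfg))` reproduces `cfg`.
#'
#' @param cfg a `pipeline_config`.
#' @return YAML string.
#' @export
serialize_config <- function(cfg) {
  yaml::as.yaml(unclass(cfg))
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[astroca] %s", sprintf(...)))
}

run_stage <- function(name, cfg, expr) {
  log_msg(cfg, "stage %s", name)
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order on a synthetic dataset (or TIFF input when
#' `io.input_stem` is set): motion correction, baseline estimation and
#' dF/F0, selective-averaging detection, ROI segmentation and
#' classification, trace extraction and per-ROI event statistics. Writes
#' intermediate artifacts, the per-ROI statistics table
#' (`roi_event_stats.csv`) and a manifest (`manifest.json`) listing every
#' output with its MD5 checksum, the parameters and the seeds used.
#'
#' @param config a `pipeline_config` from [validate_config()], or anything
#'   that function accepts.
#' @return invisibly, a list with the in-memory results: `movie`
#'   (corrected), `motion`, `baseline`, `dff`, `denoised`, `rois`,
#'   `traces`, `stats`, `manifest`, `truth` (when synthetic).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  out_dir <- cfg$io$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  save_one <- function(stack, name) {
    if (!isTRUE(cfg$io$save_intermediates)) return(invisible())
    f <- file.path(out_dir, name)
    write_stack_tiff(stack, f)
    files <<- c(files, f)
  }

  truth <- NULL
  movie <- run_stage("input", cfg, {
    if (!is.null(cfg$io$input_stem)) {
      read_movie_tiff(cfg$io$input_stem, cfg$io$frame_interval %||% 1)
    } else {
      sp <- cfg$synthetic
      sp$seed <- derive_seed(cfg$seed, "synthetic")
      sim <- generate_movie(do.call(movie_params, sp))
      truth <<- sim$truth
      sim$movie
    }
  })

  corrected <- run_stage("motion", cfg, {
    if (isTRUE(cfg$motion$enabled)) {
      mc <- correct_motion(movie, reference = cfg$motion$reference,
                           lambda = cfg$motion$lambda,
                           n_iter = cfg$motion$n_iter,
                           pyramid_levels = cfg$motion$pyramid_levels,
                           rho = cfg$motion$rho,
                           subpixel = isTRUE(cfg$motion$subpixel),
                           flow = isTRUE(cfg$motion$flow))
      mc
    } else list(movie = movie, motion = NULL)
  })
  save_one(corrected$movie$functional, "corrected_functional.tif")
  save_one(corrected$movie$structural, "corrected_structural.tif")

  bl <- run_stage("baseline", cfg, {
    estimate_baseline(corrected$movie$functional, r = cfg$baseline$r,
                      n_iter = cfg$baseline$n_iter, p = cfg$baseline$p,
                      lambda = cfg$baseline$lambda,
                      window_frames = cfg$baseline$window_frames,
                      window_px = cfg$baseline$window_px)
  })
  save_one(bl$F0, "baseline_f0.tif")
  dff <- run_stage("dff", cfg, compute_dff(corrected$movie$functional, bl))
  save_one(dff$dff, "dff.tif")

  det <- run_stage("detect", cfg, {
    selective_average_movie(dff, do.call(detection_params, cfg$detection))
  })
  save_one(det$denoised, "denoised.tif")
  save_one(det$transient_mask * 1, "transient_mask.tif")

  rois <- run_stage("segment", cfg, {
    rs <- segment_rois(corrected$movie$structural,
                       do.call(segmentation_params, cfg$segmentation))
    if (nrow(rs$rois) > 0)
      rs <- suppressMessages(classify_compartments(
        rs, vessel_map = if (!is.null(truth)) truth$vessel_mask else NULL))
    rs
  })

  stats_df <- run_stage("stats", cfg, {
    nt <- n_frames(corrected$movie)
    s0 <- cfg$events$stim_start_frame %||% (nt %/% 3 + 1L)
    s1 <- cfg$events$stim_end_frame %||% (2L * (nt %/% 3))
    if (nrow(rois$rois) > 0) {
      act <- roi_activity(det, rois)
      roi_event_table(act, c(s0, s1), corrected$movie$frame_interval,
                      cfg$events$min_duration, rois$rois$class,
                      traces = extract_traces(det, rois))
    } else data.frame()
  })
  traces <- if (nrow(rois$rois) > 0) extract_traces(det, rois) else NULL

  stats_file <- file.path(out_dir, "roi_event_stats.csv")
  utils::write.csv(stats_df, stats_file, row.names = FALSE)
  roi_file <- file.path(out_dir, "roi_table.csv")
  utils::write.csv(rois$rois, roi_file, row.names = FALSE)
  files <- c(files, stats_file, roi_file)

  manifest <- list(
    package_version = as.character(utils::packageVersion("astroca")),
    seed = cfg$seed,
    stage_seeds = list(synthetic = derive_seed(cfg$seed, "synthetic")),
    config = unclass(cfg),
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log_msg(cfg, "done: %d ROIs, outputs in %s", nrow(rois$rois), out_dir)
  invisible(list(movie = corrected$movie, motion = corrected$motion,
                 baseline = bl, dff = dff, denoised = det, rois = rois,
                 traces = traces, stats = stats_df, manifest = manifest,
                 truth = truth))
}
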