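#' Build a run configuration
#'
#' Collects everything one end-to-end run needs. `video` (and optional
#' `reflectance`, `mask`) may be file paths or in-memory objects
#' ([imaging_session()] / [roi_mask()]).
#'
#' @param video multi-page TIFF path or an [imaging_session()].
#' @param output_dir directory for all outputs (created if missing).
#' @param frame_rate,um_per_px acquisition metadata (used when `video` is a
#'   path).
#' @param stimulus a [stimulus_spec()].
#' @param reflectance optional co-registered reflectance channel; when given,
#'   motion is estimated on it and applied to the fluorescence video.
#' @param mask optional ROI mask (label TIFF path or [roi_mask()]); when
#'   absent, [auto_segment()] is used.
#' @param register run motion correction?
#' @param noise_band noise band in Hz.
#' @param n_cycles whole-cycle analysis window (`"auto"` or integer).
#' @param polarity_half_width ON/OFF classification half-width, radians.
#' @param rayleigh_significant_only restrict the Rayleigh test to significant
#'   cells?
#' @param min_roi_area minimum ROI area in pixels.
#' @param segment_params named list of overrides for [auto_segment()].
#' @param condition free-text condition label.
#' @param seed integer seed for any stochastic step.
#' @return An object of class `run_config`.
#' @export
run_config <- function(video, output_dir, frame_rate = 25, um_per_px = 1,
                       stimulus = stimulus_spec(), reflectance = NULL,
                       mask = NULL, register = TRUE, noise_band = c(10, 12),
                       n_cycles = "auto", polarity_half_width = pi / 2,
                       rayleigh_significant_only = TRUE, min_roi_area = 4,
                       segment_params = list(), condition = "", seed = 1L) {
  cfg <- as.list(environment())
  for (field in c("video", "reflectance", "mask")) {
    v <- cfg[[field]]
    if (is.character(v) && !file.exists(v))
      stopf("config: %s path does not exist: %s", field, v)
  }
  if (is.null(cfg$video)) stopf("config: video is required")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [run_config()] arguments; the `stimulus`
#' block maps onto [stimulus_spec()].
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$stimulus)) y$stimulus <- do.call(stimulus_spec, y$stimulus)
  y <- utils::modifyList(y, list(...))
  do.call(run_config, y)
}

pipeline_stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full response-extraction pipeline
#'
#' register -> activity maps -> segment (or load mask) -> extract ->
#' quantify -> classify polarity -> summarize. Every stage's outputs are
#' written under `output_dir` together with a manifest (input hashes, config,
#' package version) and a stage-granularity log that reports cell counts at
#' each filtering step. Re-running an identical config reproduces identical
#' numeric outputs; on failure a `FAILED` marker naming the stage is left
#' next to any partial outputs.
#'
#' @param config a [run_config()].
#' @return list with `records`, `summary`, `maps`, `mask`, `shifts`,
#'   `histogram`, `output_dir`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  on_fail <- function(stage_msg)
    writeLines(stage_msg, file.path(config$output_dir, "FAILED"))
  result <- tryCatch(
    run_pipeline_impl(config, log),
    error = function(e) {
      on_fail(conditionMessage(e))
      writeLines(log_lines, log_path)
      stop(e)
    })
  unlink(file.path(config$output_dir, "FAILED"))
  writeLines(log_lines, log_path)
  invisible(result)
}

run_pipeline_impl <- function(config, log) {
  set.seed(config$seed)
  out_dir <- config$output_dir
  hashes <- list()

  session <- pipeline_stage("read", log, {
    if (is.character(config$video)) {
      hashes$video <- as.vector(tools::md5sum(config$video))
      read_stack(config$video, config$frame_rate, config$um_per_px)
    } else config$video
  })
  log(sprintf("read: %d frames of %d x %d px", n_frames(session),
              dim(session$frames)[1], dim(session$frames)[2]))

  shifts <- NULL
  if (isTRUE(config$register)) {
    session <- pipeline_stage("register", log, {
      motion_src <- session
      if (!is.null(config$reflectance)) {
        motion_src <- if (is.character(config$reflectance)) {
          hashes$reflectance <- as.vector(tools::md5sum(config$reflectance))
          read_stack(config$reflectance, config$frame_rate,
                     config$um_per_px, channel = "reflectance")
        } else config$reflectance
      }
      shifts <- estimate_shifts(motion_src)
      utils::write.csv(as.data.frame(shifts),
                       file.path(out_dir, "shifts.csv"), row.names = FALSE)
      correct_motion(session, shifts)
    })
    log(sprintf("register: max |shift| %.2f px",
                max(abs(c(shifts$dx, shifts$dy)))))
  }

  maps <- pipeline_stage("maps", log, {
    m <- pixelwise_maps(session, config$stimulus, config$n_cycles)
    write_maps(m, file.path(out_dir, "activity"))
    m
  })

  mask <- pipeline_stage("segment", log, {
    m <- if (is.null(config$mask)) {
      do.call(auto_segment, c(list(maps), config$segment_params))
    } else if (is.character(config$mask)) {
      hashes$mask <- as.vector(tools::md5sum(config$mask))
      read_mask(config$mask)
    } else {
      config$mask
    }
    # pixels within the maximum shift of the frame edge are replicate-filled
    # during motion correction; ROIs touching them are unreliable
    margin <- if (is.null(shifts)) 0
              else ceiling(max(abs(c(shifts$dx, shifts$dy))))
    m <- validate_mask(m, session, min_area = config$min_roi_area,
                       exclude_margin = margin)
    write_mask(m, file.path(out_dir, "mask.tif"))
    m
  })
  log(sprintf("segment: %d ROI(s), %d dropped below %d px",
              length(mask$roi_ids), attr(mask, "n_dropped") %||% 0L,
              config$min_roi_area))

  records <- pipeline_stage("quantify", log, {
    recs <- extract_timecourses(session, mask)
    recs <- lapply(recs, quantify_cell, frame_rate = session$frame_rate,
                   stimulus = config$stimulus, band = config$noise_band,
                   n_cycles = config$n_cycles)
    sig_ph <- vapply(Filter(function(r) isTRUE(r$significant), recs),
                     `[[`, 0, "phase")
    if (length(sig_ph) >= 2) {
      oc <- estimate_on_center(sig_ph)
      recs <- lapply(recs, function(r) {
        if (isTRUE(r$significant))
          r$polarity <- classify_polarity(r$phase, oc,
                                          config$polarity_half_width)
        r
      })
      log(sprintf("quantify: ON center estimated at %.2f rad", oc))
    }
    write_records_csv(recs, file.path(out_dir, "cell_records.csv"))
    recs
  })
  n_invalid <- sum(!vapply(records, function(r) isTRUE(r$valid), TRUE))
  log(sprintf("quantify: of %d cells analyzed, %d showed significant responses (%d invalid F0 excluded)",
              length(records),
              sum(vapply(records, function(r) isTRUE(r$significant), TRUE)),
              n_invalid))

  summary <- hist <- NULL
  if (length(Filter(function(r) isTRUE(r$valid), records))) {
    summary <- pipeline_stage("summarize", log, {
      s <- summarize_population(records, config$condition,
                                config$rayleigh_significant_only)
      utils::write.csv(
        data.frame(condition = s$condition,
                   n_cells_analyzed = s$n_cells_analyzed,
                   n_significant = s$n_significant,
                   mean_norm_response = s$mean_norm_response,
                   sd_norm_response = s$sd_norm_response,
                   rayleigh_z = s$rayleigh_z, rayleigh_p = s$rayleigh_p),
        file.path(out_dir, "population_summary.csv"), row.names = FALSE)
      h <- phase_histogram(records, significant_only = TRUE)
      utils::write.csv(
        data.frame(bin_low = h$breaks[-length(h$breaks)],
                   bin_high = h$breaks[-1], count = h$counts),
        file.path(out_dir, "phase_histogram.csv"), row.names = FALSE)
      hist <- h
      s
    })
    log(sprintf("summarize: response %.3f +/- %.3f, Rayleigh p = %.3g",
                summary$mean_norm_response, summary$sd_norm_response,
                summary$rayleigh_p))
  } else log("summarize: skipped (no valid cells)")

  manifest <- list(
    package_version = as.character(utils::packageVersion("facile")),
    r_version = R.version.string,
    input_hashes = hashes,
    config = serializable_config(config),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(records = records, summary = summary, maps = maps, mask = mask,
       shifts = shifts, histogram = hist, output_dir = out_dir)
}

# drop in-memory objects from the config before writing it to the manifest
serializable_config <- function(config) {
  cfg <- unclass(config)
  for (field in c("video", "reflectance", "mask"))
    if (!is.character(cfg[[field]])) cfg[[field]] <- NULL
  cfg$stimulus <- unclass(cfg$stimulus)
  cfg
}
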