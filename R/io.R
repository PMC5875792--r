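#' Read a multi-page TIFF stack as an imaging session
#'
#' If a `<path>.json` scaling sidecar written by [write_stack()] is present,
#' the stored affine scaling is inverted so physical intensities round-trip.
#' Foreign single-channel TIFFs read without it (values as stored).
#'
#' @param path TIFF file, one page per frame.
#' @param frame_rate,um_per_px,channel acquisition metadata (not stored in
#'   the TIFF).
#' @return An [imaging_session()].
#' @export
read_stack <- function(path, frame_rate, um_per_px = 1,
                       channel = "fluorescence") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stopf("cannot read TIFF %s: %s",
                                              path, conditionMessage(e)))
  if (!length(pages)) stopf("TIFF %s contains no pages", path)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), dim(pages[[1]])))
      stopf("TIFF %s: page %d has a different shape", path, i)
    frames[, , i] <- pages[[i]]
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (identical(meta$format, "facile-stack-v1"))
      frames <- frames * meta$span + meta$min
  }
  imaging_session(frames, frame_rate, um_per_px, channel)
}

#' Write an imaging session as a scaled 32-bit multi-page TIFF
#'
#' TIFF samples are stored as 32-bit integers scaled to the stack's intensity
#' range (the tiff package offers no float sample format on write), and the
#' affine scaling is recorded in a `<path>.json` sidecar so [read_stack()]
#' restores physical intensities. Quantisation error is below `1e-9` of the
#' stack's intensity span.
#'
#' @param session an [imaging_session()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(session, path) {
  stopifnot(inherits(session, "imaging_session"))
  rng <- range(session$frames)
  span <- rng[2] - rng[1]
  scaled <- if (span > 0) (session$frames - rng[1]) / span
            else array(0, dim = dim(session$frames))
  pages <- lapply(seq_len(n_frames(session)), function(i) scaled[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(format = "facile-stack-v1",
                            min = rng[1], span = span,
                            n_frames = n_frames(session)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI label mask from a 16-bit TIFF
#'
#' @param path label TIFF written by [write_mask()] (integer labels,
#'   0 = background).
#' @return An [roi_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) stopf("cannot read TIFF %s: %s",
                                            path, conditionMessage(e)))
  roi_mask(matrix(as.integer(img), nrow(img), ncol(img)))
}

#' Write an ROI label mask as a 16-bit TIFF
#'
#' @param mask an [roi_mask()]; labels must not exceed 65535.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  if (length(mask$roi_ids) && max(mask$roi_ids) > 65535)
    stopf("labels exceed the 16-bit range")
  tiff::writeTIFF(mask$label_image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write quantified cell records as CSV
#'
#' @param records list of `cell_record`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records_to_df(records), path, row.names = FALSE)
  invisible(path)
}

#' Write activity maps as scaled 32-bit TIFFs with a JSON convention sidecar
#'
#' One TIFF per map (`sum`, `f0`, `f1_amp`, `f1_phase`, `norm`), each scaled
#' to `[0, 1]` over its own range for storage, plus `<prefix>_maps.json`
#' recording the per-map affine scaling (`map_scaling`: physical value =
#' stored value x `span` + `min`) alongside the amplitude and phase
#' conventions.
#'
#' @param maps an `activity_maps` object.
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "activity_maps"))
  files <- c(sum = "sum", f0 = "f0", f1_amp = "f1_amp",
             f1_phase = "f1_phase", norm = "norm")
  imgs <- list(maps$sum_image, maps$f0_map, maps$f1_amp_map,
               maps$f1_phase_map,
               ifelse(is.na(maps$norm_map), 0, maps$norm_map))
  paths <- paste0(prefix, "_", files, ".tif")
  scaling <- list()
  for (i in seq_along(paths)) {
    rng <- range(imgs[[i]])
    span <- rng[2] - rng[1]
    scaled <- if (span > 0) (imgs[[i]] - rng[1]) / span else imgs[[i]] * 0
    tiff::writeTIFF(scaled, paths[i], bits.per.sample = 32L, reduce = FALSE)
    scaling[[unname(files[i])]] <- list(min = rng[1], span = span)
  }
  meta <- list(
    amplitude_convention = "2|X_k|/N (cosine amplitude)",
    phase_convention = "DFT argument, origin at stimulus onset, (-pi, pi]",
    map_scaling = scaling,
    stimulus_frequency_hz = maps$stimulus$frequency,
    frame_rate_hz = maps$frame_rate, n_frames_used = maps$n_used,
    um_per_px = maps$um_per_px,
    invalid_pixels = sum(!maps$valid))
  json <- paste0(prefix, "_maps.json")
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, json))
}

#' Write synthetic ground truth as JSON
#'
#' @param truth a `ground_truth` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(cells = truth$cells,
         motion_trajectory = truth$motion_trajectory,
         field = unclass(truth$field_spec), seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
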