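#' Imaging session container
#'
#' Bundles a fluorescence (or reflectance) frame stack with its acquisition
#' metadata. Frames are stored as a numeric array `height x width x n_frames`
#' in arbitrary fluorescence units.
#'
#' @param frames numeric array `height x width x n_frames` (a single matrix is
#'   promoted to one frame). All values must be finite.
#' @param frame_rate acquisition rate in Hz (> 0).
#' @param um_per_px pixel scale in micrometers per pixel (> 0).
#' @param channel `"fluorescence"` or `"reflectance"`.
#' @param registered logical; has motion correction been applied?
#' @return An object of class `imaging_session`.
#' @export
imaging_session <- function(frames, frame_rate, um_per_px = 1,
                            channel = c("fluorescence", "reflectance"),
                            registered = FALSE) {
  channel <- match.arg(channel)
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stopf("frames must be a height x width x n_frames array")
  if (!all(is.finite(frames))) stopf("frames contain non-finite values")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stopf("frame_rate must be a positive scalar (Hz)")
  if (um_per_px <= 0) stopf("um_per_px must be positive")
  structure(
    list(frames = frames, frame_rate = frame_rate, um_per_px = um_per_px,
         channel = channel, registered = registered),
    class = "imaging_session")
}

#' @export
print.imaging_session <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<imaging_session> %d x %d px, %d frames @ %g Hz, %g um/px, %s%s\n",
    d[1], d[2], d[3], x$frame_rate, x$um_per_px, x$channel,
    if (isTRUE(x$registered)) " (registered)" else ""))
  invisible(x)
}

#' Number of frames in an imaging session
#'
#' @param session an [imaging_session()].
#' @return integer frame count.
#' @export
n_frames <- function(session) dim(session$frames)[3]

#' Periodic visual stimulus description
#'
#' @param frequency temporal frequency in Hz (> 0); the study's uniform-field
#'   stimulus is 0.2 Hz.
#' @param waveform `"square"` or `"sine"`.
#' @param onset_frame 0-based index of the frame at which the stimulus cycle
#'   starts (light-on for a square wave); analysis windows begin here.
#' @param duty on-fraction of the square-wave period, in (0, 1).
#' @param wavelength_nm stimulus wavelength in nm (metadata only).
#' @param power_uW stimulus power at the pupil in microwatts (metadata only).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(frequency = 0.2, waveform = c("square", "sine"),
                          onset_frame = 0L, duty = 0.5,
                          wavelength_nm = NA_real_, power_uW = NA_real_) {
  waveform <- match.arg(waveform)
  if (frequency <= 0) stopf("stimulus frequency must be positive")
  if (onset_frame < 0) stopf("onset_frame must be >= 0")
  if (duty <= 0 || duty >= 1) stopf("duty must lie in (0, 1)")
  if (!is.na(power_uW) && power_uW < 0) stopf("power_uW must be >= 0")
  structure(
    list(frequency = frequency, waveform = waveform,
         onset_frame = as.integer(onset_frame), duty = duty,
         wavelength_nm = wavelength_nm, power_uW = power_uW),
    class = "stimulus_spec")
}

#' Evaluate the stimulus drive waveform at given frame times
#'
#' Returns the zero-mean drive: +1/2 during light-on and -1/2 during
#' light-off for a square wave (so peak-to-trough is 1), or a half-amplitude
#' cosine-phase sine for `"sine"`. Time zero is the stimulus onset.
#'
#' @param stimulus a [stimulus_spec()].
#' @param t numeric vector of times in seconds relative to onset.
#' @return numeric vector in `[-0.5, 0.5]`.
#' @export
stimulus_drive <- function(stimulus, t) {
  ph <- (stimulus$frequency * t) %% 1
  if (stimulus$waveform == "square") {
    ifelse(ph < stimulus$duty, 0.5, -0.5)
  } else {
    0.5 * sin(2 * pi * ph)
  }
}
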