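#' Integrated-fluorescence SUM image
#'
#' Per-pixel sum of all frames in a session; the intensity cue image used for
#' cell segmentation.
#'
#' @param session an [imaging_session()].
#' @return numeric matrix `height x width`.
#' @export
compute_sum_image <- function(session) {
  stopifnot(inherits(session, "imaging_session"))
  if (n_frames(session) < 1) stopf("session has no frames")
  rowSums(session$frames, dims = 2)
}

# Shared truncation logic: window [start, start + n_use) covering a whole
# number of stimulus cycles. Returns 1-based start index, sample count and
# the DFT bin (0-based) of the stimulus fundamental.
f1_window <- function(n, frame_rate, stimulus, n_cycles = "auto") {
  if (stimulus$frequency >= frame_rate / 2)
    stopf("stimulus frequency %g Hz is at or above Nyquist (%g Hz)",
          stimulus$frequency, frame_rate / 2)
  period <- frame_rate / stimulus$frequency      # samples per cycle
  avail <- n - stimulus$onset_frame
  cycles <- floor(avail / period + 1e-9)
  if (!identical(n_cycles, "auto")) {
    if (n_cycles > cycles)
      stopf("requested %d cycles but only %d are available", n_cycles, cycles)
    cycles <- as.integer(n_cycles)
  }
  if (cycles < 1)
    stopf("trace too short: %d samples after onset, one cycle needs %g",
          avail, period)
  n_use <- as.integer(round(cycles * period))
  list(start = stimulus$onset_frame + 1L, n_use = n_use,
       bin = as.integer(round(stimulus$frequency * n_use / frame_rate)))
}

#' Fundamental-harmonic (F1) analysis of a response time course
#'
#' Truncates the trace to a whole number of stimulus cycles starting at the
#' stimulus onset, then reports the mean (F0) and the amplitude and phase of
#' the Fourier component at the stimulus frequency (F1). The amplitude
#' convention is `2|X_k|/N`: a pure cosine of amplitude `a` at the stimulus
#' frequency returns `F1 = a`, so `F1/F0` is directly the normalized response.
#' Phase is the DFT argument with time origin at the analysis-window start
#' (the stimulus onset), wrapped to `(-pi, pi]`; a cosine peaking at onset has
#' phase 0, and antiphase responses differ by pi.
#'
#' @param trace numeric vector, one sample per frame.
#' @param frame_rate sampling rate in Hz.
#' @param stimulus a [stimulus_spec()].
#' @param n_cycles `"auto"` (use all whole cycles) or a positive integer.
#' @return list with `f0`, `f1`, `phase`, `n_used`, `bin`.
#' @export
f1_analysis <- function(trace, frame_rate, stimulus, n_cycles = "auto") {
  if (!all(is.finite(trace))) stopf("trace contains non-finite values")
  w <- f1_window(length(trace), frame_rate, stimulus, n_cycles)
  seg <- trace[seq.int(w$start, length.out = w$n_use)]
  X <- stats::fft(seg)
  xk <- X[w$bin + 1L]
  list(f0 = mean(seg),
       f1 = 2 * Mod(xk) / w$n_use,
       phase = wrap_pi(Arg(xk)),
       n_used = w$n_use, bin = w$bin)
}

# Vectorised F1 over the columns of a samples x traces matrix.
# Returns f0, f1, phase vectors (one element per column).
f1_analysis_matrix <- function(traces, frame_rate, stimulus, n_cycles = "auto") {
  w <- f1_window(nrow(traces), frame_rate, stimulus, n_cycles)
  seg <- traces[seq.int(w$start, length.out = w$n_use), , drop = FALSE]
  X <- stats::mvfft(seg)[w$bin + 1L, ]
  list(f0 = colMeans(seg), f1 = 2 * Mod(X) / w$n_use,
       phase = wrap_pi(Arg(X)), n_used = w$n_use, bin = w$bin)
}

#' Pixel-wise activity maps at the stimulus frequency
#'
#' Applies [f1_analysis()] to every pixel's trace and assembles the SUM,
#' F0, F1-amplitude, F1-phase and normalized (F1/F0) maps for a session.
#' Pixels with `F0 <= 0` are flagged invalid (`NA` in `norm_map`) rather than
#' producing infinities.
#'
#' @param session a registered [imaging_session()] (an unregistered session is
#'   accepted; residual motion blurs the maps).
#' @param stimulus a [stimulus_spec()].
#' @param n_cycles passed to [f1_analysis()].
#' @return An object of class `activity_maps`: list of matrices `sum_image`,
#'   `f0_map`, `f1_amp_map`, `f1_phase_map`, `norm_map`, plus `valid` (logical
#'   matrix) and the analysis metadata.
#' @export
pixelwise_maps <- function(session, stimulus, n_cycles = "auto") {
  stopifnot(inherits(session, "imaging_session"))
  d <- dim(session$frames)
  traces <- matrix(aperm(session$frames, c(3, 1, 2)), nrow = d[3])
  r <- f1_analysis_matrix(traces, session$frame_rate, stimulus, n_cycles)
  shape <- function(v) matrix(v, d[1], d[2])
  f0 <- shape(r$f0)
  f1 <- shape(r$f1)
  valid <- f0 > 0
  norm <- ifelse(valid, f1 / f0, NA_real_)
  structure(
    list(sum_image = compute_sum_image(session), f0_map = f0, f1_amp_map = f1,
         f1_phase_map = shape(r$phase), norm_map = norm, valid = valid,
         frame_rate = session$frame_rate, um_per_px = session$um_per_px,
         stimulus = stimulus, n_used = r$n_used),
    class = "activity_maps")
}

#' @export
print.activity_maps <- function(x, ...) {
  cat(sprintf("<activity_maps> %d x %d px, F1 @ %g Hz over %d frames\n",
              nrow(x$f0_map), ncol(x$f0_map), x$stimulus$frequency, x$n_used))
  invisible(x)
}

#' Amplitude-spectrum noise estimate over a frequency band
#'
#' Mean and SD of the single-sided amplitude spectrum (`2|X|/N` convention,
#' matching [f1_analysis()]) over all DFT bins falling in `band`. The default
#' 10-12 Hz band sits well above the 0.2 Hz stimulus and its low harmonics, so
#' it estimates the recording-noise floor used by the mean + 3 SD
#' significance criterion.
#'
#' @param trace numeric vector.
#' @param frame_rate sampling rate in Hz.
#' @param band numeric length-2, `(low, high)` in Hz; must lie below Nyquist
#'   and contain at least 3 DFT bins.
#' @return list with `mean_amp`, `sd_amp`, `n_bins`, `band`.
#' @export
noise_spectrum <- function(trace, frame_rate, band = c(10, 12)) {
  n <- length(trace)
  if (band[1] <= 0 || band[2] <= band[1])
    stopf("band must satisfy 0 < low < high")
  if (band[2] > frame_rate / 2)
    stopf("band upper edge %g Hz exceeds Nyquist (%g Hz)", band[2],
          frame_rate / 2)
  freqs <- (seq_len(n) - 1) * frame_rate / n
  keep <- which(freqs >= band[1] & freqs <= band[2] & freqs <= frame_rate / 2)
  if (length(keep) < 3)
    stopf("noise band [%g, %g] Hz contains only %d DFT bins (need >= 3)",
          band[1], band[2], length(keep))
  amps <- 2 * Mod(stats::fft(trace)[keep]) / n
  list(mean_amp = mean(amps),
       sd_amp = if (length(amps) > 1) stats::sd(amps) else 0,
       n_bins = length(keep), band = band)
}

# noise_spectrum over columns of a samples x traces matrix (one fft pass)
noise_spectrum_matrix <- function(traces, frame_rate, band = c(10, 12)) {
  n <- nrow(traces)
  freqs <- (seq_len(n) - 1) * frame_rate / n
  keep <- which(freqs >= band[1] & freqs <= band[2] & freqs <= frame_rate / 2)
  if (length(keep) < 3)
    stopf("noise band [%g, %g] Hz contains only %d DFT bins (need >= 3)",
          band[1], band[2], length(keep))
  A <- 2 * Mod(stats::mvfft(traces)[keep, , drop = FALSE]) / n
  list(mean_amp = colMeans(A), sd_amp = apply(A, 2, stats::sd),
       n_bins = length(keep), band = band)
}
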