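#' Fill a cell record's response statistics
#'
#' Runs the fundamental-harmonic analysis on the cell's ROI-averaged time
#' course, estimates the noise floor from the high-frequency amplitude
#' spectrum of the same analysis window, and applies the significance rule:
#' a cell responds significantly when its F1 amplitude strictly exceeds the
#' noise mean plus three noise SDs. Cells with nonpositive F0 are flagged
#' invalid and excluded from population summaries.
#'
#' @param record a `cell_record` from [extract_timecourses()].
#' @param frame_rate sampling rate in Hz.
#' @param stimulus a [stimulus_spec()].
#' @param band noise band in Hz (default `c(10, 12)`).
#' @param n_cycles passed to [f1_analysis()].
#' @return The record with `f0`, `f1`, `phase`, `norm_response`,
#'   `noise_mean`, `noise_sd`, `significant` and `valid` filled.
#' @export
quantify_cell <- function(record, frame_rate, stimulus, band = c(10, 12),
                          n_cycles = "auto") {
  stopifnot(inherits(record, "cell_record"))
  r <- f1_analysis(record$timecourse, frame_rate, stimulus, n_cycles)
  w <- f1_window(length(record$timecourse), frame_rate, stimulus, n_cycles)
  seg <- record$timecourse[seq.int(w$start, length.out = w$n_use)]
  ns <- noise_spectrum(seg, frame_rate, band)
  record$f0 <- r$f0
  record$f1 <- r$f1
  record$phase <- r$phase
  record$noise_mean <- ns$mean_amp
  record$noise_sd <- ns$sd_amp
  record$significant <- r$f1 > ns$mean_amp + 3 * ns$sd_amp
  if (r$f0 > 0) {
    record$norm_response <- r$f1 / r$f0
    record$valid <- TRUE
  } else {
    record$norm_response <- NA_real_
    record$valid <- FALSE
  }
  record
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether phases deviate from uniformity on the circle using the mean
#' resultant length: `z = n * r^2` with `r = |sum(exp(i phi))| / n`. The
#' p-value uses the standard large-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`, clamped to `[0, 1]`.
#'
#' @param phases numeric vector of phases in radians (n >= 2).
#' @return list with `z`, `p`, `n`, `r` (mean resultant length).
#' @export
rayleigh_test <- function(phases) {
  phases <- phases[is.finite(phases)]
  n <- length(phases)
  if (n < 2) stopf("rayleigh_test needs at least 2 finite phases")
  R <- Mod(sum(exp(1i * phases)))
  r <- R / n
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(z = z, p = min(max(p, 0), 1), n = n, r = r)
}

#' Estimate the ON-cluster phase center of a population
#'
#' Circular-mode estimate for phase distributions with two antipodal lobes
#' (ON and OFF): the doubled-phase mean resultant gives the cluster axis, and
#' the lobe holding more cells is taken as the ON center (assumes ON cells
#' are not the minority; supply `on_center` to [classify_polarity()] directly
#' when they are).
#'
#' @param phases numeric vector of phases in radians.
#' @return scalar phase in `(-pi, pi]`.
#' @export
estimate_on_center <- function(phases) {
  phases <- phases[is.finite(phases)]
  if (!length(phases)) stopf("no finite phases")
  axis <- wrap_pi(Arg(mean(exp(2i * phases))) / 2)
  in_lobe <- circ_dist(phases, axis) <= pi / 2
  center <- if (sum(in_lobe) >= length(phases) / 2) axis else wrap_pi(axis + pi)
  lobe <- phases[circ_dist(phases, center) <= pi / 2]
  if (length(lobe)) wrap_pi(Arg(mean(exp(1i * lobe)))) else center
}

#' Classify response polarity from phase
#'
#' ON if the phase lies within `half_width` of the ON center, OFF if within
#' `half_width` of the antipode, otherwise UNCLASSIFIED. With the default
#' quadrant rule (`half_width = pi/2`) only exact boundary phases are left
#' unclassified.
#'
#' @param phase phase(s) in radians.
#' @param on_center ON-cluster center in radians (see [estimate_on_center()]).
#' @param half_width classification half-width in radians (default `pi/2`).
#' @return character vector in `{"ON", "OFF", "UNCLASSIFIED"}`.
#' @export
classify_polarity <- function(phase, on_center, half_width = pi / 2) {
  d_on <- circ_dist(phase, on_center)
  d_off <- circ_dist(phase, on_center + pi)
  ifelse(d_on < half_width, "ON",
         ifelse(d_off < half_width, "OFF", "UNCLASSIFIED"))
}

#' Histogram of response phases
#'
#' Counts cell phases over an equal-width partition of `(-pi, pi]`.
#'
#' @param records list of quantified `cell_record`s.
#' @param n_bins number of bins (>= 4, default 18).
#' @param significant_only include only significantly responding cells?
#' @return list with `breaks` (length `n_bins + 1`), `counts`, `mids`.
#' @export
phase_histogram <- function(records, n_bins = 18, significant_only = TRUE) {
  if (n_bins < 4) stopf("n_bins must be >= 4")
  ph <- vapply(records, `[[`, 0, "phase")
  if (significant_only && length(records)) {
    sig <- vapply(records, function(r) isTRUE(r$significant), TRUE)
    ph <- ph[sig]
  }
  ph <- wrap_pi(ph[is.finite(ph)])
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  counts <- if (length(ph))
    as.vector(table(cut(ph, breaks, right = TRUE, include.lowest = FALSE)))
  else integer(n_bins)
  # wrap_pi maps -pi to +pi, so the open lower edge of the first bin is safe
  list(breaks = breaks, counts = counts,
       mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2)
}

#' Population summary of normalized responses
#'
#' Mean and SD (n - 1 denominator) of the normalized response over valid
#' cells, the significant-cell count under the mean + 3 SD rule, and a
#' Rayleigh test of the phase distribution.
#'
#' @param records list of quantified `cell_record`s.
#' @param condition free-text condition label (wavelength, group, age).
#' @param rayleigh_significant_only run the Rayleigh test on significant
#'   cells' phases only (default TRUE, as for the red-light analyses)?
#' @return An object of class `population_summary`.
#' @export
summarize_population <- function(records, condition = "",
                                 rayleigh_significant_only = TRUE) {
  valid <- Filter(function(r) isTRUE(r$valid), records)
  n_invalid <- length(records) - length(valid)
  if (n_invalid > 0)
    message(sprintf("summarize_population: excluded %d invalid cell(s)",
                    n_invalid))
  if (!length(valid)) stopf("no valid cell records to summarize")
  norm <- vapply(valid, `[[`, 0, "norm_response")
  sig <- vapply(valid, function(r) isTRUE(r$significant), TRUE)
  ph <- vapply(valid, `[[`, 0, "phase")
  ray_ph <- if (rayleigh_significant_only) ph[sig] else ph
  ray <- if (length(ray_ph) >= 2) rayleigh_test(ray_ph) else
    list(z = NA_real_, p = NA_real_, n = length(ray_ph), r = NA_real_)
  structure(
    list(condition = condition,
         n_cells_analyzed = length(valid),
         n_significant = sum(sig),
         mean_norm_response = mean(norm),
         sd_norm_response = if (length(norm) > 1) stats::sd(norm) else 0,
         single_cell = length(norm) == 1,
         rayleigh_z = ray$z, rayleigh_p = ray$p,
         n_excluded_invalid = n_invalid),
    class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "<population_summary> %s: of %d cells analyzed, %d significant; response %.3f +/- %.3f (mean +/- SD); Rayleigh z = %.2f, p = %.3g\n",
    x$condition, x$n_cells_analyzed, x$n_significant,
    x$mean_norm_response, x$sd_norm_response, x$rayleigh_z, x$rayleigh_p))
  invisible(x)
}

#' Convert a list of cell records to a data frame
#'
#' One row per cell with every scalar field; the layout used for the CSV
#' exports.
#'
#' @param records list of `cell_record`s.
#' @return data frame.
#' @export
records_to_df <- function(records) {
  if (!length(records))
    return(data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      n_pixels = integer(0), f0 = numeric(0), f1 = numeric(0),
                      phase = numeric(0), norm_response = numeric(0),
                      noise_mean = numeric(0), noise_sd = numeric(0),
                      significant = logical(0), polarity = character(0),
                      valid = logical(0)))
  do.call(rbind, lapply(records, function(r)
    data.frame(cell_id = r$cell_id, x = r$centroid[["x"]], y = r$centroid[["y"]],
               n_pixels = r$n_pixels, f0 = r$f0, f1 = r$f1, phase = r$phase,
               norm_response = r$norm_response, noise_mean = r$noise_mean,
               noise_sd = r$noise_sd, significant = r$significant,
               polarity = r$polarity, valid = r$valid)))
}
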