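#' Field geometry and cell-population settings for the synthetic generator
#'
#' Defaults emulate the study conditions: a 5 x 6.7 degree (160 x 215
#' micrometer) imaging field at the ganglion-cell layer, somata of roughly
#' 10-30 micrometer diameter with darkened nuclei.
#'
#' @param width_px,height_px field size in pixels (>= 16).
#' @param um_per_px pixel scale (> 0). The default 1 um/px makes the default
#'   field 215 x 160 um.
#' @param n_cells number of somata to place (>= 0).
#' @param cell_radius_um length-2 `(mean, sd)` of soma radius in micrometers;
#'   sampled radii are clipped at a 2 um floor.
#' @param nucleus_fraction nucleus radius as a fraction of soma radius,
#'   in `[0, 1)`; the nucleus renders darker than the cytosol.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(width_px = 215, height_px = 160, um_per_px = 1,
                       n_cells = 30, cell_radius_um = c(7.5, 2),
                       nucleus_fraction = 0.4) {
  if (width_px < 16 || height_px < 16) stopf("field must be at least 16 x 16 px")
  if (um_per_px <= 0) stopf("um_per_px must be positive")
  if (n_cells < 0) stopf("n_cells must be >= 0")
  if (length(cell_radius_um) != 2 || cell_radius_um[1] <= 0 ||
      cell_radius_um[2] < 0)
    stopf("cell_radius_um must be (mean > 0, sd >= 0)")
  if (nucleus_fraction < 0 || nucleus_fraction >= 1)
    stopf("nucleus_fraction must lie in [0, 1)")
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         um_per_px = um_per_px, n_cells = as.integer(n_cells),
         cell_radius_um = cell_radius_um, nucleus_fraction = nucleus_fraction),
    class = "field_spec")
}

#' Calcium-indicator impulse-response kinetics
#'
#' Difference-of-exponentials kernel parameters for the slow indicator
#' (GCaMP6s-like) low-pass filtering of the stimulus drive. Defaults (0.2 s
#' rise, 1.5 s decay) visibly smooth a 0.2 Hz square wave without abolishing
#' its modulation.
#'
#' @param rise_tau rise time constant in seconds (> 0).
#' @param decay_tau decay time constant in seconds (> rise_tau).
#' @return An object of class `indicator_kinetics`.
#' @export
indicator_kinetics <- function(rise_tau = 0.2, decay_tau = 1.5) {
  if (rise_tau <= 0) stopf("rise_tau must be positive")
  if (decay_tau <= rise_tau) stopf("decay_tau must exceed rise_tau")
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau),
            class = "indicator_kinetics")
}

#' Frame-to-frame eye-motion model
#'
#' A reflecting-boundary random walk in x and y; displacements are rounded to
#' whole pixels unless `subpixel = TRUE`.
#'
#' @param jitter_sd per-frame random-walk step SD in pixels (>= 0); 0 means no
#'   motion at all.
#' @param max_excursion reflecting boundary in pixels.
#' @param subpixel keep fractional displacements?
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(jitter_sd = 0, max_excursion = 5, subpixel = FALSE) {
  if (jitter_sd < 0) stopf("jitter_sd must be >= 0")
  if (max_excursion < 0) stopf("max_excursion must be >= 0")
  structure(list(jitter_sd = jitter_sd, max_excursion = max_excursion,
                 subpixel = subpixel), class = "motion_spec")
}

#' Place a population of model somata with known ground truth
#'
#' Rejection-samples non-overlapping cell centers (minimum spacing 1.5 x mean
#' radius), assigns each cell an ON/OFF/unresponsive polarity and a response
#' amplitude, and rasterises the matching label mask. Deterministic for a
#' fixed seed.
#'
#' @param spec a [field_spec()].
#' @param polarity_mix length-3 proportions over (ON, OFF, NONE); must sum
#'   to 1.
#' @param amplitude_range length-2 interval for the peak-to-trough response
#'   amplitude (fraction of baseline) of responsive cells.
#' @param seed integer RNG seed.
#' @param max_attempts placement attempts per cell before giving up.
#' @return An object of class `ground_truth`: `cells` (data frame with
#'   `cell_id`, `x`, `y`, `radius_px`, `polarity`, `response_amplitude`,
#'   `baseline`), `label_mask` (integer matrix), `field_spec`, `seed`;
#'   `motion_trajectory` is filled in by [render_video()].
#' @export
generate_cell_field <- function(spec, polarity_mix = c(0.5, 0.3, 0.2),
                                amplitude_range = c(0.1, 0.5), seed = 1L,
                                max_attempts = 200L) {
  stopifnot(inherits(spec, "field_spec"))
  if (length(polarity_mix) != 3 || any(polarity_mix < 0) ||
      abs(sum(polarity_mix) - 1) > 1e-9)
    stopf("polarity_mix must be 3 nonnegative proportions summing to 1")
  set.seed(seed)
  n <- spec$n_cells
  h <- spec$height_px; w <- spec$width_px
  radii_px <- pmax(stats::rnorm(n, spec$cell_radius_um[1],
                                spec$cell_radius_um[2]), 2) / spec$um_per_px
  min_space <- 1.5 * spec$cell_radius_um[1] / spec$um_per_px
  xs <- ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    r <- radii_px[i]
    for (a in seq_len(max_attempts)) {
      # keep somata fully inside the field so edge cells stay segmentable
      cx <- stats::runif(1, 1 + r, w - r)
      cy <- stats::runif(1, 1 + r, h - r)
      if (!length(xs) || min(sqrt((xs - cx)^2 + (ys - cy)^2)) >= min_space) {
        xs <- c(xs, cx); ys <- c(ys, cy); placed <- TRUE; break
      }
    }
    if (!placed)
      stopf("cell packing infeasible: placed %d of %d cells on a %d x %d field",
            i - 1L, n, w, h)
  }
  polarity <- if (n)
    sample(c("ON", "OFF", "NONE"), n, replace = TRUE, prob = polarity_mix)
  else character(0)
  amp <- ifelse(polarity == "NONE", 0,
                stats::runif(n, amplitude_range[1], amplitude_range[2]))
  baseline <- stats::runif(n, 70, 130)
  cells <- data.frame(cell_id = seq_len(n), x = xs, y = ys,
                      radius_px = radii_px,
                      polarity = polarity, response_amplitude = amp,
                      baseline = baseline, stringsAsFactors = FALSE)
  structure(
    list(cells = cells, label_mask = rasterise_labels(cells, h, w),
         field_spec = spec, motion_trajectory = NULL, seed = as.integer(seed)),
    class = "ground_truth")
}

# label image from the cell table; overlaps resolved by nearest centroid
rasterise_labels <- function(cells, h, w) {
  lab <- matrix(0L, h, w)
  if (!nrow(cells)) return(lab)
  best <- matrix(Inf, h, w)
  for (i in seq_len(nrow(cells))) {
    r <- cells$radius_px[i]
    cx <- cells$x[i]; cy <- cells$y[i]
    xr <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
    yr <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
    d <- outer((yr - cy)^2, (xr - cx)^2, `+`)
    inside <- d <= r^2
    dn <- d / r^2
    sel <- inside & dn < best[yr, xr]
    lab[yr, xr][sel] <- cells$cell_id[i]
    best[yr, xr][sel] <- dn[sel]
  }
  lab
}

#' Filter a stimulus drive through the indicator kinetics
#'
#' Causal convolution with a difference-of-exponentials kernel
#' `exp(-t/decay_tau) - exp(-t/rise_tau)`, normalized to unit peak, so an
#' impulse drive returns a response whose maximum is exactly 1.
#'
#' @param drive numeric vector (unitless drive per frame).
#' @param kinetics an [indicator_kinetics()].
#' @param frame_rate sampling rate in Hz.
#' @param normalize `"peak"` (default): unit-peak kernel, so an impulse drive
#'   peaks at exactly 1; `"dc"`: unit-sum kernel, so a sustained drive
#'   converges to its own level and the filter acts as a pure low-pass
#'   attenuation (the form [render_video()] uses for the modulation
#'   envelope).
#' @return numeric vector, same length as `drive`.
#' @export
indicator_response <- function(drive, kinetics, frame_rate,
                               normalize = c("peak", "dc")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(kinetics, "indicator_kinetics"))
  if (frame_rate <= 0) stopf("frame_rate must be positive")
  if (!all(is.finite(drive))) stopf("drive contains non-finite values")
  k <- indicator_kernel(kinetics, frame_rate)
  if (normalize == "dc") k <- k / sum(k)
  n <- length(drive)
  # full causal convolution; the first n taps are the response at the frames
  y <- stats::convolve(drive, rev(k), type = "open")
  as.numeric(y[seq_len(n)])
}

indicator_kernel <- function(kinetics, frame_rate) {
  t <- seq(0, 6 * kinetics$decay_tau, by = 1 / frame_rate)
  k <- exp(-t / kinetics$decay_tau) - exp(-t / kinetics$rise_tau)
  k / max(k)
}

# reflecting-boundary random walk; returns n x 2 matrix of (dx, dy)
simulate_trajectory <- function(motion, n_frames) {
  if (motion$jitter_sd == 0) return(matrix(0, n_frames, 2))
  reflect <- function(v, m) {
    if (m == 0) return(0 * v)
    # fold the walk back into [-m, m]
    v <- (v + m) %% (4 * m)
    ifelse(v > 2 * m, 4 * m - v, v) - m
  }
  steps <- matrix(stats::rnorm(2 * n_frames, 0, motion$jitter_sd), ncol = 2)
  steps[1, ] <- 0                       # first frame is the reference
  traj <- apply(steps, 2, cumsum)
  traj <- cbind(reflect(traj[, 1], motion$max_excursion),
                reflect(traj[, 2], motion$max_excursion))
  if (!motion$subpixel) traj <- round(traj)
  traj
}

#' Render a synthetic fluorescence video with known ground truth
#'
#' Each responsive soma modulates its baseline fluorescence by the
#' indicator-filtered stimulus drive: ON cells in phase with light-on, OFF
#' cells in antiphase, unresponsive cells constant. Nuclei render at 40% of
#' the soma intensity. Frames are then displaced along a simulated eye-motion
#' trajectory and per-pixel Gaussian noise is added. Deterministic for a
#' fixed seed.
#'
#' @param truth a [generate_cell_field()] result.
#' @param stimulus a [stimulus_spec()].
#' @param kinetics an [indicator_kinetics()].
#' @param n_frames number of frames to render.
#' @param frame_rate acquisition rate in Hz.
#' @param noise_sd additive Gaussian noise SD in fluorescence units (>= 0).
#' @param motion a [motion_spec()].
#' @param seed integer RNG seed for noise and trajectory.
#' @param background_intensity fluorescence of the neuropil background.
#' @param nucleus_intensity nucleus intensity as a fraction of soma intensity.
#' @param trial_frames optional trial length in frames; with
#'   `first_trial_ramp = TRUE` the first trial's modulation ramps linearly
#'   from 0 to full, emulating adaptation to light onset. Default off.
#' @param first_trial_ramp logical, see `trial_frames`.
#' @return list with `session` (an [imaging_session()]) and `truth` (the input
#'   ground truth with `motion_trajectory` filled in).
#' @export
render_video <- function(truth, stimulus, kinetics, n_frames, frame_rate = 25,
                         noise_sd = 0, motion = motion_spec(), seed = 1L,
                         background_intensity = 10, nucleus_intensity = 0.4,
                         trial_frames = NULL, first_trial_ramp = FALSE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(stimulus, "stimulus_spec"))
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  period_frames <- frame_rate / stimulus$frequency
  if (n_frames < 2 * period_frames)
    warning(sprintf("only %.1f stimulus cycles in %d frames; >= 2 recommended",
                    n_frames / period_frames, n_frames), call. = FALSE)
  set.seed(seed)
  spec <- truth$field_spec
  h <- spec$height_px; w <- spec$width_px
  t <- (seq_len(n_frames) - 1 - stimulus$onset_frame) / frame_rate
  mod <- indicator_response(stimulus_drive(stimulus, t), kinetics, frame_rate,
                            normalize = "dc")
  if (first_trial_ramp && !is.null(trial_frames)) {
    ramp <- pmin(seq_len(n_frames) / trial_frames, 1)
    mod <- mod * ramp
  }
  cells <- truth$cells
  base <- matrix(background_intensity, h, w)
  pix <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    idx <- which(truth$label_mask == cells$cell_id[i])
    pix[[i]] <- idx
    r <- cells$radius_px[i]
    ys <- (idx - 1) %% h + 1
    xs <- (idx - 1) %/% h + 1
    nuc <- (xs - cells$x[i])^2 + (ys - cells$y[i])^2 <=
      (spec$nucleus_fraction * r)^2
    base[idx] <- cells$baseline[i] * ifelse(nuc, nucleus_intensity, 1)
  }
  sign_k <- c(ON = 1, OFF = -1, NONE = 0)[cells$polarity]
  traj <- simulate_trajectory(motion, n_frames)
  frames <- array(0, dim = c(h, w, n_frames))
  for (f in seq_len(n_frames)) {
    img <- base
    for (i in seq_len(nrow(cells))) {
      if (sign_k[i] != 0)
        img[pix[[i]]] <- base[pix[[i]]] *
          (1 + sign_k[i] * cells$response_amplitude[i] * mod[f])
    }
    if (any(traj[f, ] != 0))
      img <- translate_frame(img, traj[f, 1], traj[f, 2], fill = "replicate")
    frames[, , f] <- img
  }
  if (noise_sd > 0)
    frames <- frames + array(stats::rnorm(length(frames), 0, noise_sd),
                             dim = dim(frames))
  truth$motion_trajectory <- traj
  list(session = imaging_session(frames, frame_rate, spec$um_per_px),
       truth = truth)
}

#' Simulate a cohort of per-cell response time courses
#'
#' Generates soma-averaged fluorescence traces directly (no imaging or
#' segmentation), with each cell's target normalized response (F1/F0) drawn
#' from a truncated-at-zero normal distribution, for calibration and
#' parameter-recovery studies. The drive amplitude needed to hit a target
#' F1/F0 is obtained by measuring the pipeline's F1/F0 of a unit-amplitude
#' noiseless trace and scaling.
#'
#' @param n_cells number of cells.
#' @param mean_norm,sd_norm target mean and SD of the normalized response
#'   across the cohort; `mean_norm = 0, sd_norm = 0` gives pure-noise traces.
#' @param polarity_mix proportions over (ON, OFF) for responsive cells.
#' @param n_frames,frame_rate trace length and sampling rate.
#' @param stimulus a [stimulus_spec()].
#' @param kinetics an [indicator_kinetics()].
#' @param baseline mean fluorescence level.
#' @param noise_sd additive Gaussian noise SD per sample.
#' @param seed integer RNG seed.
#' @return list with `traces` (samples x cells matrix), `true_norm`,
#'   `polarity` (character vector), `baseline`.
#' @export
simulate_cell_traces <- function(n_cells, mean_norm = 0.16, sd_norm = 0.08,
                                 polarity_mix = c(0.7, 0.3),
                                 n_frames = 1250, frame_rate = 25,
                                 stimulus = stimulus_spec(),
                                 kinetics = indicator_kinetics(),
                                 baseline = 100, noise_sd = 1, seed = 1L) {
  set.seed(seed)
  t <- (seq_len(n_frames) - 1 - stimulus$onset_frame) / frame_rate
  mod <- indicator_response(stimulus_drive(stimulus, t), kinetics, frame_rate,
                            normalize = "dc")
  if (mean_norm > 0 || sd_norm > 0) {
    gain <- f1_analysis(baseline * (1 + mod), frame_rate, stimulus)
    gain <- gain$f1 / gain$f0           # F1/F0 of a unit-amplitude cell
    # modulation depth cannot be negative: fold the normal draw (the
    # folded distribution stays much closer to the nominal mean/SD than
    # truncation would)
    norm <- abs(stats::rnorm(n_cells, mean_norm, sd_norm))
    amp <- norm / gain
    pol <- sample(c("ON", "OFF"), n_cells, replace = TRUE, prob = polarity_mix)
  } else {
    norm <- amp <- numeric(n_cells)
    pol <- rep("NONE", n_cells)
  }
  sgn <- c(ON = 1, OFF = -1, NONE = 0)[pol]
  traces <- baseline * (1 + outer(mod, sgn * amp)) +
    matrix(stats::rnorm(n_frames * n_cells, 0, noise_sd), n_frames, n_cells)
  list(traces = traces, true_norm = norm, polarity = pol, baseline = baseline)
}
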