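# shared fixtures, all generated in code under fixed seeds

default_stim <- function(...) stimulus_spec(frequency = 0.2, ...)

# small noiseless single-ON-cell video plus its ground truth
small_on_video <- function(n_cells = 1, polarity_mix = c(1, 0, 0),
                           n_frames = 250, noise_sd = 0,
                           motion = motion_spec(), seed = 11,
                           amplitude_range = c(0.3, 0.3), width = 64,
                           height = 64, frame_rate = 25) {
  fs <- field_spec(width, height, n_cells = n_cells,
                   cell_radius_um = c(5, 0.5))
  gt <- generate_cell_field(fs, polarity_mix, amplitude_range, seed = seed)
  render_video(gt, default_stim(), indicator_kinetics(), n_frames,
               frame_rate = frame_rate, noise_sd = noise_sd, motion = motion,
               seed = seed + 1)
}

# textured stack of n identical frames (for registration tests)
textured_session <- function(n = 2, h = 64, w = 64, seed = 5) {
  set.seed(seed)
  base <- matrix(stats::rnorm(h * w), h, w)
  base <- as.matrix(EBImage::gblur(EBImage::Image(base), 1.5))
  imaging_session(array(rep(base, n), dim = c(h, w, n)), frame_rate = 25)
}

# exact circular (FFT) shift of a matrix, used as the subpixel-shift injector
fourier_shift <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  fy <- ifelse(seq_len(h) - 1 > h / 2, seq_len(h) - 1 - h, seq_len(h) - 1) / h
  fx <- ifelse(seq_len(w) - 1 > w / 2, seq_len(w) - 1 - w, seq_len(w) - 1) / w
  ph <- exp(-2i * pi * (outer(fy * dy, rep(1, w)) + outer(rep(1, h), fx * dx)))
  Re(fft(fft(img) * ph, inverse = TRUE)) / (h * w)
}

# brute-force single-bin DFT amplitude/phase, independent of fft()
direct_dft_bin <- function(x, k) {
  n <- length(x)
  w <- exp(-2i * pi * k * (seq_len(n) - 1) / n)
  sum(x * w)
}

make_record <- function(timecourse, cell_id = 1L, centroid = c(x = 1, y = 1)) {
  structure(
    list(cell_id = cell_id, centroid = centroid, n_pixels = 1L,
         timecourse = timecourse, f0 = NA_real_, f1 = NA_real_,
         phase = NA_real_, norm_response = NA_real_, noise_mean = NA_real_,
         noise_sd = NA_real_, significant = NA, polarity = "UNCLASSIFIED",
         valid = NA),
    class = "cell_record")
}

# a quantified record built directly from known statistics
stat_record <- function(norm, phase = 0, significant = TRUE, valid = TRUE) {
  r <- make_record(numeric(0))
  r$norm_response <- norm
  r$phase <- phase
  r$significant <- significant
  r$valid <- valid
  r$f1 <- norm
  r$f0 <- 1
  r
}

# sign-of-sine square wave about 1 with exact zeros at period boundaries
exact_square <- function(n_periods, samples_per_period, levels = c(0, 2)) {
  n <- samples_per_period
  one <- ifelse(seq_len(n) - 1 == 0, mean(levels),
                ifelse(seq_len(n) - 1 < n / 2, levels[2], levels[1]))
  rep(one, n_periods)
}
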