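test_that("quantify_cell fills statistics and applies the strict mean+3SD rule", {
  fr <- 25; st <- default_stim()
  t <- (0:1249) / fr
  # noiseless responsive cell: zero noise floor, significant
  rec <- make_record(100 * (1 + 0.05 * cos(2 * pi * 0.2 * t)))
  q <- quantify_cell(rec, fr, st)
  expect_true(q$significant)
  expect_true(q$valid)
  expect_equal(q$f0, 100, tolerance = 1e-9)
  expect_equal(q$f1, 5, tolerance = 1e-9)
  expect_equal(q$norm_response, 0.05, tolerance = 1e-9)
  expect_equal(q$noise_mean, 0, tolerance = 1e-9)
  # boundary: F1 exactly at mean + 3 SD is NOT significant (strict >)
  r2 <- stat_record(0.1)
  r2$f1 <- 5; r2$noise_mean <- 2; r2$noise_sd <- 1
  expect_false(r2$f1 > r2$noise_mean + 3 * r2$noise_sd)
  # nonpositive F0 flags the record invalid
  rec3 <- make_record(-1 + 0.5 * cos(2 * pi * 0.2 * t))
  q3 <- quantify_cell(rec3, fr, st)
  expect_false(q3$valid)
  expect_true(is.na(q3$norm_response))
})

test_that("significance is monotone in F1 at fixed noise", {
  fr <- 25; st <- default_stim()
  t <- (0:1249) / fr
  set.seed(40)
  noise <- rnorm(1250, 0, 2)
  sig_at <- function(a)
    quantify_cell(make_record(100 * (1 + a * cos(2 * pi * 0.2 * t)) + noise),
                  fr, st)$significant
  flags <- vapply(c(0.001, 0.003, 0.01, 0.03, 0.1), sig_at, TRUE)
  # once significant, larger amplitudes stay significant
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("the mean+3SD false-positive rate on white noise matches the Rayleigh closed form", {
  fr <- 25; st <- default_stim()
  n_cells <- 4000
  sim <- simulate_cell_traces(n_cells, mean_norm = 0, sd_norm = 0,
                              n_frames = 1250, noise_sd = 2, seed = 41)
  f1 <- facile:::f1_analysis_matrix(sim$traces, fr, st)
  ns <- facile:::noise_spectrum_matrix(sim$traces, fr)
  fp <- mean(f1$f1 > ns$mean_amp + 3 * ns$sd_amp)
  p_closed <- exp(-(sqrt(pi / 2) + 3 * sqrt((4 - pi) / 2))^2 / 2)
  se <- sqrt(p_closed * (1 - p_closed) / n_cells)
  expect_lt(abs(fp - p_closed), 3 * se + 0.002)
})

test_that("rayleigh_test matches its definition and clamps p", {
  r <- rayleigh_test(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(r$z, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
  r2 <- rayleigh_test(rep(1.3, 10))
  expect_equal(r2$r, 1, tolerance = 1e-12)
  expect_equal(r2$z, 10, tolerance = 1e-9)
  expect_lt(r2$p, 0.01)
  expect_error(rayleigh_test(0.5), "at least 2")
  # invariance under global rotation
  set.seed(42)
  ph <- runif(50, -pi, pi)
  expect_equal(rayleigh_test(ph)$p, rayleigh_test(ph + 1.234)$p,
               tolerance = 1e-9)
})

test_that("rayleigh_test is calibrated at alpha = 0.01 on uniform phases", {
  set.seed(43)
  rej <- mean(replicate(1000, rayleigh_test(runif(100, -pi, pi))$p < 0.01))
  expect_lt(abs(rej - 0.01), 0.01)
  # Monte-Carlo null oracle: the z-statistic's 99th percentile under
  # uniformity is close to -log(0.01) (the large-n exponential limit)
  z99 <- quantile(replicate(2000, rayleigh_test(runif(100, -pi, pi))$z), 0.99)
  expect_equal(as.numeric(z99), -log(0.01), tolerance = 0.1)
})

test_that("polarity classification follows the quadrant rule", {
  expect_equal(classify_polarity(0.3, on_center = 0.3), "ON")
  expect_equal(classify_polarity(0.3 + pi, on_center = 0.3), "OFF")
  expect_equal(unname(classify_polarity(c(-0.2, pi - 0.2), on_center = 0)),
               c("ON", "OFF"))
  # exact quadrant boundary is unclassified under the strict rule
  expect_equal(classify_polarity(pi / 2, on_center = 0), "UNCLASSIFIED")
})

test_that("synthetic mixed ON/OFF cohorts classify to their generative polarity", {
  fr <- 25; st <- default_stim()
  sim <- simulate_cell_traces(400, mean_norm = 0.16, sd_norm = 0.08,
                              polarity_mix = c(0.6, 0.4), n_frames = 1250,
                              noise_sd = 1, seed = 44)
  recs <- lapply(seq_len(400), function(i)
    quantify_cell(make_record(sim$traces[, i]), fr, st))
  sig <- vapply(recs, `[[`, TRUE, "significant")
  ph <- vapply(recs, `[[`, 0, "phase")
  oc <- estimate_on_center(ph[sig])
  called <- classify_polarity(ph[sig], oc)
  expect_gte(mean(called == sim$polarity[sig]), 0.98)
})

test_that("phase histograms conserve counts", {
  h0 <- phase_histogram(list(), n_bins = 12)
  expect_equal(sum(h0$counts), 0)
  expect_equal(length(h0$counts), 12)
  recs <- lapply(rep(0.52, 7), stat_record, norm = 0.1)
  recs <- lapply(recs, function(r) { r$phase <- 0.52; r })
  h1 <- phase_histogram(recs, n_bins = 18)
  expect_equal(max(h1$counts), 7)
  expect_equal(sum(h1$counts > 0), 1)
  set.seed(45)
  recs2 <- lapply(runif(40, -pi, pi), function(p) stat_record(0.1, phase = p))
  h2 <- phase_histogram(recs2, n_bins = 18, significant_only = FALSE)
  expect_equal(sum(h2$counts), 40)
  expect_error(phase_histogram(recs2, n_bins = 3), ">= 4")
})

test_that("population summaries match hand arithmetic and brute force", {
  r1 <- stat_record(0.1); r2 <- stat_record(0.3)
  s <- summarize_population(list(r1, r2), "demo")
  expect_equal(s$mean_norm_response, 0.2)
  expect_equal(s$sd_norm_response, sqrt((0.01 + 0.01) / 1), tolerance = 1e-9)
  expect_equal(s$n_significant, 2)
  # degenerate n = 1: SD reported as 0 with the single-cell flag
  s1 <- summarize_population(list(stat_record(0.1)), "one")
  expect_equal(s1$sd_norm_response, 0)
  expect_true(s1$single_cell)
  # brute-force two-pass mean/SD agreement on a larger set
  set.seed(46)
  vals <- runif(100, 0, 0.4)
  recs <- lapply(vals, stat_record)
  sb <- summarize_population(recs, "bulk")
  m <- sum(vals) / 100
  expect_equal(sb$mean_norm_response, m, tolerance = 1e-12)
  expect_equal(sb$sd_norm_response, sqrt(sum((vals - m)^2) / 99),
               tolerance = 1e-12)
  # invalid records are excluded with a message; all-invalid errors
  bad <- stat_record(NA_real_, valid = FALSE)
  expect_message(s2 <- summarize_population(list(r1, r2, bad)), "excluded 1")
  expect_equal(s2$n_cells_analyzed, 2)
  expect_error(summarize_population(list(bad)), "no valid")
})

test_that("cohort generation recovers its target response distribution", {
  fr <- 25; st <- default_stim()
  sim <- simulate_cell_traces(296, mean_norm = 0.16, sd_norm = 0.08,
                              n_frames = 1250, noise_sd = 0.5, seed = 47)
  recs <- lapply(seq_len(296), function(i)
    quantify_cell(make_record(sim$traces[, i]), fr, st))
  s <- summarize_population(recs, "synthetic WT / UV")
  expect_lt(abs(s$mean_norm_response - 0.16), 0.015)
  expect_lt(abs(s$sd_norm_response - 0.08), 0.015)
  expect_gte(s$n_significant, 290)
})
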