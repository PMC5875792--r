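test_that("cell-field generation is deterministic, handles the empty case, and validates input", {
  fs <- field_spec(64, 64, n_cells = 0)
  gt <- generate_cell_field(fs, seed = 1)
  expect_equal(nrow(gt$cells), 0)
  expect_true(all(gt$label_mask == 0))

  fs20 <- field_spec(96, 96, n_cells = 20, cell_radius_um = c(5, 1))
  a <- generate_cell_field(fs20, c(0.5, 0.3, 0.2), seed = 1)
  b <- generate_cell_field(fs20, c(0.5, 0.3, 0.2), seed = 1)
  expect_identical(a, b)
  expect_equal(sort(unique(as.vector(a$label_mask[a$label_mask > 0]))),
               a$cells$cell_id)
  expect_error(generate_cell_field(fs20, c(0.5, 0.4, 0.2), seed = 1),
               "summing to 1")
})

test_that("infeasible packing fails with an informative error", {
  # oracle: a greedy brute-force packing at 1.5 x 10 px spacing caps well
  # below 50 centers on a 64 x 64 field (at most ~25 sites fit)
  grid <- expand.grid(x = 11:54, y = 11:54)
  placed <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(grid))) {
    p <- as.numeric(grid[i, ])
    if (!nrow(placed) ||
        min(sqrt(colSums((t(placed) - p)^2))) >= 15)
      placed <- rbind(placed, p)
  }
  expect_lt(nrow(placed), 50)
  fs <- field_spec(64, 64, n_cells = 50, cell_radius_um = c(10, 0))
  expect_error(generate_cell_field(fs, seed = 1), "packing infeasible")
})

test_that("ground-truth labels lie on their somata", {
  fs <- field_spec(96, 96, n_cells = 15, cell_radius_um = c(5, 1))
  gt <- generate_cell_field(fs, seed = 3)
  h <- fs$height_px
  ok <- 0; total <- 0
  for (i in seq_len(nrow(gt$cells))) {
    idx <- which(gt$label_mask == gt$cells$cell_id[i])
    ys <- (idx - 1) %% h + 1
    xs <- (idx - 1) %/% h + 1
    d <- sqrt((xs - gt$cells$x[i])^2 + (ys - gt$cells$y[i])^2)
    ok <- ok + sum(d <= gt$cells$radius_px[i] + 1)
    total <- total + length(idx)
  }
  expect_gte(ok / total, 0.99)
})

test_that("indicator response is causal, normalized, and matches direct convolution", {
  k <- indicator_kinetics(0.2, 1.5)
  expect_error(indicator_kinetics(1.5, 0.2), "exceed")
  expect_equal(indicator_response(numeric(100), k, 25), numeric(100))
  # unit impulse peaks at exactly 1
  y <- indicator_response(c(1, numeric(250)), k, 25)
  expect_equal(max(y), 1)
  expect_equal(y[1], 0)  # difference of exponentials starts at zero
  # constant drive converges to c * kernel sum / kernel peak
  kern <- facile:::indicator_kernel(k, 25)
  yc <- indicator_response(rep(2, 500), k, 25)
  expect_equal(yc[500], 2 * sum(kern), tolerance = 1e-6)
  # oracle: direct discrete convolution loop
  set.seed(7)
  x <- rnorm(60)
  y2 <- indicator_response(x, k, 25)
  direct <- vapply(seq_along(x), function(n)
    sum(kern[seq_len(n)] * x[n:1][seq_len(min(n, length(kern)))]), 0)
  expect_equal(y2, direct, tolerance = 1e-9)
})

test_that("rendered videos are deterministic and respect the motion invariant", {
  v1 <- small_on_video(n_cells = 4, noise_sd = 1,
                       motion = motion_spec(jitter_sd = 1))
  v2 <- small_on_video(n_cells = 4, noise_sd = 1,
                       motion = motion_spec(jitter_sd = 1))
  expect_identical(v1$session$frames, v2$session$frames)
  expect_identical(v1$truth$motion_trajectory, v2$truth$motion_trajectory)
  v0 <- small_on_video(n_cells = 2)
  expect_true(all(v0$truth$motion_trajectory == 0))
})

test_that("noiseless rendering matches the pipeline's F1/F0 closed form and polarity phases", {
  st <- default_stim(); kin <- indicator_kinetics(); fr <- 25
  v <- small_on_video(n_cells = 3, amplitude_range = c(0.25, 0.25))
  t <- (0:249) / fr
  mod <- indicator_response(stimulus_drive(st, t), kin, fr, normalize = "dc")
  oracle <- f1_analysis(100 * (1 + 0.25 * mod), fr, st)
  for (id in v$truth$cells$cell_id) {
    idx <- which(v$truth$label_mask == id)
    tc <- apply(v$session$frames, 3, function(f) mean(f[idx]))
    r <- f1_analysis(tc, fr, st)
    expect_equal(r$f1 / r$f0, oracle$f1 / oracle$f0, tolerance = 0.01)
  }
  # ON and OFF cells with equal amplitude are antiphase
  von <- small_on_video(n_cells = 1, polarity_mix = c(1, 0, 0))
  voff <- small_on_video(n_cells = 1, polarity_mix = c(0, 1, 0))
  ph <- function(v) {
    idx <- which(v$truth$label_mask > 0)
    f1_analysis(apply(v$session$frames, 3, function(f) mean(f[idx])),
                fr, st)$phase
  }
  expect_equal(abs(facile:::wrap_pi(ph(von) - ph(voff))), pi, tolerance = 0.05)
})

test_that("unresponsive cells carry no stimulus-locked power", {
  v <- small_on_video(n_cells = 5, polarity_mix = c(0, 0, 1))
  maps <- pixelwise_maps(v$session, default_stim())
  soma <- v$truth$label_mask > 0
  expect_true(all(maps$norm_map[soma] < 1e-10))
})

test_that("soma-averaged F1 increases strictly with response amplitude", {
  st <- default_stim(); fr <- 25
  f1_at <- function(a) {
    v <- small_on_video(n_cells = 1, amplitude_range = c(a, a))
    idx <- which(v$truth$label_mask > 0)
    f1_analysis(apply(v$session$frames, 3, function(f) mean(f[idx])),
                fr, st)$f1
  }
  f1s <- vapply(c(0.05, 0.1, 0.2, 0.4), f1_at, 0)
  expect_true(all(diff(f1s) > 0))
})

test_that("first-trial adaptation ramp attenuates only the first trial", {
  st <- default_stim(); kin <- indicator_kinetics()
  fs <- field_spec(48, 48, n_cells = 1, cell_radius_um = c(5, 0))
  gt <- generate_cell_field(fs, c(1, 0, 0), c(0.4, 0.4), seed = 2)
  plain <- render_video(gt, st, kin, 375, seed = 3)
  ramped <- render_video(gt, st, kin, 375, seed = 3,
                         trial_frames = 125, first_trial_ramp = TRUE)
  idx <- which(gt$label_mask > 0)
  tc <- function(v, fr) mean(v$session$frames[, , fr][idx])
  # early frames are attenuated toward baseline, late frames agree
  dev <- function(v, fr) abs(tc(v, fr) - tc(v, 1))
  expect_lt(sum(vapply(2:60, function(f) dev(ramped, f), 0)),
            sum(vapply(2:60, function(f) dev(plain, f), 0)))
  expect_equal(plain$session$frames[, , 300], ramped$session$frames[, , 300],
               tolerance = 1e-12)
})
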