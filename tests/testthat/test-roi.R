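test_that("validate_mask relabels, filters small ROIs, and checks shape", {
  lab <- matrix(0L, 10, 10)
  lab[1:3, 1:3] <- 3L      # 9 px
  lab[8:9, 8:9] <- 7L      # 4 px
  m <- validate_mask(roi_mask(lab))
  expect_equal(m$roi_ids, c(1L, 2L))
  expect_equal(attr(m, "relabel_map"), c("3" = 1L, "7" = 2L))
  # 2 px ROI dropped with a message
  lab2 <- lab; lab2[5, 5:6] <- 9L
  expect_message(m2 <- validate_mask(roi_mask(lab2)), "dropped 1")
  expect_equal(length(m2$roi_ids), 2)
  expect_equal(attr(m2, "n_dropped"), 1L)
  # empty mask passes through
  e <- validate_mask(roi_mask(matrix(0L, 5, 5)))
  expect_equal(length(e$roi_ids), 0)
  sess <- imaging_session(array(0, dim = c(4, 4, 2)), 25)
  expect_error(validate_mask(roi_mask(lab), sess), "4 x 4")
})

test_that("validate_mask can exclude ROIs touching the registration margin", {
  lab <- matrix(0L, 20, 20)
  lab[2:5, 2:5] <- 1L       # touches the 3-px border
  lab[9:12, 9:12] <- 2L     # interior
  lab[16:19, 9:12] <- 3L    # touches the bottom border
  expect_message(m <- validate_mask(roi_mask(lab), exclude_margin = 3),
                 "frame edge")
  expect_equal(length(m$roi_ids), 1)
  expect_equal(attr(m, "relabel_map"), c("2" = 1L))
  expect_equal(attr(m, "n_dropped"), 2L)
  # margin 0 keeps everything (default behavior unchanged)
  m0 <- validate_mask(roi_mask(lab))
  expect_equal(length(m0$roi_ids), 3)
})

test_that("ROI time courses equal the brute-force pixel average", {
  v <- small_on_video(n_cells = 3, noise_sd = 1)
  mask <- validate_mask(roi_mask(v$truth$label_mask))
  recs <- extract_timecourses(v$session, mask)
  expect_equal(length(recs), 3)
  for (r in recs) {
    idx <- which(mask$label_image == r$cell_id)
    brute <- vapply(seq_len(dim(v$session$frames)[3]), function(f) {
      acc <- 0
      for (i in idx) {
        y <- (i - 1) %% 64 + 1; x <- (i - 1) %/% 64 + 1
        acc <- acc + v$session$frames[y, x, f]
      }
      acc / length(idx)
    }, 0)
    expect_equal(r$timecourse, brute, tolerance = 1e-12)
  }
  # single-pixel ROI reproduces that pixel's trace
  lab1 <- matrix(0L, 64, 64); lab1[10, 20] <- 1L
  r1 <- extract_timecourses(v$session, roi_mask(lab1))[[1]]
  expect_equal(r1$timecourse, v$session$frames[10, 20, ])
  expect_equal(unname(r1$centroid), c(20, 10))
  # traces t and -t average to zero
  fr <- array(0, dim = c(4, 4, 50))
  fr[1, 1, ] <- sin(1:50); fr[1, 2, ] <- -sin(1:50)
  lab2 <- matrix(0L, 4, 4); lab2[1, 1:2] <- 1L
  r2 <- extract_timecourses(imaging_session(fr, 25), roi_mask(lab2))[[1]]
  expect_equal(r2$timecourse, rep(0, 50), tolerance = 1e-14)
})

test_that("ROI-averaged F1 equals the complex average of pixel-wise F1 (DFT linearity)", {
  v <- small_on_video(n_cells = 2)
  st <- default_stim()
  mask <- validate_mask(roi_mask(v$truth$label_mask))
  recs <- extract_timecourses(v$session, mask)
  for (r in recs) {
    idx <- which(mask$label_image == r$cell_id)
    zs <- vapply(idx, function(i) {
      y <- (i - 1) %% 64 + 1; x <- (i - 1) %/% 64 + 1
      a <- f1_analysis(v$session$frames[y, x, ], 25, st)
      complex(modulus = a$f1, argument = a$phase)
    }, complex(1))
    roi_f1 <- f1_analysis(r$timecourse, 25, st)
    z <- mean(zs)
    expect_equal(roi_f1$f1, Mod(z), tolerance = 1e-9)
    expect_equal(roi_f1$phase, Arg(z), tolerance = 1e-9)
  }
})

test_that("auto_segment recovers well-separated cells with few spurious ROIs", {
  st <- default_stim()
  fs <- field_spec(160, 160, n_cells = 20, cell_radius_um = c(5, 0.5))
  gt <- generate_cell_field(fs, c(0.5, 0.3, 0.2), c(0.3, 0.6), seed = 9)
  v <- render_video(gt, st, indicator_kinetics(), 250, noise_sd = 2, seed = 10)
  seg <- auto_segment(pixelwise_maps(v$session, st))
  recs <- extract_timecourses(v$session, seg)
  cents <- do.call(rbind, lapply(recs, function(r) r$centroid))
  matched <- sum(vapply(seq_len(nrow(gt$cells)), function(i) {
    d <- sqrt((cents[, 1] - gt$cells$x[i])^2 + (cents[, 2] - gt$cells$y[i])^2)
    any(d <= gt$cells$radius_px[i])
  }, TRUE))
  spurious <- sum(vapply(seq_len(nrow(cents)), function(j) {
    d <- sqrt((gt$cells$x - cents[j, 1])^2 + (gt$cells$y - cents[j, 2])^2)
    all(d > gt$cells$radius_px + 2)
  }, TRUE))
  expect_gte(matched, 18)
  expect_lte(spurious, 2)
})

test_that("auto_segment returns an empty mask on blank maps", {
  blank <- imaging_session(array(1, dim = c(32, 32, 250)), 25)
  seg <- auto_segment(pixelwise_maps(blank, default_stim()))
  expect_equal(length(seg$roi_ids), 0)
})

test_that("fused antiphase neighbours are split by phase coherence", {
  # one smooth cue blob covering two cells responding in antiphase
  h <- w <- 48
  xs <- matrix(rep(1:w, each = h), h, w)
  ys <- matrix(rep(1:h, w), h, w)
  blob <- exp(-((xs - 24)^2 / 200 + (ys - 24)^2 / 60))
  phase <- ifelse(xs <= 24, 0, pi) + 0.05 * sin(ys)  # two antipodal lobes
  amp <- blob
  maps <- structure(
    list(sum_image = blob * 100, f0_map = blob * 100 + 1, f1_amp_map = amp,
         f1_phase_map = phase, norm_map = amp / (blob * 100 + 1),
         valid = matrix(TRUE, h, w), frame_rate = 25, um_per_px = 1,
         stimulus = default_stim(), n_used = 250),
    class = "activity_maps")
  seg <- auto_segment(maps, min_area = 20, max_area = 2000)
  expect_gte(length(seg$roi_ids), 2)
  # the two halves carry distinct phases
  recs_ph <- vapply(seg$roi_ids, function(id)
    Arg(mean(exp(1i * phase[seg$label_image == id]))), 0)
  expect_gt(max(abs(facile:::wrap_pi(outer(recs_ph, recs_ph, "-")))), 2.5)
})

test_that("cell matching is exact for identity and uniform-shift cases", {
  v <- small_on_video(n_cells = 6, width = 96, height = 96, seed = 21)
  recs <- extract_timecourses(v$session, roi_mask(v$truth$label_mask))
  m <- match_cells(recs, recs)
  expect_equal(m$id_a, m$id_b)
  expect_true(all(m$distance_um == 0))
  shifted <- lapply(recs, function(r) {
    r$centroid <- r$centroid + c(3, -2); r
  })
  m2 <- match_cells(recs, shifted, session_transform = c(3, -2))
  expect_equal(m2$id_a, m2$id_b)
  expect_true(all(m2$distance_um < 1e-9))
  # symmetry
  m3 <- match_cells(shifted, recs, session_transform = c(-3, 2))
  expect_equal(m3$id_a, m2$id_b[order(m2$id_b)])
})

test_that("greedy matching recovers a known permutation under jitter", {
  set.seed(30)
  n <- 30
  # well-separated random centroids
  cents <- cbind(runif(n, 5, 195), runif(n, 5, 195))
  while (min(dist(cents)) < 12) cents <- cbind(runif(n, 5, 195),
                                               runif(n, 5, 195))
  perm <- sample(n)
  jit <- matrix(runif(2 * n, -1, 1), n, 2)
  mk <- function(cc, ids) lapply(seq_len(nrow(cc)), function(i)
    make_record(numeric(0), cell_id = ids[i],
                centroid = c(x = cc[i, 1], y = cc[i, 2])))
  ra <- mk(cents, seq_len(n))
  rb <- mk(cents[perm, ] + jit, seq_len(n))
  m <- match_cells(ra, rb, max_dist_um = 5)
  # oracle: the generative permutation (optimal at this separation/jitter)
  hits <- sum(vapply(seq_len(nrow(m)), function(i)
    perm[m$id_b[i]] == m$id_a[i], TRUE))
  expect_gte(hits / n, 0.95)
  # one-to-one and distance-bounded
  expect_equal(anyDuplicated(m$id_a), 0)
  expect_equal(anyDuplicated(m$id_b), 0)
  expect_true(all(m$distance_um <= 5))
})
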