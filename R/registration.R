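#' Translate a single frame by a (possibly fractional) pixel shift
#'
#' Moves frame content by `dx` columns and `dy` rows using bilinear
#' interpolation. Out-of-field samples are taken from the nearest edge pixel
#' (`fill = "replicate"`) or set to zero (`fill = "zero"`).
#'
#' @param frame numeric matrix.
#' @param dx,dy shift in pixels (positive = content moves right / down).
#' @param fill `"replicate"` or `"zero"`.
#' @return numeric matrix of the same shape.
#' @export
translate_frame <- function(frame, dx, dy, fill = c("replicate", "zero")) {
  fill <- match.arg(fill)
  h <- nrow(frame); w <- ncol(frame)
  sr <- seq_len(h) - dy
  sc <- seq_len(w) - dx
  r0 <- floor(sr); wr <- sr[1] - r0[1]  # uniform shift: one fractional weight
  c0 <- floor(sc); wc <- sc[1] - c0[1]
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  ri0 <- clamp(r0, h); ri1 <- clamp(r0 + 1, h)
  ci0 <- clamp(c0, w); ci1 <- clamp(c0 + 1, w)
  out <- (1 - wr) * (1 - wc) * frame[ri0, ci0, drop = FALSE] +
         wr       * (1 - wc) * frame[ri1, ci0, drop = FALSE] +
         (1 - wr) * wc       * frame[ri0, ci1, drop = FALSE] +
         wr       * wc       * frame[ri1, ci1, drop = FALSE]
  if (fill == "zero") {
    out[sr < 1 | sr > h, ] <- 0
    out[, sc < 1 | sc > w] <- 0
  }
  out
}

# signed DFT frequencies as fractions of the axis length
fft_freq <- function(n) {
  f <- seq_len(n) - 1
  ifelse(f > n / 2, f - n, f) / n
}

# refine an integer cross-correlation peak on a 1/upsample grid around
# (dy0, dx0) by direct evaluation of the cross-correlation from the
# cross-power spectrum (matrix-multiply DFT)
refine_peak <- function(cp, dy0, dx0, upsample) {
  h <- nrow(cp); w <- ncol(cp)
  gy <- dy0 + seq(-1, 1, by = 1 / upsample)
  gx <- dx0 + seq(-1, 1, by = 1 / upsample)
  ey <- exp(2i * pi * outer(fft_freq(h), gy))
  ex <- exp(2i * pi * outer(fft_freq(w), gx))
  cc <- Re(crossprod(ey, cp %*% ex))
  idx <- arrayInd(which.max(cc), dim(cc))
  c(gy[idx[1]], gx[idx[2]])
}

#' Estimate per-frame rigid translations against a reference image
#'
#' Frame-wise translation-only motion estimation by FFT cross-correlation,
#' with optional subpixel refinement on a `1/upsample`-pixel grid around the
#' integer peak. A generic frame-level stand-in for strip-based eye-motion
#' pipelines; see the vignette for the scope of that substitution.
#'
#' @param session an [imaging_session()]. When a reflectance channel is
#'   available, estimate on it and apply the trace to the fluorescence
#'   session with [correct_motion()].
#' @param reference `"mean10"` (mean of the first 10 frames; default),
#'   `"first"`, `"mean"`, or `"index"` with `ref_index`.
#' @param ref_index frame index used when `reference = "index"`.
#' @param upsample integer >= 1; subpixel precision is `1/upsample` px.
#' @return An object of class `motion_trace`: data frame with columns
#'   `frame`, `dx`, `dy`, plus attributes `reference` and `degenerate`
#'   (TRUE when the frames carry no texture and zero shifts were returned).
#' @export
estimate_shifts <- function(session,
                            reference = c("mean10", "first", "mean", "index"),
                            ref_index = 1L, upsample = 1L) {
  stopifnot(inherits(session, "imaging_session"))
  reference <- match.arg(reference)
  frames <- session$frames
  n <- dim(frames)[3]
  if (n < 2) stopf("need at least 2 frames to estimate motion")
  if (upsample < 1) stopf("upsample must be >= 1")
  degenerate <- stats::sd(frames) == 0
  out <- data.frame(frame = seq_len(n), dx = 0, dy = 0)
  if (degenerate) {
    warning("all frames are constant; returning zero shifts", call. = FALSE)
    attr(out, "degenerate") <- TRUE
    attr(out, "reference") <- reference
    class(out) <- c("motion_trace", class(out))
    return(out)
  }
  ref <- switch(reference,
    mean10 = rowMeans(frames[, , seq_len(min(10, n)), drop = FALSE], dims = 2),
    first  = frames[, , 1],
    mean   = rowMeans(frames, dims = 2),
    index  = frames[, , ref_index])
  h <- dim(frames)[1]; w <- dim(frames)[2]
  fr <- stats::fft(ref)
  for (f in seq_len(n)) {
    cp <- stats::fft(frames[, , f]) * Conj(fr)
    cc <- Re(stats::fft(cp, inverse = TRUE))
    idx <- arrayInd(which.max(cc), dim(cc)) - 1L
    dy <- if (idx[1] > h / 2) idx[1] - h else idx[1]
    dx <- if (idx[2] > w / 2) idx[2] - w else idx[2]
    if (upsample > 1) {
      p <- refine_peak(cp, dy, dx, upsample)
      dy <- p[1]; dx <- p[2]
    }
    out$dx[f] <- dx; out$dy[f] <- dy
  }
  attr(out, "degenerate") <- FALSE
  attr(out, "reference") <- reference
  class(out) <- c("motion_trace", class(out))
  out
}

#' Apply the inverse of an estimated motion trace to a session
#'
#' Translates every frame by `-(dx, dy)` so that frame content returns to the
#' reference position. Metadata is preserved and the result is flagged
#' registered.
#'
#' @param session an [imaging_session()].
#' @param trace a `motion_trace` (or data frame with `dx`, `dy`).
#' @param fill edge handling passed to [translate_frame()].
#' @return A registered [imaging_session()].
#' @export
correct_motion <- function(session, trace, fill = c("replicate", "zero")) {
  fill <- match.arg(fill)
  stopifnot(inherits(session, "imaging_session"))
  n <- n_frames(session)
  if (nrow(trace) != n)
    stopf("motion trace has %d rows but session has %d frames", nrow(trace), n)
  frames <- session$frames
  for (f in seq_len(n)) {
    if (trace$dx[f] != 0 || trace$dy[f] != 0)
      frames[, , f] <- translate_frame(frames[, , f],
                                       -trace$dx[f], -trace$dy[f], fill)
  }
  out <- session
  out$frames <- frames
  out$registered <- TRUE
  out
}

#' Apply a motion trace to a session (forward direction)
#'
#' Shifts each frame by `+(dx, dy)`; the inverse of [correct_motion()].
#' Mainly used to inject known motion when testing registration.
#'
#' @inheritParams correct_motion
#' @return An [imaging_session()] with motion applied.
#' @export
apply_motion <- function(session, trace, fill = c("replicate", "zero")) {
  fill <- match.arg(fill)
  frames <- session$frames
  for (f in seq_len(nrow(trace))) {
    if (trace$dx[f] != 0 || trace$dy[f] != 0)
      frames[, , f] <- translate_frame(frames[, , f],
                                       trace$dx[f], trace$dy[f], fill)
  }
  out <- session
  out$frames <- frames
  out
}
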