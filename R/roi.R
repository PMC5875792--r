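#' ROI label-mask container
#'
#' @param label_image integer matrix; 0 = background, positive integers label
#'   cells.
#' @return An object of class `roi_mask` with elements `label_image` and
#'   `roi_ids` (sorted unique positive labels).
#' @export
roi_mask <- function(label_image) {
  if (!is.matrix(label_image)) stopf("label_image must be a matrix")
  if (any(label_image < 0) || any(label_image != round(label_image)))
    stopf("labels must be nonnegative integers")
  storage.mode(label_image) <- "integer"
  ids <- sort(unique(label_image[label_image > 0]))
  structure(list(label_image = label_image, roi_ids = ids), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d ROIs\n",
              nrow(x$label_image), ncol(x$label_image), length(x$roi_ids)))
  invisible(x)
}

#' Validate and normalise an ROI mask against a session
#'
#' Checks the mask shape, drops ROIs below the minimum pixel area (and,
#' optionally, ROIs touching the frame-edge margin), and relabels the
#' survivors to consecutive ids preserving the original order. The id
#' mapping is attached as attribute `relabel_map` and the number of dropped
#' ROIs as `n_dropped`.
#'
#' Pixels within the maximum registration shift of the frame edge are
#' filled by edge replication during motion correction, so their time
#' courses are corrupted; passing that shift as `exclude_margin` drops any
#' ROI overlapping the unreliable border.
#'
#' @param mask an [roi_mask()] (or a bare label matrix).
#' @param session optional [imaging_session()] for the shape check.
#' @param min_area minimum ROI size in pixels (default 4).
#' @param exclude_margin drop ROIs with any pixel within this many pixels
#'   of the frame edge (default 0 = keep all); typically the maximum
#'   absolute shift from [estimate_shifts()].
#' @return A validated `roi_mask`.
#' @export
validate_mask <- function(mask, session = NULL, min_area = 4,
                          exclude_margin = 0) {
  if (!inherits(mask, "roi_mask")) mask <- roi_mask(mask)
  if (!is.null(session) &&
      !identical(dim(mask$label_image), dim(session$frames)[1:2]))
    stopf("mask is %d x %d but frames are %d x %d",
          nrow(mask$label_image), ncol(mask$label_image),
          dim(session$frames)[1], dim(session$frames)[2])
  lab <- mask$label_image
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  dropped <- length(sizes) - length(keep)
  if (dropped > 0)
    message(sprintf("validate_mask: dropped %d ROI(s) smaller than %d px",
                    dropped, min_area))
  if (exclude_margin > 0 && length(keep)) {
    m <- ceiling(exclude_margin)
    border <- matrix(TRUE, nrow(lab), ncol(lab))
    if (nrow(lab) > 2 * m && ncol(lab) > 2 * m)
      border[(m + 1):(nrow(lab) - m), (m + 1):(ncol(lab) - m)] <- FALSE
    edge_ids <- unique(lab[border & lab > 0])
    n_edge <- sum(keep %in% edge_ids)
    if (n_edge > 0) {
      message(sprintf(
        "validate_mask: dropped %d ROI(s) within %d px of the frame edge",
        n_edge, m))
      keep <- keep[!keep %in% edge_ids]
      dropped <- dropped + n_edge
    }
  }
  new_lab <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) new_lab[lab == keep[i]] <- i
  out <- roi_mask(new_lab)
  attr(out, "relabel_map") <- stats::setNames(seq_along(keep), keep)
  attr(out, "n_dropped") <- dropped
  out
}

#' Automated cell segmentation from activity maps
#'
#' Builds a composite cue image (normalized SUM image plus a weighted
#' normalized F1-amplitude map), detects somata as smoothed local maxima, and
#' grows labels over the cue foreground. Candidate ROIs whose pixel phases
#' are incoherent (circular SD above `phase_split_sd`) are split by phase,
#' mirroring the use of the phase map to refine boundaries between adjacent
#' cells with opposite response polarity. A convenience for unattended
#' pipelines; manually drawn masks remain first-class input.
#'
#' @param maps an `activity_maps` object from [pixelwise_maps()].
#' @param smooth_sigma Gaussian smoothing SD in pixels for the cue image.
#' @param amp_weight weight of the F1-amplitude map in the cue image.
#' @param min_area,max_area ROI area bounds in pixels.
#' @param threshold `"otsu"` (default) for Otsu's method on the smoothed cue,
#'   or a quantile in (0, 1) above which pixels count as candidate soma area.
#' @param seed_brush diameter (odd, pixels) of the regional-maximum window
#'   used to detect one seed per soma; roughly the soma diameter.
#' @param phase_split_sd circular-SD threshold (radians) above which a
#'   candidate ROI is split by phase.
#' @return A validated `roi_mask` (possibly empty).
#' @export
auto_segment <- function(maps, smooth_sigma = 2, amp_weight = 1,
                         min_area = 20, max_area = 1200,
                         threshold = "otsu", seed_brush = 9,
                         phase_split_sd = 1.0) {
  stopifnot(inherits(maps, "activity_maps"))
  cue <- norm01(maps$sum_image) + amp_weight * norm01(maps$f1_amp_map)
  if (all(cue == 0)) return(roi_mask(matrix(0L, nrow(cue), ncol(cue))))
  sm <- as.matrix(EBImage::gblur(EBImage::Image(cue), sigma = smooth_sigma))
  sm <- norm01(sm)
  thr <- if (identical(threshold, "otsu")) EBImage::otsu(EBImage::Image(sm))
         else stats::quantile(sm, threshold)
  fg <- sm > thr
  if (!any(fg)) return(roi_mask(matrix(0L, nrow(cue), ncol(cue))))
  # seeds: regional maxima of the smoothed cue inside the foreground
  mx <- as.matrix(EBImage::dilate(EBImage::Image(sm),
                                  EBImage::makeBrush(seed_brush, "disc")))
  seeds <- fg & (sm >= mx - 1e-12)
  seed_lab <- EBImage::bwlabel(EBImage::Image(seeds))
  grown <- EBImage::propagate(EBImage::Image(sm), seed_lab,
                              mask = EBImage::Image(fg))
  lab <- matrix(as.integer(as.matrix(grown)), nrow(cue), ncol(cue))
  lab <- split_incoherent_rois(lab, maps$f1_phase_map, maps$f1_amp_map,
                               phase_split_sd, min_area)
  # enforce area bounds
  sizes <- table(lab[lab > 0])
  bad <- as.integer(names(sizes)[sizes < min_area | sizes > max_area])
  lab[lab %in% bad] <- 0L
  validate_mask(roi_mask(lab), min_area = min_area)
}

# split ROIs whose phases are bimodal (e.g. fused antiphase neighbours):
# assign pixels to the nearer of the two antipodal phase centers, then keep
# connected components meeting the minimum area
split_incoherent_rois <- function(lab, phase_map, amp_map, sd_thresh,
                                  min_area) {
  next_id <- max(lab) + 1L
  for (id in sort(unique(lab[lab > 0]))) {
    idx <- which(lab == id)
    if (length(idx) < 2 * min_area) next
    ph <- phase_map[idx]
    r <- Mod(mean(exp(1i * ph)))
    circ_sd <- sqrt(-2 * log(max(r, 1e-12)))
    if (circ_sd <= sd_thresh) next
    # antipodal axis from the doubled phases
    axis <- Arg(mean(exp(2i * ph))) / 2
    g1 <- circ_dist(ph, axis) <= pi / 2
    comp <- matrix(0L, nrow(lab), ncol(lab))
    comp[idx[g1]] <- 1L
    comp[idx[!g1]] <- 2L
    for (g in 1:2) {
      m <- EBImage::bwlabel(EBImage::Image(comp == g))
      m <- matrix(as.integer(as.matrix(m)), nrow(lab), ncol(lab))
      for (cc in sort(unique(m[m > 0]))) {
        pix <- which(m == cc)
        lab[pix] <- if (length(pix) >= min_area) {
          next_id <- next_id + 1L
          next_id - 1L
        } else 0L
      }
    }
  }
  lab
}

#' Construct a cell record from a time course
#'
#' Cell records are normally produced by [extract_timecourses()]; this
#' constructor supports trace-level workflows (e.g. analysing the columns of
#' [simulate_cell_traces()] directly). Response statistics start unset and
#' are filled by [quantify_cell()].
#'
#' @param timecourse numeric vector, one sample per frame.
#' @param cell_id integer id.
#' @param centroid `(x, y)` centroid in pixels.
#' @param n_pixels number of pixels averaged into the time course.
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(timecourse, cell_id = 1L,
                        centroid = c(x = NA_real_, y = NA_real_),
                        n_pixels = 1L) {
  structure(
    list(cell_id = as.integer(cell_id),
         centroid = stats::setNames(as.numeric(centroid), c("x", "y")),
         n_pixels = as.integer(n_pixels), timecourse = timecourse,
         f0 = NA_real_, f1 = NA_real_, phase = NA_real_,
         norm_response = NA_real_, noise_mean = NA_real_,
         noise_sd = NA_real_, significant = NA,
         polarity = "UNCLASSIFIED", valid = NA),
    class = "cell_record")
}

#' Extract per-ROI average time courses
#'
#' Each cell's time course is the unweighted mean over its ROI pixels, frame
#' by frame, taken from the (registered) video.
#'
#' @param session an [imaging_session()].
#' @param mask a validated [roi_mask()].
#' @return A list of `cell_record` objects with `cell_id`, `centroid`
#'   (x, y in pixels), `n_pixels` and `timecourse` filled; response statistics
#'   are filled later by [quantify_cell()].
#' @export
extract_timecourses <- function(session, mask) {
  stopifnot(inherits(session, "imaging_session"), inherits(mask, "roi_mask"))
  if (!identical(dim(mask$label_image), dim(session$frames)[1:2]))
    stopf("mask shape does not match frames")
  d <- dim(session$frames)
  lab <- as.vector(mask$label_image)
  traces <- matrix(aperm(session$frames, c(3, 1, 2)), nrow = d[3])
  lapply(mask$roi_ids, function(id) {
    idx <- which(lab == id)
    ys <- (idx - 1) %% d[1] + 1
    xs <- (idx - 1) %/% d[1] + 1
    tc <- if (length(idx) == 1) traces[, idx] else rowMeans(traces[, idx])
    cell_record(tc, cell_id = id, centroid = c(x = mean(xs), y = mean(ys)),
                n_pixels = length(idx))
  })
}

#' Match cells across two imaging sessions
#'
#' Greedy mutual-nearest-neighbour matching of cell centroids after applying
#' a between-session rigid translation: pairs are accepted in order of
#' increasing distance, each id used at most once, and no accepted pair
#' exceeds `max_dist_um`. Symmetric in its two arguments.
#'
#' @param records_a,records_b lists of `cell_record`s (centroids required).
#' @param session_transform `(dx, dy)` in pixels mapping session A coordinates
#'   into session B's frame (e.g. from registering the two SUM images with
#'   [estimate_shifts()]).
#' @param max_dist_um maximum matching distance in micrometers (default 5).
#' @param um_per_px pixel scale shared by the sessions.
#' @return data frame with columns `id_a`, `id_b`, `distance_um`.
#' @export
match_cells <- function(records_a, records_b, session_transform = c(0, 0),
                        max_dist_um = 5, um_per_px = 1) {
  ca <- do.call(rbind, lapply(records_a, `[[`, "centroid"))
  cb <- do.call(rbind, lapply(records_b, `[[`, "centroid"))
  empty <- data.frame(id_a = integer(0), id_b = integer(0),
                      distance_um = numeric(0))
  if (is.null(ca) || is.null(cb)) return(empty)
  ca <- sweep(ca, 2, session_transform, `+`)
  dmat <- um_per_px * sqrt(outer(ca[, 1], cb[, 1], `-`)^2 +
                           outer(ca[, 2], cb[, 2], `-`)^2)
  ids_a <- vapply(records_a, `[[`, 0, "cell_id")
  ids_b <- vapply(records_b, `[[`, 0, "cell_id")
  out <- empty
  repeat {
    m <- which.min(dmat)
    if (!length(m) || dmat[m] > max_dist_um) break
    ij <- arrayInd(m, dim(dmat))
    out <- rbind(out, data.frame(id_a = ids_a[ij[1]], id_b = ids_b[ij[2]],
                                 distance_um = dmat[m]))
    dmat[ij[1], ] <- Inf
    dmat[, ij[2]] <- Inf
    if (all(is.infinite(dmat))) break
  }
  out[order(out$id_a), , drop = FALSE]
}
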