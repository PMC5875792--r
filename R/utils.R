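# internal helpers shared across modules

#' Wrap angles to the half-open interval (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector with every element in (-pi, pi].
#' @keywords internal
wrap_pi <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  # floor() maps the upper boundary to -pi; the convention here is (-pi, pi]
  w[w <= -pi] <- pi
  w
}

#' Circular distance between two angles
#'
#' @param a,b angles in radians.
#' @return absolute angular separation in `[0, pi]`.
#' @keywords internal
circ_dist <- function(a, b) abs(wrap_pi(a - b))

# rescale to [0, 1]; constant input maps to all zeros
norm01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] <= r[1]) return(array(0, dim = dim(x) %||% length(x)))
  (x - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
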