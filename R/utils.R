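#' @importFrom stats rnorm runif rnbinom rpois sd var cor.test t.test
#'   p.adjust prcomp qt quantile dnbinom qnbinom median
#' @importFrom utils head write.csv read.csv
NULL

# Resolve a threshold specification against a 2D intensity matrix.
# `spec` may be a number (used as-is) or "otsu" (Otsu's method on the
# intensity histogram, via EBImage). A flat image gets a threshold above
# its maximum so the foreground mask is empty rather than arbitrary.
resolve_threshold <- function(x, spec = "otsu") {
  if (is.numeric(spec)) return(spec)
  if (!identical(spec, "otsu")) stop("unknown threshold method: ", spec)
  rng <- range(x)
  # flat image: all-positive when saturated, empty when all-zero
  if (diff(rng) <= .Machine$double.eps)
    return(if (rng[2] > 0) rng[2] else rng[2] + 1)
  mx <- rng[2]
  thr <- EBImage::otsu(EBImage::as.Image(x / mx), range = c(0, 1))
  thr * mx
}

# 4-connected component labelling. EBImage::bwlabel labels 4-connected
# foreground sets, which is the connectivity used throughout (diagonal
# bridges between adjacent plaques must not merge them).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(EBImage::as.Image(mask * 1))
  matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(mask))
}

# Physical coordinates of pixel centres: x along columns, y along rows,
# both in micrometres, origin at the image corner.
pixel_centers <- function(nrow, ncol, pixel_size_um) {
  list(
    x = (seq_len(ncol) - 0.5) * pixel_size_um,
    y = (seq_len(nrow) - 0.5) * pixel_size_um
  )
}

# Angle in degrees in [0, 360), counterclockwise from the +x axis of the
# image physical frame (y increasing with row index).
angle_deg <- function(dx, dy) {
  (atan2(dy, dx) * 180 / pi) %% 360
}

#' Total degrees covered by a set of angular intervals
#'
#' Intervals are half-open `[start, end)` in degrees within `[0, 360)`;
#' an interval with `end < start` wraps through 0. Used both by the
#' generator (ground-truth coverage is exactly the summed lengths / 360)
#' and by interval validation.
#'
#' @param intervals list of length-2 numeric vectors `c(start, end)`.
#' @return total length in degrees.
#' @export
interval_total_deg <- function(intervals) {
  if (length(intervals) == 0) return(0)
  sum(vapply(intervals, function(iv) {
    len <- (iv[2] - iv[1]) %% 360
    if (len == 0 && iv[2] != iv[1]) 360 else if (iv[1] == 0 && iv[2] == 360) 360 else len
  }, numeric(1)))
}

#' Test whether angles fall inside a set of half-open angular intervals
#'
#' @param theta numeric vector of angles in degrees (any range; reduced
#'   modulo 360).
#' @param intervals list of `c(start, end)` half-open intervals in degrees.
#' @return logical vector.
#' @export
angle_in_intervals <- function(theta, intervals) {
  theta <- theta %% 360
  hit <- rep(FALSE, length(theta))
  for (iv in intervals) {
    a <- iv[1] %% 360
    b <- iv[2]
    if (b == 360 && a == 0) {
      hit <- hit | TRUE
    } else {
      b <- b %% 360
      if (a <= b) hit <- hit | (theta >= a & theta < b)
      else hit <- hit | (theta >= a | theta < b)
    }
  }
  hit
}

# Disk mask: TRUE where the pixel centre is within `radius_um` of
# `center_um` (x, y in micrometres).
disk_mask <- function(nrow, ncol, pixel_size_um, center_um, radius_um) {
  pc <- pixel_centers(nrow, ncol, pixel_size_um)
  dx <- outer(rep(1, nrow), pc$x - center_um[1])
  dy <- outer(pc$y - center_um[2], rep(1, ncol))
  sqrt(dx^2 + dy^2) <= radius_um
}

# Matrices of per-pixel dx, dy, radius and angle relative to a centre.
pixel_polar <- function(nrow, ncol, pixel_size_um, center_um) {
  pc <- pixel_centers(nrow, ncol, pixel_size_um)
  dx <- outer(rep(1, nrow), pc$x - center_um[1])
  dy <- outer(pc$y - center_um[2], rep(1, ncol))
  list(dx = dx, dy = dy, r = sqrt(dx^2 + dy^2), theta = angle_deg(dx, dy))
}
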