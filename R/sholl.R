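#' Sholl profile from an SWC morphology
#'
#' Counts, for each concentric sphere of radius `r` around the soma, the
#' exact number of intersections between tree edges (straight segments
#' between consecutive SWC nodes) and the sphere. An edge whose endpoint
#' distances straddle `r` crosses once; an edge with both endpoints
#' outside but closest approach inside crosses twice. Crossings are
#' found by solving the segment-sphere quadratic on `t` in `(0, 1]`.
#'
#' @param morph `NeuronMorphology` (see [simulate_neuron_swc()],
#'   [read_swc()]).
#' @param delta_r_um radial step of the concentric circles, micrometres
#'   (5 by default, the standard spacing for this assay).
#' @param max_r_um largest radius; defaults to the farthest node
#'   distance rounded up to a multiple of `delta_r_um`.
#' @param types optional SWC type codes to keep (e.g. `3` for basal
#'   dendrites); soma nodes are always kept as origins. `NULL` counts
#'   all neurites.
#' @return `ShollProfile`: list with `radii_um`, `intersections`, `auc`.
#' @export
sholl_from_swc <- function(morph, delta_r_um = 5, max_r_um = NULL,
                           types = NULL) {
  validate_morphology(morph)
  soma <- morph[morph$parent < 0, ][1, ]
  p0 <- c(soma$x, soma$y, soma$z)
  keep <- morph$parent >= 0
  if (!is.null(types)) keep <- keep & morph$type %in% types
  child <- morph[keep, , drop = FALSE]
  pid <- match(child$parent, morph$id)
  a <- cbind(morph$x[pid], morph$y[pid], morph$z[pid])
  b <- cbind(child$x, child$y, child$z)
  da <- sqrt(rowSums(sweep(a, 2, p0)^2))
  db <- sqrt(rowSums(sweep(b, 2, p0)^2))
  far <- max(c(0, da, db))
  if (is.null(max_r_um)) max_r_um <- max(delta_r_um,
                                         ceiling(far / delta_r_um) * delta_r_um)
  if (max_r_um < delta_r_um) stop("max_r_um must be >= delta_r_um")
  radii <- seq(delta_r_um, max_r_um, by = delta_r_um)
  counts <- vapply(radii, function(r)
    sum(segment_sphere_crossings(a, b, p0, r)), numeric(1))
  new_sholl_profile(radii, counts)
}

# Exact number of intersections of segments a->b with the sphere of
# radius r centred at p0, counting parameter values t in (0, 1].
segment_sphere_crossings <- function(a, b, p0, r) {
  if (nrow(a) == 0) return(integer(0))
  a0 <- sweep(a, 2, p0); b0 <- sweep(b, 2, p0)
  d <- b0 - a0
  A <- rowSums(d^2)
  B <- 2 * rowSums(a0 * d)
  C <- rowSums(a0^2) - r^2
  n <- numeric(nrow(a))
  disc <- B^2 - 4 * A * C
  ok <- A > 0 & disc >= 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- (-B[ok] - sq) / (2 * A[ok])
    t2 <- (-B[ok] + sq) / (2 * A[ok])
    eps <- 1e-12
    n[ok] <- (t1 > eps & t1 <= 1 + eps) + (t2 > eps & t2 <= 1 + eps & sq > eps)
  }
  n
}

new_sholl_profile <- function(radii, counts) {
  counts <- as.numeric(counts)
  auc <- if (length(radii) >= 2) trapezoid_integral(radii, counts) else 0
  structure(list(radii_um = radii, intersections = counts, auc = auc),
            class = "ShollProfile")
}

#' @export
print.ShollProfile <- function(x, ...) {
  cat("ShollProfile:", length(x$radii_um), "radii,",
      "max", max(x$intersections), "intersections, AUC",
      format(x$auc, digits = 6), "\n")
  invisible(x)
}

trapezoid_integral <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

#' Sholl profile from a binary neurite mask
#'
#' For each radius, the discrete circle of that radius around the soma
#' is rasterized with the midpoint algorithm, the mask is sampled along
#' the (8-connected, angularly ordered, closed) circle path, and each
#' maximal run of foreground pixels counts as one intersection.
#'
#' @param mask logical or 0/1 matrix (rows = y, cols = x).
#' @param soma_xy_um soma position (x, y) in micrometres.
#' @param pixel_size_um micrometres per pixel.
#' @param delta_r_um radial step, micrometres.
#' @param max_r_um largest radius; defaults to the largest circle fully
#'   measurable inside the image.
#' @return `ShollProfile`.
#' @export
sholl_from_mask <- function(mask, soma_xy_um, pixel_size_um, delta_r_um = 5,
                            max_r_um = NULL) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  ny <- nrow(mask); nx <- ncol(mask)
  sc <- floor(soma_xy_um[1] / pixel_size_um) + 1  # column
  sr <- floor(soma_xy_um[2] / pixel_size_um) + 1  # row
  if (sr < 1 || sr > ny || sc < 1 || sc > nx)
    stop("soma position lies outside the image")
  if (is.null(max_r_um)) {
    lim_px <- min(sr - 1, ny - sr, sc - 1, nx - sc)
    max_r_um <- max(delta_r_um, floor(lim_px * pixel_size_um / delta_r_um) *
                      delta_r_um)
  }
  radii <- seq(delta_r_um, max_r_um, by = delta_r_um)
  counts <- vapply(radii, function(r) {
    rp <- round(r / pixel_size_um)
    if (rp < 1) return(0)
    pts <- midpoint_circle(rp)
    rows <- sr + pts[, 2]; cols <- sc + pts[, 1]
    inside <- rows >= 1 & rows <= ny & cols >= 1 & cols <= nx
    fg <- rep(FALSE, nrow(pts))
    fg[inside] <- mask[cbind(rows[inside], cols[inside])]
    count_circular_runs(fg)
  }, numeric(1))
  new_sholl_profile(radii, counts)
}

# Midpoint-circle pixel offsets (dx, dy) of radius r (pixels), ordered
# by angle so consecutive points are 8-connected around the circle.
midpoint_circle <- function(r) {
  x <- r; y <- 0; err <- 1 - r
  pts <- matrix(0L, 0, 2)
  while (x >= y) {
    pts <- rbind(pts, c(x, y))
    y <- y + 1
    if (err < 0) err <- err + 2 * y + 1
    else { x <- x - 1; err <- err + 2 * (y - x) + 1 }
  }
  # reflect one octant into all eight, then order by angle
  oct <- rbind(pts,
               cbind(pts[, 2], pts[, 1]),
               cbind(-pts[, 2], pts[, 1]),
               cbind(-pts[, 1], pts[, 2]),
               cbind(-pts[, 1], -pts[, 2]),
               cbind(-pts[, 2], -pts[, 1]),
               cbind(pts[, 2], -pts[, 1]),
               cbind(pts[, 1], -pts[, 2]))
  oct <- unique(oct)
  ang <- atan2(oct[, 2], oct[, 1])
  oct[order(ang), , drop = FALSE]
}

# Number of maximal TRUE runs in a circular boolean sequence.
count_circular_runs <- function(fg) {
  n <- length(fg)
  if (n == 0 || !any(fg)) return(0)
  if (all(fg)) return(1)
  starts <- fg & !fg[c(n, seq_len(n - 1))]
  sum(starts)
}

#' Area under a Sholl curve
#'
#' Trapezoidal integral of intersection counts over radius (the default
#' arborization summary); a plain sum of counts is exposed as an option.
#'
#' @param profile `ShollProfile`.
#' @param method `"trapezoid"` (default) or `"sum"`.
#' @return numeric AUC (um x count) or summed counts.
#' @export
profile_auc <- function(profile, method = c("trapezoid", "sum")) {
  method <- match.arg(method)
  if (length(profile$radii_um) < 2) stop("AUC needs at least two radii")
  if (method == "sum") return(sum(profile$intersections))
  trapezoid_integral(profile$radii_um, profile$intersections)
}

#' Render a morphology into a binary pixel mask
#'
#' Draws every edge as a one-pixel-wide line (dense sampling along the
#' segment) plus a soma disk, on a canvas centred on the soma. Used to
#' cross-check mask-based against vector-based Sholl profiles.
#'
#' Neurites are drawn with a physical thickness (`neurite_radius_um`) so
#' that every crossing of a discrete sampling circle shares at least one
#' pixel with it (a one-pixel line and a one-pixel circle can cross
#' between pixels).
#'
#' @param morph `NeuronMorphology`.
#' @param pixel_size_um micrometres per pixel.
#' @param pad_um canvas margin beyond the farthest node.
#' @param soma_radius_um rendered soma disk radius.
#' @param neurite_radius_um rendered neurite half-thickness.
#' @return list with `mask` (logical matrix) and `soma_xy_um`.
#' @export
render_morphology_mask <- function(morph, pixel_size_um = 0.5, pad_um = 10,
                                   soma_radius_um = 2,
                                   neurite_radius_um = 0.4) {
  validate_morphology(morph)
  soma <- morph[morph$parent < 0, ][1, ]
  ext <- max(sqrt((morph$x - soma$x)^2 + (morph$y - soma$y)^2)) + pad_um
  n <- 2 * ceiling(ext / pixel_size_um) + 1
  soma_xy <- c(ext, ext)
  mask <- matrix(FALSE, n, n)
  # pixels within neurite_radius of a sampled point along each segment
  reach_px <- max(0L, ceiling(neurite_radius_um / pixel_size_um))
  offs <- expand.grid(dr = -reach_px:reach_px, dc = -reach_px:reach_px)
  offs <- offs[sqrt(offs$dr^2 + offs$dc^2) * pixel_size_um <=
                 neurite_radius_um + 0.5 * pixel_size_um, , drop = FALSE]
  mark <- function(x_um, y_um) {
    cols <- floor(x_um / pixel_size_um) + 1
    rows <- floor(y_um / pixel_size_um) + 1
    for (o in seq_len(nrow(offs))) {
      r2 <- rows + offs$dr[o]; c2 <- cols + offs$dc[o]
      ok <- r2 >= 1 & r2 <= n & c2 >= 1 & c2 <= n
      mask[cbind(r2[ok], c2[ok])] <<- TRUE
    }
  }
  child <- morph[morph$parent >= 0, , drop = FALSE]
  pid <- match(child$parent, morph$id)
  for (k in seq_len(nrow(child))) {
    x0 <- morph$x[pid[k]] - soma$x + ext; y0 <- morph$y[pid[k]] - soma$y + ext
    x1 <- child$x[k] - soma$x + ext;      y1 <- child$y[k] - soma$y + ext
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    t <- seq(0, 1, length.out = max(2, ceiling(len / (pixel_size_um / 3))))
    mark(x0 + t * (x1 - x0), y0 + t * (y1 - y0))
  }
  dm <- disk_mask(n, n, pixel_size_um, soma_xy, soma_radius_um)
  mask <- mask | dm
  list(mask = mask, soma_xy_um = soma_xy)
}
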