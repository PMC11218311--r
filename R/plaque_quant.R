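#' Maximum-intensity projection of central optical slices
#'
#' Projects `n_slices` slices centred on `z_center` (clamped at the
#' stack boundaries) by element-wise maximum, for every channel. Three
#' slices through the plaque centre is the standard window for the
#' coverage/dystrophy measurements.
#'
#' @param stack `ImageStack`.
#' @param z_center central slice index; defaults to the middle slice.
#' @param n_slices odd number of slices to project.
#' @return `ImageStack` with a single z-slice.
#' @export
project_central_slices <- function(stack, z_center = NULL, n_slices = 3) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$pixels)
  if (d[3] < 1) stop("empty stack")
  if (n_slices %% 2 != 1) stop("n_slices must be odd")
  if (is.null(z_center)) z_center <- ceiling(d[3] / 2)
  half <- (n_slices - 1) / 2
  zs <- max(1, z_center - half):min(d[3], z_center + half)
  proj <- array(0, dim = c(d[1], d[2], 1, d[4]))
  for (ch in seq_len(d[4]))
    proj[, , 1, ch] <- apply(stack$pixels[, , zs, ch, drop = FALSE],
                             c(1, 2), max)
  image_stack(proj, stack$pixel_size_um, stack$z_step_um, stack$channel_roles)
}

#' Segment amyloid plaques from the plaque channel
#'
#' Thresholds the channel (Otsu by default), labels 4-connected
#' components, drops components below `min_area_um2`, and reports each
#' plaque with its intensity-weighted centroid (the plaque "centre
#' point"), area and equivalent diameter. Plaques are ordered by
#' centroid (y, x) so output is deterministic.
#'
#' @param img `ImageStack` projection or plain matrix.
#' @param pixel_size_um calibration; taken from `img` when it is a
#'   stack.
#' @param threshold `"otsu"` or a numeric intensity cutoff.
#' @param min_area_um2 minimum plaque area, square micrometres.
#' @param channel channel role used when `img` is a stack.
#' @param z_center slice index recorded on each plaque.
#' @return list of `Plaque` objects (possibly empty); each has `id`,
#'   `mask`, `centroid_um`, `area_um2`, `equiv_diameter_um`, `z_center`.
#'   Use [plaque_table()] for a data.frame view.
#' @export
segment_plaques <- function(img, pixel_size_um = NULL, threshold = "otsu",
                            min_area_um2 = 10, channel = "plaque",
                            z_center = 1L) {
  if (inherits(img, "ImageStack")) {
    pixel_size_um <- img$pixel_size_um
    mat <- get_channel(img, channel)
  } else mat <- img
  if (is.null(pixel_size_um)) stop("pixel_size_um required for matrix input")
  thr <- resolve_threshold(mat, threshold)
  mask <- mat >= thr
  if (!any(mask)) return(list())
  lab <- label_components(mask)
  px_area <- pixel_size_um^2
  pc <- pixel_centers(nrow(mat), ncol(mat), pixel_size_um)
  out <- list()
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    area <- sum(comp) * px_area
    if (area < min_area_um2) next
    w <- mat * comp
    tw <- sum(w)
    cx <- sum(sweep(w, 2, pc$x, `*`)) / tw
    cy <- sum(sweep(w, 1, pc$y, `*`)) / tw
    out[[length(out) + 1]] <- structure(
      list(id = NA_integer_, mask = comp, centroid_um = c(cx, cy),
           area_um2 = area, equiv_diameter_um = 2 * sqrt(area / pi),
           z_center = as.integer(z_center)),
      class = "Plaque")
  }
  if (length(out) == 0) return(out)
  ord <- order(vapply(out, function(p) p$centroid_um[2], numeric(1)),
               vapply(out, function(p) p$centroid_um[1], numeric(1)))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Tabulate a list of segmented plaques
#'
#' @param plaques list of `Plaque` objects from [segment_plaques()].
#' @return data.frame with one row per plaque.
#' @export
plaque_table <- function(plaques) {
  if (length(plaques) == 0)
    return(data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), equiv_diameter_um = numeric()))
  data.frame(
    id = vapply(plaques, `[[`, integer(1), "id"),
    x_um = vapply(plaques, function(p) p$centroid_um[1], numeric(1)),
    y_um = vapply(plaques, function(p) p$centroid_um[2], numeric(1)),
    area_um2 = vapply(plaques, `[[`, numeric(1), "area_um2"),
    equiv_diameter_um = vapply(plaques, `[[`, numeric(1),
                               "equiv_diameter_um"))
}

#' Fraction of an ROI positive for Iba1
#'
#' Thresholded-positive pixels divided by ROI pixels; the microgliosis
#' readout ("percentage of Iba1-positive area").
#'
#' @param mat 2D intensity matrix (Iba1 channel).
#' @param threshold `"otsu"` or numeric.
#' @param roi_mask logical matrix restricting the measurement; `NULL`
#'   uses the whole image.
#' @return fraction in `[0, 1]`.
#' @export
iba1_area_fraction <- function(mat, threshold = "otsu", roi_mask = NULL) {
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(mat), ncol(mat))
  if (!any(roi_mask)) stop("empty ROI")
  if (max(mat) <= 0) return(0)
  thr <- resolve_threshold(mat, threshold)
  sum(mat[roi_mask] >= thr) / sum(roi_mask)
}

#' Detect microglial somata as soma-scale blobs
#'
#' Thresholds the Iba1 channel, labels 4-connected components, and keeps
#' components whose area is within `[0.25, 4]` times the nominal soma
#' disk area; centroids are returned in micrometres. Two somata closer
#' than the soma diameter merge into a single component and are reported
#' as one detection.
#'
#' @param mat 2D Iba1 intensity matrix.
#' @param pixel_size_um calibration.
#' @param soma_diameter_um nominal soma diameter (6 um default).
#' @param threshold `"otsu"` or numeric.
#' @return `SomaSet` data.frame with `x_um`, `y_um`.
#' @export
detect_somata <- function(mat, pixel_size_um, soma_diameter_um = 6,
                          threshold = "otsu") {
  empty <- data.frame(x_um = numeric(), y_um = numeric())
  if (max(mat) <= 0) return(empty)
  thr <- resolve_threshold(mat, threshold)
  mask <- mat >= thr
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  nominal <- pi * (soma_diameter_um / 2)^2 / pixel_size_um^2
  pc <- pixel_centers(nrow(mat), ncol(mat), pixel_size_um)
  xs <- ys <- numeric(0)
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    n <- sum(comp)
    if (n < 0.25 * nominal || n > 4 * nominal) next
    idx <- which(comp, arr.ind = TRUE)
    xs <- c(xs, mean(pc$x[idx[, 2]]))
    ys <- c(ys, mean(pc$y[idx[, 1]]))
  }
  out <- data.frame(x_um = xs, y_um = ys)
  out[order(out$y_um, out$x_um), , drop = FALSE]
}

#' Count plaque-associated microglia
#'
#' For each plaque, the number of somata within `radius_um` (Euclidean
#' distance from the plaque centre point; boundary ties at exactly the
#' radius are included). 25 um is the standard association radius.
#'
#' @param plaques list of `Plaque` objects or a data.frame with
#'   `x_um`, `y_um` (and optionally `id`).
#' @param somata `SomaSet` data.frame with `x_um`, `y_um`.
#' @param radius_um association radius, micrometres.
#' @return data.frame `plaque_id`, `microglia_count`.
#' @export
count_plaque_associated_microglia <- function(plaques, somata,
                                              radius_um = 25) {
  tab <- if (is.data.frame(plaques)) plaques else plaque_table(plaques)
  if (!"id" %in% names(tab)) tab$id <- seq_len(nrow(tab))
  counts <- vapply(seq_len(nrow(tab)), function(i) {
    if (nrow(somata) == 0) return(0L)
    d <- sqrt((somata$x_um - tab$x_um[i])^2 + (somata$y_um - tab$y_um[i])^2)
    sum(d <= radius_um)
  }, integer(1))
  data.frame(plaque_id = tab$id, microglia_count = counts)
}
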