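#' Simulate a phagocytosis assay field
#'
#' Places `n_cells` non-overlapping cell bodies (Iba1 channel) with a
#' nucleus each (nuclei channel) by dart throwing, and deposits bright
#' FITC puncta inside exactly `round(frac_positive * n_cells)` cells.
#' Which cells are positive is part of the emitted ground truth.
#'
#' @param n_cells number of cells.
#' @param frac_positive fraction of cells containing FITC puncta.
#' @param puncta_intensity intensity of the FITC puncta plateau (a.u.).
#' @param seed integer seed.
#' @param field_size_um square field side, micrometres.
#' @param pixel_size_um micrometres per pixel.
#' @param cell_radius_um,nucleus_radius_um rendered cell/nucleus radii.
#' @param n_puncta,punctum_radius_um puncta per positive cell and their
#'   radius.
#' @param noise_sd,psf_sigma_um noise model (see [sim_config()]).
#' @param max_tries dart-throwing retries per cell before failing.
#' @return list with `stack` (`ImageStack` with roles `iba1`, `nuclei`,
#'   `fitc`; single z-slice) and `truth` (data.frame: cell centre,
#'   `positive` label).
#' @export
simulate_phagocytosis_image <- function(n_cells, frac_positive,
                                        puncta_intensity = 0.8, seed = 1L,
                                        field_size_um = 250,
                                        pixel_size_um = 0.5,
                                        cell_radius_um = 7,
                                        nucleus_radius_um = 2.5,
                                        n_puncta = 3,
                                        punctum_radius_um = 1.5,
                                        noise_sd = 0.01,
                                        psf_sigma_um = 0.15,
                                        max_tries = 2000) {
  stopifnot(frac_positive >= 0, frac_positive <= 1, n_cells >= 1)
  set.seed(as.integer(seed))
  n <- round(field_size_um / pixel_size_um)
  margin <- cell_radius_um + 2
  centers <- matrix(NA_real_, 0, 2)
  min_gap <- 2 * cell_radius_um + 1
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- runif(2, margin, field_size_um - margin)
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_gap) {
        centers <- rbind(centers, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n_cells, " non-overlapping cells in a ",
           field_size_um, " um field after ", max_tries, " tries each")
  }
  n_pos <- round(frac_positive * n_cells)
  positive <- rep(FALSE, n_cells)
  if (n_pos > 0) positive[sample.int(n_cells, n_pos)] <- TRUE

  iba1 <- nucl <- fitc <- matrix(0, n, n)
  for (i in seq_len(n_cells)) {
    cm <- disk_mask(n, n, pixel_size_um, centers[i, ], cell_radius_um)
    iba1[cm] <- 0.8
    nm <- disk_mask(n, n, pixel_size_um, centers[i, ], nucleus_radius_um)
    nucl[nm] <- 1
    if (positive[i]) {
      for (k in seq_len(n_puncta)) {
        rr <- runif(1, nucleus_radius_um + punctum_radius_um,
                    0.7 * cell_radius_um)
        th <- runif(1, 0, 2 * pi)
        pc <- centers[i, ] + rr * c(cos(th), sin(th))
        pm <- disk_mask(n, n, pixel_size_um, pc, punctum_radius_um)
        fitc[pm] <- puncta_intensity
      }
    }
  }
  blur_noise <- function(m) {
    s <- psf_sigma_um / pixel_size_um
    if (s > 0) m <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(m),
                                                      sigma = s))
    if (noise_sd > 0) m <- m + rnorm(length(m), sd = noise_sd)
    pmax(m, 0)
  }
  px <- array(0, dim = c(n, n, 1, 3))
  px[, , 1, 1] <- blur_noise(iba1)
  px[, , 1, 2] <- blur_noise(nucl)
  px[, , 1, 3] <- blur_noise(fitc)
  stack <- image_stack(px, pixel_size_um, 1,
                       c(iba1 = 1, nuclei = 2, fitc = 3))
  truth <- data.frame(cell_id = seq_len(n_cells),
                      x_um = centers[, 1], y_um = centers[, 2],
                      positive = positive)
  list(stack = stack, truth = truth)
}
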