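#' Simulation configuration for synthetic histology fields
#'
#' Defines the imaging geometry and noise model of a synthetic
#' multi-channel stack. Defaults emulate 40x confocal acquisition of
#' hippocampal sections: sub-micrometre lateral sampling, 3-um z-steps,
#' and a small-sigma Gaussian point-spread approximation. One `seed`
#' fixes all randomness; two runs with an equal config are bit-identical.
#'
#' @param field_size_um length-2 field extent (x, y) in micrometres.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param z_slices number of optical slices (>= 1).
#' @param z_step_um axial step, micrometres.
#' @param channel_roles named role -> channel index map.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param psf_sigma_um Gaussian PSF sigma, micrometres.
#' @param seed integer random seed.
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(field_size_um = c(80, 80), pixel_size_um = 0.5,
                       z_slices = 5, z_step_um = 3,
                       channel_roles = c(plaque = 1, iba1 = 2, lamp1 = 3,
                                         nuclei = 4, fitc = 5),
                       noise_sd = 0.02, psf_sigma_um = 0.4, seed = 1L) {
  stopifnot(length(field_size_um) == 2, pixel_size_um > 0, z_slices >= 1,
            noise_sd >= 0, psf_sigma_um >= 0)
  structure(list(field_size_um = as.numeric(field_size_um),
                 pixel_size_um = pixel_size_um, z_slices = as.integer(z_slices),
                 z_step_um = z_step_um, channel_roles = channel_roles,
                 noise_sd = noise_sd, psf_sigma_um = psf_sigma_um,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Ground-truth specification of one synthetic plaque neighbourhood
#'
#' Describes a disk-like amyloid deposit, the angular intervals of its
#' perimeter enveloped by microglia (Iba1), the peri-plaque Lamp1 halo
#' (dystrophic neurites) with sector-class-dependent density, and the
#' surrounding microglial soma point process.
#'
#' `lamp1_density_*` are area fractions: the expected fraction of halo
#' pixels (between the plaque edge and `lamp1_outer_radius_um`) that are
#' Lamp1-positive within covered / uncovered sectors. The implied true
#' Lamp1 area per degree is `density * pi * (R^2 - r^2) / 360`.
#'
#' @param center_um plaque centre (x, y), micrometres.
#' @param radius_um plaque radius (> 0), micrometres.
#' @param covered_intervals_deg list of half-open `[start, end)` degree
#'   intervals in `[0, 360)`, pairwise disjoint; angles counterclockwise
#'   from +x in the image physical frame.
#' @param lamp1_density_covered,lamp1_density_uncovered halo area
#'   fractions (>= 0, <= 1) in covered / uncovered sectors.
#' @param lamp1_outer_radius_um outer halo radius, micrometres
#'   (>= radius_um).
#' @param n_somata_within_25um microglial somata placed within 25 um of
#'   the centre (outside the plaque).
#' @param n_somata_background somata scattered over the whole field.
#' @return object of class `PlaqueSpec`.
#' @export
plaque_spec <- function(center_um, radius_um, covered_intervals_deg = list(),
                        lamp1_density_covered = 0, lamp1_density_uncovered = 0,
                        lamp1_outer_radius_um = radius_um,
                        n_somata_within_25um = 0, n_somata_background = 0) {
  stopifnot(radius_um > 0, lamp1_density_covered >= 0,
            lamp1_density_uncovered >= 0,
            lamp1_density_covered <= 1, lamp1_density_uncovered <= 1,
            lamp1_outer_radius_um >= radius_um)
  for (iv in covered_intervals_deg)
    stopifnot(length(iv) == 2, iv[1] >= 0, iv[1] < 360, iv[2] > iv[1],
              iv[2] <= 360)
  # pairwise disjoint check on [start, end) intervals
  if (length(covered_intervals_deg) > 1) {
    m <- do.call(rbind, covered_intervals_deg)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2]))
      stop("covered intervals must be pairwise disjoint")
  }
  structure(list(center_um = as.numeric(center_um), radius_um = radius_um,
                 covered_intervals_deg = covered_intervals_deg,
                 lamp1_density_covered = lamp1_density_covered,
                 lamp1_density_uncovered = lamp1_density_uncovered,
                 lamp1_outer_radius_um = lamp1_outer_radius_um,
                 n_somata_within_25um = as.integer(n_somata_within_25um),
                 n_somata_background = as.integer(n_somata_background)),
            class = "PlaqueSpec")
}

# Soma rendering scale: microglial somata are drawn as 6-um-diameter
# disks, a typical soma size that stays detectable at the pixel sizes
# used here.
SOMA_DIAMETER_UM <- 6

# Thickness of the rendered Iba1 envelope over covered arcs.
ARC_THICKNESS_UM <- 2

# Radius of the rendered Lamp1 blobs; 1.5 um is a typical cross-section
# of a swollen dystrophic neurite and keeps blobs resolvable (and their
# thresholded area faithful) after PSF blur at the default pixel sizes.
LAMP1_BLOB_RADIUS_UM <- 1.5

# Stamp a disk of `value` into `mat` (bounded rasterization).
stamp_disk <- function(mat, center_um, radius_um, pixel_size_um, value) {
  r0 <- max(1, floor((center_um[2] - radius_um) / pixel_size_um))
  r1 <- min(nrow(mat), ceiling((center_um[2] + radius_um) / pixel_size_um) + 1)
  c0 <- max(1, floor((center_um[1] - radius_um) / pixel_size_um))
  c1 <- min(ncol(mat), ceiling((center_um[1] + radius_um) / pixel_size_um) + 1)
  if (r0 > r1 || c0 > c1) return(mat)
  ys <- (r0:r1 - 0.5) * pixel_size_um - center_um[2]
  xs <- (c0:c1 - 0.5) * pixel_size_um - center_um[1]
  d2 <- outer(ys^2, xs^2, `+`)
  sub <- mat[r0:r1, c0:c1, drop = FALSE]
  sub[d2 <= radius_um^2] <- value
  mat[r0:r1, c0:c1] <- sub
  mat
}

# Render a Lamp1 halo region as a boolean model of small disks whose
# expected area fraction equals `density`: blob intensity per unit area
# lambda solves 1 - exp(-lambda * blob_area) = density.
render_lamp1_blobs <- function(lam_mat, region, density, pixel_size_um) {
  if (density <= 0 || !any(region)) return(lam_mat)
  density <- min(density, 0.99)
  a_blob <- pi * LAMP1_BLOB_RADIUS_UM^2
  area <- sum(region) * pixel_size_um^2
  n_blobs <- round(-log(1 - density) / a_blob * area)
  if (n_blobs == 0) return(lam_mat)
  idx <- which(region, arr.ind = TRUE)
  pick <- idx[sample.int(nrow(idx), n_blobs, replace = TRUE), , drop = FALSE]
  cx <- (pick[, 2] - 1 + runif(n_blobs)) * pixel_size_um
  cy <- (pick[, 1] - 1 + runif(n_blobs)) * pixel_size_um
  for (k in seq_len(n_blobs))
    lam_mat <- stamp_disk(lam_mat, c(cx[k], cy[k]), LAMP1_BLOB_RADIUS_UM,
                          pixel_size_um, 0.9)
  lam_mat
}

#' Simulate a multi-channel peri-plaque histology stack
#'
#' Renders, for each [plaque_spec()]: a bright disk on the plaque
#' channel; an Iba1 annulus present only over the covered angular
#' intervals, plus soma disks (near-plaque and background) on the Iba1
#' and nuclei channels; and a speckled Lamp1 halo between the plaque
#' edge and the outer halo radius whose per-degree positive area matches
#' the spec densities in expectation. Structures are strongest on the
#' central slice and fade axially; each slice is blurred with the
#' Gaussian PSF and Gaussian noise is added.
#'
#' @param cfg [sim_config()].
#' @param plaques list of [plaque_spec()] (a single spec is accepted).
#' @return list with elements `stack` (an [image_stack()]), `truth`
#'   (data.frame, one row per plaque: true coverage, per-degree Lamp1
#'   areas by sector class, soma count) and `somata` (data.frame of true
#'   soma centres with a `plaque_id` of 0 for background somata).
#' @export
simulate_histology_stack <- function(cfg, plaques) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (inherits(plaques, "PlaqueSpec")) plaques <- list(plaques)
  nx <- round(cfg$field_size_um[1] / cfg$pixel_size_um)
  ny <- round(cfg$field_size_um[2] / cfg$pixel_size_um)
  for (p in plaques) {
    reach <- max(p$lamp1_outer_radius_um, p$radius_um)
    if (p$center_um[1] - reach < 0 || p$center_um[1] + reach > cfg$field_size_um[1] ||
        p$center_um[2] - reach < 0 || p$center_um[2] + reach > cfg$field_size_um[2])
      stop("plaque at (", p$center_um[1], ", ", p$center_um[2],
           ") um with halo radius ", reach, " um does not fit inside the ",
           cfg$field_size_um[1], " x ", cfg$field_size_um[2], " um field")
  }
  set.seed(cfg$seed)
  n_ch <- max(cfg$channel_roles)
  plane <- array(0, dim = c(ny, nx, n_ch))
  ch <- function(role) cfg$channel_roles[[role]]

  truth <- data.frame(plaque_id = integer(), x_um = numeric(), y_um = numeric(),
                      radius_um = numeric(), coverage = numeric(),
                      lamp1_per_deg_covered_um2 = numeric(),
                      lamp1_per_deg_uncovered_um2 = numeric(),
                      n_somata_within_25um = integer())
  somata <- data.frame(plaque_id = integer(), x_um = numeric(), y_um = numeric())

  for (i in seq_along(plaques)) {
    p <- plaques[[i]]
    pol <- pixel_polar(ny, nx, cfg$pixel_size_um, p$center_um)
    pk <- pol$r <= p$radius_um
    plane[, , ch("plaque")][pk] <- 1

    covered <- angle_in_intervals(pol$theta, p$covered_intervals_deg)
    annulus <- pol$r > p$radius_um & pol$r <= p$radius_um + ARC_THICKNESS_UM
    plane[, , ch("iba1")][annulus & covered] <- 1

    halo <- pol$r > p$radius_um & pol$r <= p$lamp1_outer_radius_um
    if (any(halo)) {
      lam <- plane[, , ch("lamp1")]
      lam <- render_lamp1_blobs(lam, halo & covered,
                                p$lamp1_density_covered, cfg$pixel_size_um)
      lam <- render_lamp1_blobs(lam, halo & !covered,
                                p$lamp1_density_uncovered, cfg$pixel_size_um)
      plane[, , ch("lamp1")] <- lam
    }

    # near-plaque somata: uniform in angle, radius in (r + soma, 25]
    if (p$n_somata_within_25um > 0) {
      r_lo <- p$radius_um + SOMA_DIAMETER_UM / 2
      if (r_lo >= 25)
        stop("plaque radius too large to place somata within 25 um")
      rr <- sqrt(runif(p$n_somata_within_25um, r_lo^2, 25^2))
      th <- runif(p$n_somata_within_25um, 0, 2 * pi)
      sx <- p$center_um[1] + rr * cos(th)
      sy <- p$center_um[2] + rr * sin(th)
      somata <- rbind(somata, data.frame(plaque_id = i, x_um = sx, y_um = sy))
    }
    if (p$n_somata_background > 0) {
      sx <- runif(p$n_somata_background, SOMA_DIAMETER_UM,
                  cfg$field_size_um[1] - SOMA_DIAMETER_UM)
      sy <- runif(p$n_somata_background, SOMA_DIAMETER_UM,
                  cfg$field_size_um[2] - SOMA_DIAMETER_UM)
      somata <- rbind(somata, data.frame(plaque_id = 0L, x_um = sx, y_um = sy))
    }

    ring_area_per_deg <- pi * (p$lamp1_outer_radius_um^2 - p$radius_um^2) / 360
    truth <- rbind(truth, data.frame(
      plaque_id = i, x_um = p$center_um[1], y_um = p$center_um[2],
      radius_um = p$radius_um,
      coverage = interval_total_deg(p$covered_intervals_deg) / 360,
      lamp1_per_deg_covered_um2 = p$lamp1_density_covered * ring_area_per_deg,
      lamp1_per_deg_uncovered_um2 = p$lamp1_density_uncovered * ring_area_per_deg,
      n_somata_within_25um = p$n_somata_within_25um))
  }

  # render somata on iba1 + nuclei channels
  if (nrow(somata) > 0) {
    for (s in seq_len(nrow(somata))) {
      dm <- disk_mask(ny, nx, cfg$pixel_size_um,
                      c(somata$x_um[s], somata$y_um[s]), SOMA_DIAMETER_UM / 2)
      plane[, , ch("iba1")][dm] <- 1
      nm <- disk_mask(ny, nx, cfg$pixel_size_um,
                      c(somata$x_um[s], somata$y_um[s]), SOMA_DIAMETER_UM / 4)
      plane[, , ch("nuclei")][nm] <- 1
    }
  }

  # axial profile: structures peak at the central slice and fade with a
  # one-slice Gaussian falloff
  zc <- (cfg$z_slices + 1) / 2
  zw <- exp(-((seq_len(cfg$z_slices) - zc)^2) / 2)
  px <- array(0, dim = c(ny, nx, cfg$z_slices, n_ch))
  sigma_px <- cfg$psf_sigma_um / cfg$pixel_size_um
  for (z in seq_len(cfg$z_slices)) for (cc in seq_len(n_ch)) {
    sl <- plane[, , cc] * zw[z]
    if (sigma_px > 0)
      sl <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(sl),
                                              sigma = sigma_px))
    if (cfg$noise_sd > 0)
      sl <- sl + rnorm(length(sl), sd = cfg$noise_sd)
    px[, , z, cc] <- pmax(sl, 0)
  }

  list(stack = image_stack(px, cfg$pixel_size_um, cfg$z_step_um,
                           cfg$channel_roles),
       truth = truth, somata = somata)
}
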