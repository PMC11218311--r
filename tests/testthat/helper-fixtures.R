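# Shared fixtures and independent oracles, all built in code.

# Draw disks on a blank matrix; used to build small images by hand.
draw_disks <- function(nrow, ncol, pixel_size_um, centers_um, radius_um,
                       value = 1) {
  m <- matrix(0, nrow, ncol)
  xs <- (seq_len(ncol) - 0.5) * pixel_size_um
  ys <- (seq_len(nrow) - 0.5) * pixel_size_um
  for (i in seq_len(nrow(centers_um))) {
    d <- outer((ys - centers_um[i, 2])^2, (xs - centers_um[i, 1])^2, `+`)
    m[d <= radius_um^2] <- value
  }
  m
}

# One simulated single-plaque field plus its projection and segmented
# plaque; the work-horse fixture for barrier tests.
sim_one_plaque <- function(seed, radius_um = 8, intervals = list(c(0, 180)),
                           d_cov = 0, d_unc = 0, outer_um = 20,
                           n_bg_somata = 6, field = 80, noise_sd = 0.02,
                           pixel_size_um = 0.5) {
  cfg <- sim_config(field_size_um = c(field, field), seed = seed,
                    noise_sd = noise_sd, pixel_size_um = pixel_size_um)
  ps <- plaque_spec(center_um = c(field / 2, field / 2), radius_um = radius_um,
                    covered_intervals_deg = intervals,
                    lamp1_density_covered = d_cov,
                    lamp1_density_uncovered = d_unc,
                    lamp1_outer_radius_um = outer_um,
                    n_somata_background = n_bg_somata)
  sim <- simulate_histology_stack(cfg, list(ps))
  proj <- project_central_slices(sim$stack)
  pl <- segment_plaques(proj)
  list(sim = sim, proj = proj, plaque = pl[[1]], n_plaques = length(pl))
}

# Independent per-pixel angular-histogram oracle for perimeter
# colocalization: for each 1-degree bin, the boundary radius is the
# outermost plaque-mask pixel whose angle falls in the bin, and the bin
# is covered when any Iba1-positive pixel in the bin lies within
# band_um of that boundary radius.
angular_histogram_oracle <- function(proj, plaque, band_um = 1,
                                     iba1_threshold, dt = 1) {
  px <- proj$pixel_size_um
  iba1 <- get_channel(proj, "iba1")
  imask <- iba1 >= iba1_threshold
  ctr <- plaque$centroid_um
  pix_angle_r <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    x <- (idx[, 2] - 0.5) * px - ctr[1]
    y <- (idx[, 1] - 0.5) * px - ctr[2]
    list(theta = (atan2(y, x) * 180 / pi) %% 360, r = sqrt(x^2 + y^2))
  }
  pm <- pix_angle_r(plaque$mask)
  im <- pix_angle_r(imask)
  n_bins <- 360 / dt
  covered <- logical(n_bins)
  for (b in seq_len(n_bins)) {
    in_bin_p <- pm$theta >= (b - 1) * dt & pm$theta < b * dt
    if (!any(in_bin_p)) { covered[b] <- NA; next }
    bnd <- max(pm$r[in_bin_p])
    in_bin_i <- im$theta >= (b - 1) * dt & im$theta < b * dt
    covered[b] <- any(in_bin_i & abs(im$r - bnd) <= band_um)
  }
  covered
}

# Exhaustive segment-sphere crossing count for one radius, looping over
# edges and solving each quadratic with polyroot (independent of the
# package's vectorized routine).
sholl_brute_force <- function(morph, radii) {
  soma <- morph[morph$parent < 0, ][1, ]
  child <- morph[morph$parent >= 0, , drop = FALSE]
  pid <- match(child$parent, morph$id)
  vapply(radii, function(r) {
    total <- 0
    for (k in seq_len(nrow(child))) {
      p0 <- c(morph$x[pid[k]], morph$y[pid[k]], morph$z[pid[k]]) -
        c(soma$x, soma$y, soma$z)
      p1 <- c(child$x[k], child$y[k], child$z[k]) -
        c(soma$x, soma$y, soma$z)
      d <- p1 - p0
      roots <- tryCatch(polyroot(c(sum(p0^2) - r^2, 2 * sum(p0 * d),
                                   sum(d^2))),
                        error = function(e) complex(0))
      for (rt in roots) {
        if (abs(Im(rt)) < 1e-9) {
          t <- Re(rt)
          if (t > 1e-12 && t <= 1 + 1e-12) total <- total + 1
        }
      }
      # tangency (double root) counted once
      if (length(roots) == 2 && abs(Im(roots[1])) < 1e-9 &&
          abs(Re(roots[1]) - Re(roots[2])) < 1e-9) {
        t <- Re(roots[1])
        if (t > 1e-12 && t <= 1 + 1e-12) total <- total - 1
      }
    }
    total
  }, numeric(1))
}

# Direct transcription of the doubly-trimmed weighted-mean-of-M formula
# for a two-sample TMM factor, independent of the package routine.
tmm_direct_oracle <- function(obs, ref) {
  n_o <- sum(obs); n_r <- sum(ref)
  pos <- obs > 0 & ref > 0
  M <- log2((obs[pos] / n_o) / (ref[pos] / n_r))
  A <- 0.5 * log2((obs[pos] / n_o) * (ref[pos] / n_r))
  w <- (n_o - obs[pos]) / (n_o * obs[pos]) + (n_r - ref[pos]) / (n_r * ref[pos])
  n <- length(M)
  keepM <- rank(M) >= floor(n * 0.3) + 1 & rank(M) <= n - floor(n * 0.3)
  keepA <- rank(A) >= floor(n * 0.05) + 1 & rank(A) <= n - floor(n * 0.05)
  keep <- keepM & keepA
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

# 90-degree clockwise rotation of a matrix (row 1 becomes column n).
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# Rotate every channel of a projected single-slice stack.
rotate_proj <- function(proj) {
  d <- dim(proj$pixels)
  out <- array(0, dim = c(d[2], d[1], 1, d[4]))
  for (ch in seq_len(d[4])) out[, , 1, ch] <- rot90cw(proj$pixels[, , 1, ch])
  image_stack(out, proj$pixel_size_um, proj$z_step_um, proj$channel_roles)
}
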