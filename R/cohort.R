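#' Simulate and measure a cohort of single-plaque fields
#'
#' The work-horse study driver: renders `n_plaques` independent fields,
#' one plaque each, with known coverage, size and Lamp1 sector
#' densities; runs the full measurement chain (projection, plaque
#' segmentation, angular profile, coverage, sector dystrophy) on every
#' field; and returns truth and measurement side by side.
#'
#' Each field gets its own seed derived as `seed * 1000 + i`, so the
#' whole cohort is reproducible from one integer.
#'
#' @param n_plaques number of fields.
#' @param seed master seed.
#' @param coverage vector of true coverage fractions (recycled); `NULL`
#'   draws uniformly from `[0.05, 0.95]`.
#' @param radius_range plaque radius range, micrometres (uniform).
#' @param d_cov,d_unc Lamp1 halo area-fraction densities in covered /
#'   uncovered sectors.
#' @param halo_width_um Lamp1 halo width beyond the plaque edge.
#' @param field_um square field side.
#' @param n_bg_somata background microglial somata per field.
#' @param noise_sd imaging noise (see [sim_config()]).
#' @return data.frame, one row per plaque: truth columns (prefixed
#'   `true_`) and measured columns from [barrier_table()].
#' @export
simulate_barrier_cohort <- function(n_plaques, seed = 1, coverage = NULL,
                                    radius_range = c(3.5, 11),
                                    d_cov = 0.05, d_unc = 0.5,
                                    halo_width_um = 10, field_um = 80,
                                    n_bg_somata = 6, noise_sd = 0.02) {
  set.seed(seed)
  cov_true <- if (is.null(coverage)) runif(n_plaques, 0.05, 0.95)
              else rep(coverage, length.out = n_plaques)
  radii <- runif(n_plaques, radius_range[1], radius_range[2])
  offsets <- runif(n_plaques, 0, 360)
  rows <- vector("list", n_plaques)
  for (i in seq_len(n_plaques)) {
    field_seed <- (seed * 1000 + i) %% 2147483647  # keep within 32-bit
    cfg <- sim_config(field_size_um = c(field_um, field_um),
                      seed = field_seed, noise_sd = noise_sd)
    ivs <- coverage_intervals(offsets[i], cov_true[i])
    ps <- plaque_spec(center_um = c(field_um / 2, field_um / 2),
                      radius_um = radii[i], covered_intervals_deg = ivs,
                      lamp1_density_covered = d_cov,
                      lamp1_density_uncovered = d_unc,
                      lamp1_outer_radius_um = radii[i] + halo_width_um,
                      n_somata_background = n_bg_somata)
    sim <- simulate_histology_stack(cfg, list(ps))
    proj <- project_central_slices(sim$stack)
    plq <- segment_plaques(proj)
    if (length(plq) == 0) next
    meas <- barrier_table(proj, plq[1])
    tr <- sim$truth
    rows[[i]] <- cbind(
      data.frame(field = i, true_coverage = tr$coverage,
                 true_radius_um = tr$radius_um,
                 true_lamp1_per_deg_covered = tr$lamp1_per_deg_covered_um2,
                 true_lamp1_per_deg_uncovered =
                   tr$lamp1_per_deg_uncovered_um2),
      meas[, setdiff(names(meas), "plaque_id")])
  }
  do.call(rbind, rows)
}

# Half-open interval(s) of total length 360 * coverage starting at
# `offset` degrees, split at the 0/360 wrap.
coverage_intervals <- function(offset, coverage) {
  span <- 360 * coverage
  if (span <= 0) return(list())
  if (span >= 360) return(list(c(0, 360)))
  a <- offset %% 360
  b <- a + span
  if (b <= 360) list(c(a, b))
  else list(c(a, 360), c(0, b - 360))
}
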