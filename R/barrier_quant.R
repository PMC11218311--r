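#' Angular profile of a plaque perimeter
#'
#' Partitions `[0, 360)` into `360 / delta_theta_deg` half-open degree
#' bins and casts, for each bin, a ray from the plaque centroid along the
#' bin-centre angle. The perimeter crossing is the outermost plaque-mask
#' point on the ray; the bin is scored Iba1-colocalized when any
#' Iba1-positive pixel lies within `band_um` of that crossing along the
#' ray, and the bin's Lamp1 outer extent is the farthest Lamp1-positive
#' point on the ray beyond the perimeter (plaque area excluded). Angles
#' are counterclockwise from +x in the image physical frame.
#'
#' @param proj projected `ImageStack` (single z) containing `iba1` and
#'   `lamp1` roles, or a list with `iba1`/`lamp1` matrices and
#'   `pixel_size_um`.
#' @param plaque `Plaque` object (mask + centroid).
#' @param delta_theta_deg bin width in degrees; must divide 360.
#' @param band_um half-width of the colocalization band along the ray.
#' @param iba1_threshold,lamp1_threshold `"otsu"` or numeric.
#' @return `AngularProfile`: data.frame with `theta_start_deg`,
#'   `iba1_at_perimeter`, `perimeter_radius_um`, `lamp1_outer_extent_um`
#'   (NA when no Lamp1 on the ray) and attributes `delta_theta_deg`,
#'   `plaque_id`, `centroid_um`.
#' @export
build_angular_profile <- function(proj, plaque, delta_theta_deg = 1,
                                  band_um = 1, iba1_threshold = "otsu",
                                  lamp1_threshold = "otsu") {
  if (360 %% delta_theta_deg != 0) stop("delta_theta_deg must divide 360")
  px <- if (inherits(proj, "ImageStack")) proj$pixel_size_um else proj$pixel_size_um
  iba1 <- get_channel(proj, "iba1")
  lamp1 <- get_channel(proj, "lamp1")
  if (!any(plaque$mask)) stop("plaque mask is empty")
  iba1_mask <- iba1 >= resolve_threshold(iba1, iba1_threshold)
  lamp1_mask <- (lamp1 >= resolve_threshold(lamp1, lamp1_threshold)) &
    !plaque$mask
  ny <- nrow(iba1); nx <- ncol(iba1)
  ctr <- plaque$centroid_um
  # degenerate centroid (outside own mask): fall back to mask centroid
  crow <- floor(ctr[2] / px) + 1; ccol <- floor(ctr[1] / px) + 1
  degenerate <- !(crow >= 1 && crow <= ny && ccol >= 1 && ccol <= nx &&
                    plaque$mask[crow, ccol])
  if (degenerate) {
    idx <- which(plaque$mask, arr.ind = TRUE)
    ctr <- c(mean((idx[, 2] - 0.5) * px), mean((idx[, 1] - 0.5) * px))
  }

  n_bins <- 360 / delta_theta_deg
  theta_start <- (seq_len(n_bins) - 1) * delta_theta_deg
  theta_mid <- (theta_start + delta_theta_deg / 2) * pi / 180
  step <- px / 2
  r_max <- sqrt(max(ctr[1], nx * px - ctr[1])^2 +
                  max(ctr[2], ny * px - ctr[2])^2)
  ts <- seq(step, r_max, by = step)
  # all (bin, step) sample points at once
  cosm <- outer(cos(theta_mid), ts)   # n_bins x n_steps, x-offsets
  sinm <- outer(sin(theta_mid), ts)
  cols <- floor((ctr[1] + cosm) / px) + 1
  rows <- floor((ctr[2] + sinm) / px) + 1
  inside <- rows >= 1 & rows <= ny & cols >= 1 & cols <= nx
  flat <- function(mask) {
    v <- matrix(FALSE, n_bins, length(ts))
    v[inside] <- mask[cbind(rows[inside], cols[inside])]
    v
  }
  on_plaque <- flat(plaque$mask)
  on_iba1 <- flat(iba1_mask)
  on_lamp1 <- flat(lamp1_mask)

  tmat <- matrix(ts, n_bins, length(ts), byrow = TRUE)
  perimeter_r <- apply(ifelse(on_plaque, tmat, NA_real_), 1,
                       function(v) if (all(is.na(v))) NA_real_ else
                         max(v, na.rm = TRUE))
  fallback_r <- sqrt(sum(plaque$mask) * px^2 / pi)
  perimeter_r[is.na(perimeter_r)] <- fallback_r

  band_lo <- perimeter_r - band_um
  band_hi <- perimeter_r + band_um
  in_band <- tmat >= band_lo & tmat <= band_hi
  iba1_at_perimeter <- rowSums(on_iba1 & in_band) > 0

  beyond <- tmat > perimeter_r
  lamp1_extent <- apply(ifelse(on_lamp1 & beyond, tmat, NA_real_), 1,
                        function(v) if (all(is.na(v))) NA_real_ else
                          max(v, na.rm = TRUE))

  out <- data.frame(theta_start_deg = theta_start,
                    iba1_at_perimeter = iba1_at_perimeter,
                    perimeter_radius_um = perimeter_r,
                    lamp1_outer_extent_um = lamp1_extent)
  attr(out, "delta_theta_deg") <- delta_theta_deg
  attr(out, "plaque_id") <- plaque$id
  attr(out, "centroid_um") <- ctr
  attr(out, "degenerate_centroid") <- degenerate
  class(out) <- c("AngularProfile", "data.frame")
  out
}

#' Microglial coverage of a plaque perimeter
#'
#' Coverage is the summed arc (in degrees) of perimeter bins colocalized
#' with Iba1, divided by 360. Covered and uncovered degrees always sum
#' to exactly 360 (integer arithmetic in bin-width units).
#'
#' @param profile `AngularProfile`.
#' @return `CoverageResult`: list with `plaque_id`, `covered_deg`,
#'   `uncovered_deg`, `coverage`.
#' @export
microglia_coverage <- function(profile) {
  dt <- attr(profile, "delta_theta_deg")
  covered <- dt * sum(profile$iba1_at_perimeter)
  structure(list(plaque_id = attr(profile, "plaque_id"),
                 covered_deg = covered, uncovered_deg = 360 - covered,
                 coverage = covered / 360),
            class = "CoverageResult")
}

#' Peri-plaque dystrophic-neurite (Lamp1) area by sector class
#'
#' Extends each covered/uncovered angular bin radially to that bin's
#' Lamp1 limit and assigns every Lamp1-positive pixel outside the plaque
#' mask to the bin of its angle from the centroid, radially capped at
#' the bin's outer extent. Areas are summed over covered and uncovered
#' bins and normalized to each class's total degrees. The covered and
#' uncovered areas partition the assigned Lamp1 area exactly. A class
#' with zero degrees gets an `NA` (undefined) per-degree value, not 0.
#'
#' @param proj projected image (as in [build_angular_profile()]).
#' @param profile `AngularProfile` of the plaque.
#' @param plaque `Plaque` object (same plaque).
#' @param lamp1_threshold `"otsu"` or numeric.
#' @return `DystrophyResult`: list with per-class areas (um^2),
#'   per-degree areas (um^2/deg, NA when the class is empty) and
#'   `total_lamp1_um2`.
#' @export
dystrophy_by_sector <- function(proj, profile, plaque,
                                lamp1_threshold = "otsu") {
  px <- proj$pixel_size_um
  lamp1 <- get_channel(proj, "lamp1")
  lamp1_mask <- (lamp1 >= resolve_threshold(lamp1, lamp1_threshold)) &
    !plaque$mask
  dt <- attr(profile, "delta_theta_deg")
  ctr <- attr(profile, "centroid_um")
  idx <- which(lamp1_mask, arr.ind = TRUE)
  cov_area <- unc_area <- 0
  if (nrow(idx) > 0) {
    xs <- (idx[, 2] - 0.5) * px - ctr[1]
    ys <- (idx[, 1] - 0.5) * px - ctr[2]
    theta <- angle_deg(xs, ys)
    r <- sqrt(xs^2 + ys^2)
    bin <- pmin(floor(theta / dt) + 1, nrow(profile))
    ext <- profile$lamp1_outer_extent_um[bin]
    keep <- !is.na(ext) & r <= ext & r > profile$perimeter_radius_um[bin]
    covered_bin <- profile$iba1_at_perimeter[bin]
    a <- px^2
    cov_area <- sum(keep & covered_bin) * a
    unc_area <- sum(keep & !covered_bin) * a
  }
  cov_deg <- dt * sum(profile$iba1_at_perimeter)
  unc_deg <- 360 - cov_deg
  structure(list(
    plaque_id = attr(profile, "plaque_id"),
    lamp1_area_covered_um2 = cov_area,
    lamp1_area_uncovered_um2 = unc_area,
    lamp1_per_deg_covered = if (cov_deg > 0) cov_area / cov_deg else NA_real_,
    lamp1_per_deg_uncovered = if (unc_deg > 0) unc_area / unc_deg else NA_real_,
    covered_deg = cov_deg, uncovered_deg = unc_deg,
    total_lamp1_um2 = cov_area + unc_area),
    class = "DystrophyResult")
}

#' Default plaque-size bins for the coverage-dystrophy correlation
#'
#' Diameter bins `[0, 9)`, `[9, 18)`, `[18, Inf)` um; only the < 9 um
#' edge is anchored by the reported small-plaque effect, the remaining
#' edges are exposed defaults.
#'
#' @return data.frame with `label`, `lo_um`, `hi_um`.
#' @export
default_size_bins <- function() {
  data.frame(label = c("<9um", "9-18um", ">=18um"),
             lo_um = c(0, 9, 18), hi_um = c(9, 18, Inf))
}

#' Correlation between coverage and Lamp1 area, by plaque-size bin
#'
#' Pearson correlation (two-sided p from the t distribution, n - 2 df)
#' between microglial coverage and total Lamp1-positive area within each
#' equivalent-diameter bin. Bins with fewer than 3 plaques, or with
#' zero coverage variance, report `NA` with a reason.
#'
#' @param tab data.frame with columns `coverage`, `total_lamp1_um2`,
#'   `equiv_diameter_um` (one row per plaque), e.g. from
#'   [barrier_table()].
#' @param bins data.frame as [default_size_bins()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame per bin: `label`, `n`, `r`, `p_value`, `reason`.
#' @export
coverage_dystrophy_correlation <- function(tab, bins = default_size_bins(),
                                           method = "pearson") {
  out <- data.frame(label = bins$label, n = 0L, r = NA_real_,
                    p_value = NA_real_, reason = "", stringsAsFactors = FALSE)
  for (b in seq_len(nrow(bins))) {
    sel <- tab$equiv_diameter_um >= bins$lo_um[b] &
      tab$equiv_diameter_um < bins$hi_um[b]
    n <- sum(sel)
    out$n[b] <- n
    if (n < 3) { out$reason[b] <- "fewer than 3 plaques"; next }
    x <- tab$coverage[sel]; y <- tab$total_lamp1_um2[sel]
    if (sd(x) == 0 || sd(y) == 0) { out$reason[b] <- "zero variance"; next }
    ct <- cor.test(x, y, method = method, exact = FALSE)
    out$r[b] <- unname(ct$estimate)
    out$p_value[b] <- ct$p.value
  }
  out
}

#' Paired comparison of dystrophy in covered vs uncovered sectors
#'
#' Across plaques having both sector classes defined, compares
#' per-degree Lamp1 area in covered vs uncovered sectors with a paired
#' two-sided t test.
#'
#' @param results list of `DystrophyResult`, or a data.frame with
#'   `lamp1_per_deg_covered`, `lamp1_per_deg_uncovered`.
#' @return list with group means, sds, `n`, `t`, `p_value` and
#'   `direction` (`"uncovered>covered"` etc.).
#' @export
compare_covered_vs_uncovered <- function(results) {
  tab <- if (is.data.frame(results)) results else
    data.frame(lamp1_per_deg_covered =
                 vapply(results, `[[`, numeric(1), "lamp1_per_deg_covered"),
               lamp1_per_deg_uncovered =
                 vapply(results, `[[`, numeric(1), "lamp1_per_deg_uncovered"))
  ok <- !is.na(tab$lamp1_per_deg_covered) & !is.na(tab$lamp1_per_deg_uncovered)
  if (sum(ok) < 2)
    stop("need at least 2 plaques with both sector classes defined")
  x <- tab$lamp1_per_deg_covered[ok]
  y <- tab$lamp1_per_deg_uncovered[ok]
  if (all(x == y)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(y, x, paired = TRUE)
  }
  list(mean_covered = mean(x), sd_covered = sd(x),
       mean_uncovered = mean(y), sd_uncovered = sd(y),
       n = sum(ok), t = unname(tt$statistic), p_value = tt$p.value,
       direction = if (mean(y) > mean(x)) "uncovered>covered"
                   else if (mean(y) < mean(x)) "covered>uncovered" else "equal")
}

#' Per-plaque coverage + dystrophy summary table
#'
#' Convenience wrapper: for each segmented plaque of a projected field,
#' builds the angular profile, the coverage result and the sector
#' dystrophy result, and returns one row per plaque.
#'
#' @param proj projected `ImageStack`.
#' @param plaques list of `Plaque` objects.
#' @param ... passed to [build_angular_profile()].
#' @return data.frame with coverage, degrees, Lamp1 areas and
#'   per-degree values.
#' @export
barrier_table <- function(proj, plaques, ...) {
  rows <- lapply(plaques, function(p) {
    prof <- build_angular_profile(proj, p, ...)
    cov <- microglia_coverage(prof)
    dys <- dystrophy_by_sector(proj, prof, p)
    data.frame(plaque_id = p$id, equiv_diameter_um = p$equiv_diameter_um,
               coverage = cov$coverage, covered_deg = cov$covered_deg,
               uncovered_deg = cov$uncovered_deg,
               lamp1_area_covered_um2 = dys$lamp1_area_covered_um2,
               lamp1_area_uncovered_um2 = dys$lamp1_area_uncovered_um2,
               lamp1_per_deg_covered = dys$lamp1_per_deg_covered,
               lamp1_per_deg_uncovered = dys$lamp1_per_deg_uncovered,
               total_lamp1_um2 = dys$total_lamp1_um2)
  })
  do.call(rbind, rows)
}
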