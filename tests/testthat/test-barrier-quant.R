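test_that("full and absent envelopment give coverage 1 and 0", {
  full <- sim_one_plaque(seed = 31, intervals = list(c(0, 360)))
  prof <- build_angular_profile(full$proj, full$plaque)
  cov <- microglia_coverage(prof)
  expect_equal(cov$coverage, 1)
  expect_equal(cov$covered_deg + cov$uncovered_deg, 360)
  none <- sim_one_plaque(seed = 32, intervals = list())
  cov0 <- microglia_coverage(build_angular_profile(none$proj, none$plaque))
  expect_equal(cov0$coverage, 0)
})

test_that("no Lamp1 anywhere gives absent extents and zero areas", {
  res <- sim_one_plaque(seed = 33, intervals = list(c(0, 90)))
  prof <- build_angular_profile(res$proj, res$plaque, lamp1_threshold = 0.5)
  expect_true(all(is.na(prof$lamp1_outer_extent_um)))
  dys <- dystrophy_by_sector(res$proj, prof, res$plaque, lamp1_threshold = 0.5)
  expect_equal(dys$total_lamp1_um2, 0)
  expect_equal(dys$lamp1_area_covered_um2, 0)
})

test_that("covered bins match the generator intervals up to edge bins", {
  res <- sim_one_plaque(seed = 34, intervals = list(c(0, 90), c(180, 270)))
  prof <- build_angular_profile(res$proj, res$plaque)
  want <- angle_in_intervals(prof$theta_start_deg + 0.5,
                             list(c(0, 90), c(180, 270)))
  # allow blur-induced flips within 3 degrees of an interval edge
  edges <- c(0, 90, 180, 270)
  d_edge <- sapply(prof$theta_start_deg + 0.5, function(th)
    min(abs(((th - edges) + 180) %% 360 - 180)))
  interior <- d_edge > 3
  expect_true(all(prof$iba1_at_perimeter[interior] == want[interior]))
})

test_that("coverage estimates recover generator truth within 0.05", {
  for (cov_true in c(0.25, 0.75)) {
    res <- sim_one_plaque(seed = 35 + round(100 * cov_true),
                          intervals = list(c(40, 40 + 360 * cov_true)))
    est <- microglia_coverage(build_angular_profile(res$proj, res$plaque))
    expect_equal(est$coverage, cov_true, tolerance = 0.05 / cov_true)
  }
})

test_that("ray-cast profile agrees with the per-pixel angular oracle", {
  # the per-pixel histogram needs several pixels per 1-degree bin at the
  # perimeter, hence a large convex plaque sampled at 0.25 um/px; the
  # centre is kept off the pixel grid (generic position)
  agree <- sapply(c(41, 42, 43), function(s) {
    cfg <- sim_config(field_size_um = c(60, 60), seed = s,
                      pixel_size_um = 0.25)
    ps <- plaque_spec(center_um = c(30.13, 29.88), radius_um = 12,
                      covered_intervals_deg = list(c(20, 150), c(200, 330)),
                      lamp1_outer_radius_um = 12)
    sim <- simulate_histology_stack(cfg, list(ps))
    proj <- project_central_slices(sim$stack)
    plq <- segment_plaques(proj)[[1]]
    iba1 <- get_channel(proj, "iba1")
    thr <- max(iba1) / 2
    prof <- build_angular_profile(proj, plq, iba1_threshold = thr)
    oracle <- angular_histogram_oracle(proj, plq, iba1_threshold = thr)
    ok <- !is.na(oracle)
    mean(prof$iba1_at_perimeter[ok] == oracle[ok])
  })
  expect_true(all(agree >= 0.99))
})

test_that("sector areas partition total Lamp1 exactly and recover density", {
  res <- sim_one_plaque(seed = 51, intervals = list(c(0, 180)),
                        d_cov = 0, d_unc = 0.4)
  prof <- build_angular_profile(res$proj, res$plaque)
  dys <- dystrophy_by_sector(res$proj, prof, res$plaque)
  expect_identical(dys$total_lamp1_um2,
                   dys$lamp1_area_covered_um2 + dys$lamp1_area_uncovered_um2)
  truth <- res$sim$truth
  expect_equal(dys$lamp1_per_deg_uncovered, truth$lamp1_per_deg_uncovered_um2,
               tolerance = 0.10)
  # contamination of the covered sector (blob spill + edge-bin blur) is
  # assessed in aggregate across plaques
  ca <- ua <- cd <- ud <- 0
  for (s in 50:55) {
    r2 <- sim_one_plaque(seed = s, intervals = list(c(0, 180)),
                         d_cov = 0, d_unc = 0.4)
    p2 <- build_angular_profile(r2$proj, r2$plaque)
    d2 <- dystrophy_by_sector(r2$proj, p2, r2$plaque)
    ca <- ca + d2$lamp1_area_covered_um2
    ua <- ua + d2$lamp1_area_uncovered_um2
    cd <- cd + d2$covered_deg
    ud <- ud + d2$uncovered_deg
  }
  expect_lt((ca / cd) / (ua / ud), 0.1)
})

test_that("uniform halos give matching per-degree density in both sectors", {
  ratios <- sapply(c(52, 53, 54), function(s) {
    res <- sim_one_plaque(seed = s, intervals = list(c(10, 190)),
                          d_cov = 0.4, d_unc = 0.4)
    prof <- build_angular_profile(res$proj, res$plaque)
    dys <- dystrophy_by_sector(res$proj, prof, res$plaque)
    dys$lamp1_per_deg_covered / dys$lamp1_per_deg_uncovered
  })
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("an empty sector class reports NA per-degree, not zero", {
  res <- sim_one_plaque(seed = 55, intervals = list(c(0, 360)),
                        d_cov = 0.3, d_unc = 0.3)
  prof <- build_angular_profile(res$proj, res$plaque)
  dys <- dystrophy_by_sector(res$proj, prof, res$plaque)
  expect_equal(dys$uncovered_deg, 0)
  expect_true(is.na(dys$lamp1_per_deg_uncovered))
  expect_false(is.na(dys$lamp1_per_deg_covered))
})

test_that("rotating the field by 90 degrees leaves coverage and dystrophy", {
  res <- sim_one_plaque(seed = 56, intervals = list(c(30, 170)),
                        d_cov = 0.1, d_unc = 0.45)
  prof <- build_angular_profile(res$proj, res$plaque)
  cov <- microglia_coverage(prof)
  dys <- dystrophy_by_sector(res$proj, prof, res$plaque)
  projR <- rotate_proj(res$proj)
  plR <- segment_plaques(projR)
  expect_length(plR, 1)
  profR <- build_angular_profile(projR, plR[[1]])
  covR <- microglia_coverage(profR)
  dysR <- dystrophy_by_sector(projR, profR, plR[[1]])
  expect_equal(covR$coverage, cov$coverage, tolerance = 0.01)
  expect_equal(dysR$lamp1_per_deg_uncovered, dys$lamp1_per_deg_uncovered,
               tolerance = 0.01)
  expect_equal(dysR$total_lamp1_um2, dys$total_lamp1_um2, tolerance = 0.01)
})

test_that("correlation handles exact anticorrelation and degenerate bins", {
  tab <- data.frame(coverage = seq(0.1, 0.9, length.out = 8),
                    total_lamp1_um2 = 100 - 90 * seq(0.1, 0.9,
                                                     length.out = 8),
                    equiv_diameter_um = rep(5, 8))
  res <- coverage_dystrophy_correlation(tab)
  expect_equal(res$r[res$label == "<9um"], -1)
  expect_lt(res$p_value[res$label == "<9um"], 1e-6)
  expect_equal(res$reason[res$label == "9-18um"], "fewer than 3 plaques")
  tab$coverage <- 0.5
  res2 <- coverage_dystrophy_correlation(tab)
  expect_true(is.na(res2$r[1]))
  expect_equal(res2$reason[1], "zero variance")
})

test_that("covered-vs-uncovered comparison handles ties and direction", {
  same <- data.frame(lamp1_per_deg_covered = c(1, 2, 3),
                     lamp1_per_deg_uncovered = c(1, 2, 3))
  res <- compare_covered_vs_uncovered(same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  set.seed(6)
  n <- 40
  biased <- data.frame(lamp1_per_deg_covered = rnorm(n, 0.3, 0.05),
                       lamp1_per_deg_uncovered = rnorm(n, 1.2, 0.2))
  res2 <- compare_covered_vs_uncovered(biased)
  expect_equal(res2$direction, "uncovered>covered")
  expect_lt(res2$p_value, 0.05)
  expect_error(compare_covered_vs_uncovered(
    data.frame(lamp1_per_deg_covered = c(1, NA),
               lamp1_per_deg_uncovered = c(NA, 2))), "at least 2")
})
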