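test_that("ground-truth coverage equals summed interval lengths over 360", {
  # interval-arithmetic oracle: sum of (end - start) / 360
  cases <- list(
    list(iv = list(c(0, 360)), want = 1.0),
    list(iv = list(), want = 0.0),
    list(iv = list(c(0, 90), c(180, 270)), want = 0.5),
    list(iv = list(c(10, 25), c(100, 190), c(300, 351)), want = NA)
  )
  cases[[4]]$want <- sum(c(25 - 10, 190 - 100, 351 - 300)) / 360
  cfg <- sim_config(seed = 1, noise_sd = 0, psf_sigma_um = 0)
  for (cs in cases) {
    ps <- plaque_spec(c(40, 40), 8, covered_intervals_deg = cs$iv,
                      lamp1_outer_radius_um = 15)
    sim <- simulate_histology_stack(cfg, list(ps))
    expect_equal(sim$truth$coverage, cs$want)
  }
})

test_that("simulation is deterministic given config and seed", {
  cfg <- sim_config(seed = 7)
  ps <- plaque_spec(c(40, 40), 8, list(c(30, 200)), 0.2, 0.4, 18, 2, 4)
  s1 <- simulate_histology_stack(cfg, list(ps))
  s2 <- simulate_histology_stack(cfg, list(ps))
  expect_identical(s1, s2)
  m1 <- simulate_neuron_swc(3, 8, seed = 5)
  m2 <- simulate_neuron_swc(3, 8, seed = 5)
  expect_identical(m1, m2)
  p1 <- simulate_phagocytosis_image(20, 0.5, seed = 9)
  p2 <- simulate_phagocytosis_image(20, 0.5, seed = 9)
  expect_identical(p1, p2)
  c1 <- simulate_count_matrix(count_sim_spec(seed = 11))
  c2 <- simulate_count_matrix(count_sim_spec(seed = 11))
  expect_identical(c1, c2)
})

test_that("plaques that do not fit in the field are rejected", {
  cfg <- sim_config(field_size_um = c(50, 50), seed = 1)
  expect_error(
    simulate_histology_stack(cfg, list(
      plaque_spec(c(45, 25), 8, lamp1_outer_radius_um = 20))),
    "does not fit")
})

test_that("overlapping covered intervals are rejected", {
  expect_error(plaque_spec(c(40, 40), 8,
                           covered_intervals_deg = list(c(0, 90), c(80, 120))),
               "disjoint")
})

test_that("noiseless Lamp1 render matches spec density per degree within 10%", {
  cfg <- sim_config(field_size_um = c(80, 80), seed = 3, noise_sd = 0,
                    psf_sigma_um = 0)
  ps <- plaque_spec(c(40, 40), 8, covered_intervals_deg = list(c(0, 180)),
                    lamp1_density_covered = 0.4, lamp1_density_uncovered = 0.4,
                    lamp1_outer_radius_um = 20)
  sim <- simulate_histology_stack(cfg, list(ps))
  lam <- sim$stack$pixels[, , 3, cfg$channel_roles[["lamp1"]]] > 0.5
  px <- cfg$pixel_size_um
  idx <- which(lam, arr.ind = TRUE)
  r <- sqrt(((idx[, 2] - 0.5) * px - 40)^2 + ((idx[, 1] - 0.5) * px - 40)^2)
  in_ring <- r > 8 & r <= 20
  measured_per_deg <- sum(in_ring) * px^2 / 360
  expect_lt(abs(measured_per_deg - sim$truth$lamp1_per_deg_covered_um2) /
              sim$truth$lamp1_per_deg_covered_um2, 0.10)
})

test_that("phagocytosis generator labels exactly the requested fraction", {
  sim0 <- simulate_phagocytosis_image(20, 0, seed = 1)
  expect_equal(sum(sim0$truth$positive), 0)
  # zero FITC inside every cell (noise only)
  expect_lt(max(get_channel(sim0$stack, "fitc")), 0.1)
  sim1 <- simulate_phagocytosis_image(50, 1.0, seed = 2)
  expect_equal(sum(sim1$truth$positive), 50)
  sim4 <- simulate_phagocytosis_image(100, 0.4, seed = 3)
  expect_equal(sum(sim4$truth$positive), 40)
})

test_that("cell packing failure raises an informative error", {
  expect_error(simulate_phagocytosis_image(500, 0.5, seed = 1,
                                           field_size_um = 80,
                                           max_tries = 20),
               "non-overlapping")
})

test_that("count simulator matches cohort shape and DE contract", {
  sim <- simulate_count_matrix(count_sim_spec(n_case = 11, n_control = 14,
                                              seed = 4))
  expect_equal(ncol(sim$counts), 25)
  expect_equal(as.vector(table(sim$groups)), c(11, 14))
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  sim0 <- simulate_count_matrix(count_sim_spec(frac_de = 0, seed = 5))
  expect_equal(sum(sim0$truth$is_de), 0)
})

test_that("dispersion-0 counts are Poisson-like and recover the fold change", {
  # Monte-Carlo oracle: with >= 1000 DE features at |log2FC| = 1, the
  # mean |log2 mean ratio| converges to 1 and Poisson variance ~ mean
  spec <- count_sim_spec(n_case = 30, n_control = 30, n_mirna = 2000,
                         dispersion = 0, mean_log_range = c(8, 10),
                         frac_de = 1, log2fc_de = 1, seed = 6)
  sim <- simulate_count_matrix(spec)
  mc <- rowMeans(sim$counts[, sim$groups == "case"])
  mn <- rowMeans(sim$counts[, sim$groups == "control"])
  expect_equal(mean(abs(log2(mc / mn))), 1, tolerance = 0.02)
  # Poisson: index of dispersion near 1 for null features
  sim0 <- simulate_count_matrix(count_sim_spec(n_case = 50, n_control = 50,
                                               n_mirna = 500, dispersion = 0,
                                               mean_log_range = c(8, 8),
                                               frac_de = 0, seed = 7))
  iod <- apply(sim0$counts, 1, var) / rowMeans(sim0$counts)
  expect_equal(mean(iod), 1, tolerance = 0.05)
})

test_that("neuron generator emits a valid rooted tree with soma at origin", {
  m <- simulate_neuron_swc(3, 8, seed = 2)
  expect_s3_class(m, "NeuronMorphology")
  expect_equal(sum(m$parent < 0), 1)
  soma <- m[m$parent < 0, ]
  expect_equal(c(soma$x, soma$y, soma$z), c(0, 0, 0))
  # binary tree node count: 1 + n_primary * (2^(depth+1) - 1)
  expect_equal(nrow(m), 1 + 3 * (2^4 - 1))
})
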