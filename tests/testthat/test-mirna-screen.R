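cohort_groups <- rep(c("case", "control"), c(11, 14))

test_that("expression filter applies the strict-majority rule per group", {
  # hand-computed keep/drop decisions on a toy matrix (11 + 14 samples)
  mk <- function(case_hits, ctrl_hits)
    c(rep(10, case_hits), rep(0, 11 - case_hits),
      rep(10, ctrl_hits), rep(0, 14 - ctrl_hits))
  counts <- rbind(
    all_high  = rep(50, 25),        # kept
    all_zero  = rep(0, 25),         # dropped
    just_in   = mk(6, 8),           # 6 > 5.5 and 8 > 7 -> kept
    case_low  = mk(5, 14),          # 5 < 5.5 -> dropped
    ctrl_edge = mk(11, 7),          # 7 = 7 not > 7 -> dropped
    value_low = c(rep(9, 25)))      # 9 < 10 everywhere -> dropped
  kept <- rownames(filter_by_expression(counts, cohort_groups))
  expect_setequal(kept, c("all_high", "just_in"))
  expect_warning(filter_by_expression(counts[c("all_zero", "value_low"), ],
                                      cohort_groups), "no features")
})

test_that("TMM factors are 1 for identical and depth-scaled libraries", {
  set.seed(21)
  base <- rnbinom(400, mu = 200, size = 5) + 1
  ident <- cbind(a = base, b = base, c = base)
  expect_equal(tmm_normalize(ident)$factors, rep(1, 3))
  depth <- cbind(a = base, b = base * 3)
  expect_equal(tmm_normalize(depth)$factors, c(1, 1), tolerance = 1e-6)
})

test_that("TMM matches the direct-formula oracle and edgeR", {
  sim <- simulate_count_matrix(count_sim_spec(
    n_mirna = 300, frac_de = 0.2, log2fc_de = 3, lib_size_factor_sd = 0.3,
    seed = 22))
  nf <- tmm_normalize(sim$counts)
  # geometric mean of factors is 1
  expect_equal(exp(mean(log(nf$factors))), 1, tolerance = 1e-12)
  # direct transcription of the trimmed weighted-mean formula
  ref <- nf$ref_sample
  raw <- vapply(seq_len(ncol(sim$counts)), function(j)
    tmm_direct_oracle(sim$counts[, j], sim$counts[, ref]), numeric(1))
  expect_equal(nf$factors, raw / exp(mean(log(raw))), tolerance = 1e-10)
  # independent library cross-check
  f_edger <- edgeR::calcNormFactors(edgeR::DGEList(sim$counts),
                                    method = "TMM")$samples$norm.factors
  expect_equal(nf$factors, f_edger, tolerance = 1e-10)
})

test_that("TMM is near-invariant to scaling one library by a constant", {
  # the M-values and trimming are scale-invariant exactly; the precision
  # weights are not (they depend on absolute counts), leaving a small
  # residual shift of the weighted mean that reference implementations
  # share. Both the approximate invariance and exact agreement with the
  # independent implementation on the scaled matrix are checked.
  sim <- simulate_count_matrix(count_sim_spec(n_mirna = 200, seed = 23))
  nf1 <- tmm_normalize(sim$counts)
  scaled <- sim$counts
  scaled[, 4] <- scaled[, 4] * 5
  nf2 <- tmm_normalize(scaled)
  expect_equal(nf1$factors, nf2$factors, tolerance = 1e-2)
  f_edger <- edgeR::calcNormFactors(edgeR::DGEList(scaled),
                                    method = "TMM")$samples$norm.factors
  expect_equal(nf2$factors, f_edger, tolerance = 1e-10)
})

test_that("BH adjustment matches hand computation", {
  expect_equal(bh_adjust(0.04), 0.04)
  # step-up: p_(i) * n / i, then cumulative min from the top
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.001, 0.01, 0.9)),
               c(0.003, 0.015, 0.9))
})

test_that("null counts give calibrated type-I error and empty DEM set", {
  sim <- simulate_count_matrix(count_sim_spec(n_mirna = 2000, frac_de = 0,
                                              dispersion = 0.1, seed = 24))
  de <- de_test(sim$counts, sim$groups)
  alpha <- mean(de$p_value < 0.05)
  expect_gte(alpha, 0.03)
  expect_lte(alpha, 0.07)
  expect_lte(mean(bh_adjust(de$p_value) < 0.05), 0.05 + 2 * sqrt(0.05 / 2000))
})

test_that("true two-fold changes are detected with high power", {
  sim <- simulate_count_matrix(count_sim_spec(n_mirna = 300, frac_de = 0.1,
                                              log2fc_de = 2, dispersion = 0.1,
                                              seed = 25))
  dem <- select_dems(de_test(sim$counts, sim$groups))
  sens <- mean(dem$status[sim$truth$is_de] != "ns")
  expect_gte(sens, 0.8)
  called <- dem$status != "ns"
  fdp <- if (any(called)) mean(!sim$truth$is_de[called]) else 0
  expect_lte(fdp, 0.1)
  # recovered signs match the simulated directions
  de_idx <- which(sim$truth$is_de & called)
  expect_true(all(sign(dem$log2fc[de_idx]) ==
                    sign(sim$truth$true_log2fc[de_idx])))
})

test_that("DEM status respects both the fold-change and FDR cutoffs", {
  rec <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2fc = c(0.9, 1.5, -2.1, 3.0),
                    p_value = c(0.0001, 0.01, 0.002, 0.4),
                    fdr = c(0.001, 0.04, 0.01, 0.6))
  out <- select_dems(rec)
  expect_equal(out$status, c("ns", "up", "down", "ns"))
  expect_equal(attr(out, "n_up"), 1)
  expect_equal(attr(out, "n_down"), 1)
})

test_that("all-zero features get p = 1", {
  sim <- simulate_count_matrix(count_sim_spec(n_mirna = 50, seed = 26))
  counts <- rbind(sim$counts, zero = rep(0L, 25))
  de <- de_test(counts, sim$groups)
  expect_equal(de$p_value[de$feature_id == "zero"], 1)
})

test_that("the 95%-CI signature rule flags the engineered feature only", {
  set.seed(27)
  expr <- matrix(rnorm(6 * 25, mean = 8, sd = 1), 6, 25,
                 dimnames = list(paste0("m", 1:6), NULL))
  expr[4, 1:11] <- expr[4, 1:11] + 12   # every case far outside
  expr[5, 1] <- expr[5, 1] + 12         # only one case outside
  sig <- ci_signature(expr, cohort_groups)
  expect_equal(sig$feature_id[sig$flagged], "m4")
  expect_equal(sig$n_cases_outside[4], 11)
  # direct interval arithmetic for one feature
  ctrl <- expr[1, 12:25]
  half <- qt(0.975, 13) * sd(ctrl) * sqrt(1 + 1 / 14)
  expect_equal(sig$ci_lo[1], mean(ctrl) - half)
  expect_equal(sig$ci_hi[1], mean(ctrl) + half)
  # mean-CI variant is strictly narrower
  sig_m <- ci_signature(expr, cohort_groups, type = "mean")
  expect_true(all(sig_m$ci_hi - sig_m$ci_lo <
                    sig$ci_hi - sig$ci_lo))
  # cases equal to the control mean are never flagged
  expr2 <- expr
  expr2[4, 1:11] <- mean(expr2[4, 12:25])
  expect_false(ci_signature(expr2, cohort_groups)$flagged[4])
})

test_that("exclusive-to-cases detection uses raw counts", {
  counts <- rbind(excl = c(rep(3, 11), rep(0, 14)),
                  both = rep(5, 25),
                  none = rep(0, 25))
  expr <- log2(counts + 0.5)
  sig <- ci_signature(expr, cohort_groups, counts = counts)
  expect_equal(sig$exclusive_to_cases, c(TRUE, FALSE, FALSE))
})

test_that("PCA separates constructed clusters with deterministic signs", {
  set.seed(28)
  expr <- matrix(rnorm(30 * 25, 5, 0.1), 30, 25)
  expr[1, 1:11] <- expr[1, 1:11] + 5
  pc <- pca_scores(expr)
  s <- pc$scores[, 1]
  expect_true(all(sign(s[1:11]) == sign(s[1])) &&
                all(sign(s[12:25]) == -sign(s[1])))
  # duplicate samples get identical scores
  expr2 <- cbind(expr, expr[, 1])
  pc2 <- pca_scores(expr2)
  expect_equal(pc2$scores[26, ], pc2$scores[1, ], ignore_attr = TRUE)
  # variance explained sums to 1 over full rank
  expect_equal(sum(pc$variance_explained), 1)
  expect_error(pca_scores(matrix(3, 5, 8)), "constant")
})

test_that("ddCt relative expression matches hand arithmetic", {
  expect_equal(ddct_relative_expression(20, 15, 20, 15), 1)
  expect_equal(ddct_relative_expression(21, 15, 20, 15), 0.5)
  expect_equal(ddct_relative_expression(24, 18, 26, 18), 4)
  expect_error(ddct_relative_expression(NA, 1, 1, 1), "finite")
})

test_that("the screen is deterministic and order-invariant", {
  sim <- simulate_count_matrix(count_sim_spec(n_mirna = 120, frac_de = 0.1,
                                              seed = 29))
  d1 <- select_dems(de_test(sim$counts, sim$groups))
  d2 <- select_dems(de_test(sim$counts, sim$groups))
  expect_identical(d1, d2)
  perm <- sample(nrow(sim$counts))
  d3 <- select_dems(de_test(sim$counts[perm, ], sim$groups))
  expect_equal(d3[match(d1$feature_id, d3$feature_id), "fdr"], d1$fdr,
               ignore_attr = TRUE)
})
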