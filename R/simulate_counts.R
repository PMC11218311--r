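#' Specification for a synthetic miRNA count matrix
#'
#' Negative-binomial counts for a case/control cohort. Defaults emulate
#' the plasma screening cohort of 11 cases vs 14 controls with a plasma
#' small-RNA-like abundance range and moderate biological dispersion.
#'
#' @param n_case,n_control sample counts per group.
#' @param n_mirna number of features.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2);
#'   0 gives Poisson counts.
#' @param mean_log_range length-2 range of log2 mean abundance from
#'   which feature means are drawn uniformly.
#' @param frac_de fraction of features differentially expressed.
#' @param log2fc_de absolute log2 fold change of DE features (signs
#'   alternate so both directions occur).
#' @param lib_size_factor_sd sd of lognormal library-size factors
#'   (0 for equal depths).
#' @param seed integer seed.
#' @return object of class `CountSimSpec`.
#' @export
count_sim_spec <- function(n_case = 11, n_control = 14, n_mirna = 200,
                           dispersion = 0.1, mean_log_range = c(4, 12),
                           frac_de = 0.1, log2fc_de = 2,
                           lib_size_factor_sd = 0, seed = 1L) {
  stopifnot(frac_de >= 0, frac_de <= 1, dispersion >= 0,
            n_case >= 1, n_control >= 1)
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_mirna = as.integer(n_mirna), dispersion = dispersion,
                 mean_log_range = mean_log_range, frac_de = frac_de,
                 log2fc_de = log2fc_de,
                 lib_size_factor_sd = lib_size_factor_sd,
                 seed = as.integer(seed)),
            class = "CountSimSpec")
}

#' Simulate an miRNA count matrix with known differential expression
#'
#' Feature means are lognormal over `mean_log_range`; the first
#' `round(frac_de * n_mirna)` features are differentially expressed with
#' log2 fold change `+/- log2fc_de` (alternating sign) applied to the
#' case group; counts are negative binomial (Poisson when
#' `dispersion = 0`), scaled per sample by a library-size factor.
#'
#' @param spec [count_sim_spec()].
#' @return list with `counts` (feature x sample integer matrix, named),
#'   `groups` (factor `case`/`control` per sample) and `truth`
#'   (data.frame: feature, `is_de`, `true_log2fc`).
#' @export
simulate_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "CountSimSpec"))
  set.seed(spec$seed)
  n_s <- spec$n_case + spec$n_control
  groups <- factor(rep(c("case", "control"), c(spec$n_case, spec$n_control)),
                   levels = c("case", "control"))
  mu0 <- 2^runif(spec$n_mirna, spec$mean_log_range[1], spec$mean_log_range[2])
  n_de <- round(spec$frac_de * spec$n_mirna)
  lfc <- numeric(spec$n_mirna)
  if (n_de > 0)
    lfc[seq_len(n_de)] <- rep(c(1, -1), length.out = n_de) * spec$log2fc_de
  lib <- if (spec$lib_size_factor_sd > 0)
    exp(rnorm(n_s, 0, spec$lib_size_factor_sd)) else rep(1, n_s)
  mu <- outer(mu0, lib)  # feature x sample
  case_cols <- which(groups == "case")
  mu[, case_cols] <- mu[, case_cols] * 2^lfc
  counts <- if (spec$dispersion > 0)
    matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
           nrow = spec$n_mirna)
  else
    matrix(rpois(length(mu), lambda = mu), nrow = spec$n_mirna)
  rownames(counts) <- sprintf("miR-%04d", seq_len(spec$n_mirna))
  colnames(counts) <- paste0(ifelse(groups == "case", "AD_", "CN_"),
                             seq_len(n_s))
  truth <- data.frame(feature_id = rownames(counts),
                      is_de = lfc != 0, true_log2fc = lfc)
  list(counts = counts, groups = groups, truth = truth)
}
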