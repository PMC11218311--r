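#' Filter an miRNA count matrix by expression level
#'
#' Keeps features whose count is at least `min_count` in strictly more
#' than `min_frac` of the samples within *each* group (both groups must
#' satisfy the rule). With the default 10 / 0.5 this is the
#' strict-majority low-expression filter used for small plasma cohorts.
#' Feature order is preserved.
#'
#' @param counts feature x sample nonnegative integer matrix.
#' @param groups factor/character vector of group labels per sample
#'   (exactly two groups).
#' @param min_count minimum count.
#' @param min_frac fraction of samples that must exceed it (strict).
#' @return filtered count matrix (warns when empty).
#' @export
filter_by_expression <- function(counts, groups, min_count = 10,
                                 min_frac = 0.5) {
  groups <- as.factor(groups)
  stopifnot(nlevels(droplevels(groups)) == 2, ncol(counts) == length(groups))
  keep <- rep(TRUE, nrow(counts))
  for (g in levels(droplevels(groups))) {
    sel <- groups == g
    frac <- rowMeans(counts[, sel, drop = FALSE] >= min_count)
    keep <- keep & (frac > min_frac)
  }
  if (!any(keep)) warning("no features pass the expression filter")
  counts[keep, , drop = FALSE]
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes, for every sample against a reference sample, the weighted
#' mean of per-feature log2 ratios (M-values) after doubly trimming the
#' most extreme 30% of M-values and 5% of average log abundances
#' (A-values) from each tail, with inverse-asymptotic-variance precision
#' weights. The reference is the sample whose upper-quartile count
#' fraction is closest to the mean upper quartile. Factors are rescaled
#' so their geometric mean is 1; effective library sizes are
#' `colSums(counts) * factor`. A sample sharing no co-expressed feature
#' with the reference gets factor 1 with a warning.
#'
#' @param counts feature x sample count matrix; every sample must have
#'   positive total counts.
#' @param trim_m total trim fraction applied to each tail of the
#'   M-values (0.30).
#' @param trim_a trim fraction for each tail of the A-values (0.05).
#' @return `NormFactors`: list with `factors` (per sample, geometric
#'   mean 1), `effective_lib_sizes`, `ref_sample`.
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(ncol(counts) >= 2)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample must have positive total counts")
  uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    trim_m, trim_a), numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = f, effective_lib_sizes = lib * f,
                 ref_sample = ref),
            class = "NormFactors")
}

# One sample's TMM factor against the reference (2^ weighted trimmed
# mean of M). Mirrors the standard doubly-trimmed weighted mean: keep
# features whose M-rank and A-rank both avoid the trimmed tails.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) {
    warning("sample shares no co-expressed features with the reference; ",
            "factor set to 1")
    return(1)
  }
  o <- obs[pos] / n_obs
  r <- ref[pos] / n_ref
  M <- log2(o / r)
  A <- (log2(o) + log2(r)) / 2
  w <- (n_obs - obs[pos]) / (n_obs * obs[pos]) +
    (n_ref - ref[pos]) / (n_ref * ref[pos])
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM &
    rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  f <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(f)) return(1)
  2^f
}

#' Counts per million on TMM-effective library sizes
#'
#' @param counts feature x sample matrix.
#' @param nf `NormFactors` from [tmm_normalize()]; `NULL` uses raw
#'   library sizes.
#' @param prior_count pseudo-count added before scaling (on the CPM
#'   scale after scaling when `log = TRUE`).
#' @param log return log2 CPM.
#' @return matrix of (log2) CPM values.
#' @export
cpm_matrix <- function(counts, nf = NULL, prior_count = 0.5, log = FALSE) {
  lib <- if (is.null(nf)) colSums(counts) else nf$effective_lib_sizes
  out <- sweep(counts, 2, lib / 1e6, `/`)
  if (log) log2(out + prior_count) else out
}

#' Transcripts-per-million style depth-referenced expression
#'
#' For miRNA counts (uniform feature length) this is counts scaled to a
#' common depth of one million per sample on TMM-effective library
#' sizes; emitted for reporting alongside the CPM used for testing.
#'
#' @inheritParams cpm_matrix
#' @return matrix.
#' @export
tpm_matrix <- function(counts, nf = NULL) cpm_matrix(counts, nf)

#' Negative-binomial exact-style differential-expression test
#'
#' Per feature, an exact-style two-sided test of case vs control counts,
#' conditional on the feature's total: counts are scaled to a common
#' effective library size (TMM-effective sizes to their geometric mean,
#' rounded), group sums `zA`, `zB` are modelled as NB with a common
#' dispersion (sum of n iid NB(mu, phi) is NB(n mu, phi / n)), and the
#' two-sided p-value is the total conditional probability of outcomes no
#' more likely than the observed split. The common dispersion defaults
#' to a pooled method-of-moments estimate across features. The log2
#' fold change is the ratio of group mean TMM-CPM with pseudo-count 0.5.
#'
#' @param counts feature x sample matrix (already expression-filtered).
#' @param groups two-level factor; the first level is the "case" whose
#'   positive log2FC means higher expression.
#' @param nf `NormFactors`; computed internally when `NULL`.
#' @param dispersion common NB dispersion; `NULL` estimates it by
#'   pooled method of moments ([estimate_common_dispersion()]).
#' @return data.frame `DEMRecord`s: `feature_id`, `log2fc`, `p_value`
#'   (no FDR yet; see [bh_adjust()], [select_dems()]), with the
#'   dispersion used and the test name in attributes.
#' @export
de_test <- function(counts, groups, nf = NULL, dispersion = NULL) {
  groups <- as.factor(groups)
  stopifnot(nlevels(droplevels(groups)) == 2)
  lv <- levels(droplevels(groups))
  if (is.null(nf)) nf <- tmm_normalize(counts)
  eff <- nf$effective_lib_sizes
  common <- exp(mean(log(eff)))
  pseudo <- sweep(counts, 2, common / eff, `*`)
  if (is.null(dispersion)) dispersion <- estimate_common_dispersion(pseudo,
                                                                   groups)
  a_cols <- groups == lv[1]; b_cols <- groups == lv[2]
  nA <- sum(a_cols); nB <- sum(b_cols)
  zA <- round(rowSums(pseudo[, a_cols, drop = FALSE]))
  zB <- round(rowSums(pseudo[, b_cols, drop = FALSE]))
  p <- vapply(seq_len(nrow(counts)), function(i)
    nb_exact_pvalue(zA[i], zB[i], nA, nB, dispersion), numeric(1))
  cpm <- cpm_matrix(counts, nf)
  mA <- rowMeans(cpm[, a_cols, drop = FALSE])
  mB <- rowMeans(cpm[, b_cols, drop = FALSE])
  out <- data.frame(feature_id = if (is.null(rownames(counts)))
    as.character(seq_len(nrow(counts))) else rownames(counts),
    log2fc = log2(mA + 0.5) - log2(mB + 0.5),
    p_value = p, stringsAsFactors = FALSE)
  attr(out, "dispersion") <- dispersion
  attr(out, "test") <- "NB exact-style conditional test, common dispersion"
  out
}

#' Pooled method-of-moments common NB dispersion
#'
#' Per feature and group, dispersion solves
#' `var = mu + phi mu^2`; per-feature estimates `(s^2 - m) / m^2` are
#' pooled (library-size-equalized counts, both groups) by a weighted
#' mean with weights proportional to the group df, then floored at 0.
#'
#' @param pseudo feature x sample matrix on a common library size.
#' @param groups two-level factor.
#' @return scalar dispersion >= 0.
#' @export
estimate_common_dispersion <- function(pseudo, groups) {
  groups <- droplevels(as.factor(groups))
  num <- den <- 0
  for (g in levels(groups)) {
    x <- pseudo[, groups == g, drop = FALSE]
    n <- ncol(x)
    if (n < 2) next
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    ok <- m > 0
    phi <- (v[ok] - m[ok]) / m[ok]^2
    num <- num + sum(phi) * (n - 1)
    den <- den + sum(ok) * (n - 1)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

# Exact-style conditional two-sided p-value for the split (zA, zB) of
# s = zA + zB between groups of sizes nA, nB under a common NB model.
# Probabilities are evaluated on a window of k covering all but ~1e-12
# of the conditional mass and renormalized.
nb_exact_pvalue <- function(zA, zB, nA, nB, dispersion) {
  s <- zA + zB
  if (s == 0) return(1)
  mu <- s / (nA + nB)
  if (dispersion <= 0) {
    # Poisson limit: conditional law is Binomial(s, nA/(nA+nB))
    pk <- stats::dbinom(0:s, s, nA / (nA + nB))
    p_obs <- pk[zA + 1]
    return(min(1, sum(pk[pk <= p_obs * (1 + 1e-12)])))
  }
  sizeA <- nA / dispersion; sizeB <- nB / dispersion
  muA <- nA * mu; muB <- nB * mu
  # window around the conditional mode capturing all but ~1e-15 of the
  # conditional mass; the conditional sd is bounded by the harmonic
  # combination of the two marginal variances
  vA <- muA + muA^2 / sizeA
  vB <- muB + muB^2 / sizeB
  sd_c <- sqrt(vA * vB / (vA + vB))
  kc <- s * nA / (nA + nB)
  lo <- max(0, min(zA, floor(kc - 8 * sd_c - 50)))
  hi <- min(s, max(zA, ceiling(kc + 8 * sd_c + 50)))
  ks <- lo:hi
  logp <- dnbinom(ks, size = sizeA, mu = muA, log = TRUE) +
    dnbinom(s - ks, size = sizeB, mu = muB, log = TRUE)
  pk <- exp(logp - max(logp))
  p_obs <- pk[match(zA, ks)]
  min(1, sum(pk[pk <= p_obs * (1 + 1e-12)]) / sum(pk))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement, invariant to feature
#' order (delegates to `stats::p.adjust(method = "BH")`).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of FDR-adjusted values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Select differentially expressed miRNAs
#'
#' Adds FDR (when absent) and a status column: `up` / `down` when
#' `|log2fc| > log2fc_cut` and `fdr < fdr_cut`, `ns` otherwise.
#'
#' @param records data.frame from [de_test()] (columns `feature_id`,
#'   `log2fc`, `p_value`, optionally `fdr`).
#' @param log2fc_cut absolute log2-fold-change cutoff (1 = two-fold).
#' @param fdr_cut FDR cutoff.
#' @return the table with `fdr` and `status`, plus `n_up` / `n_down`
#'   attributes.
#' @export
select_dems <- function(records, log2fc_cut = 1, fdr_cut = 0.05) {
  if (!"fdr" %in% names(records)) records$fdr <- bh_adjust(records$p_value)
  records$status <- "ns"
  de <- abs(records$log2fc) > log2fc_cut & records$fdr < fdr_cut
  records$status[de & records$log2fc > 0] <- "up"
  records$status[de & records$log2fc < 0] <- "down"
  attr(records, "n_up") <- sum(records$status == "up")
  attr(records, "n_down") <- sum(records$status == "down")
  records
}

#' Control-interval signature rule
#'
#' For each feature, builds a 95% interval from the control samples and
#' flags the feature when *every* case sample falls outside it. The
#' default interval is prediction-style,
#' `mean +/- t(0.975, n-1) * sd * sqrt(1 + 1/n)` (the rule is applied
#' to individual case values); `type = "mean"` gives the narrower CI of
#' the mean, `mean +/- t * sd / sqrt(n)`. Zero control variance yields
#' the degenerate interval `[mean, mean]`: any case value different
#' from the control mean then counts as outside. When raw `counts` are
#' supplied, features detected (count > 0) in at least one case and in
#' no control are additionally marked `exclusive_to_cases`.
#'
#' @param expr feature x sample expression matrix (e.g. log2 TMM-CPM).
#' @param groups two-level factor; first level = cases.
#' @param level interval level (0.95).
#' @param type `"prediction"` (default) or `"mean"`.
#' @param counts optional raw count matrix (same rows/columns) for the
#'   exclusivity call.
#' @return data.frame `SignatureRecord`s: `feature_id`, `ci_lo`,
#'   `ci_hi`, `n_cases_outside`, `flagged`, `exclusive_to_cases`.
#' @export
ci_signature <- function(expr, groups, level = 0.95,
                         type = c("prediction", "mean"), counts = NULL) {
  type <- match.arg(type)
  groups <- as.factor(groups)
  lv <- levels(droplevels(groups))
  case <- groups == lv[1]; ctrl <- groups == lv[2]
  n_ctrl <- sum(ctrl); n_case <- sum(case)
  if (n_ctrl < 3) stop("need at least 3 control samples")
  tq <- qt(1 - (1 - level) / 2, df = n_ctrl - 1)
  m <- rowMeans(expr[, ctrl, drop = FALSE])
  s <- apply(expr[, ctrl, drop = FALSE], 1, sd)
  half <- if (type == "prediction") tq * s * sqrt(1 + 1 / n_ctrl)
          else tq * s / sqrt(n_ctrl)
  lo <- m - half; hi <- m + half
  cx <- expr[, case, drop = FALSE]
  outside <- (cx < lo) | (cx > hi)
  n_out <- rowSums(outside)
  excl <- if (!is.null(counts)) {
    rowSums(counts[, ctrl, drop = FALSE] > 0) == 0 &
      rowSums(counts[, case, drop = FALSE] > 0) >= 1
  } else rep(NA, nrow(expr))
  data.frame(feature_id = if (is.null(rownames(expr)))
    as.character(seq_len(nrow(expr))) else rownames(expr),
    ci_lo = lo, ci_hi = hi, n_cases_outside = n_out,
    flagged = n_out == n_case, exclusive_to_cases = excl,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' PCA scores of an expression matrix
#'
#' Centered (optionally unit-scaled) PCA by singular-value
#' decomposition (`prcomp`) of the sample x feature matrix, with a fixed
#' sign convention: the loading of largest magnitude on each component
#' is made positive, so scores are deterministic.
#'
#' @param expr feature x sample matrix (samples become rows of the
#'   score matrix).
#' @param scale. scale features to unit variance.
#' @param n_components number of leading components to return.
#' @return list with `scores` (sample x PC), `variance_explained`
#'   (per component, fractions of total variance).
#' @export
pca_scores <- function(expr, scale. = FALSE, n_components = 2) {
  x <- t(expr)
  keep <- apply(x, 2, function(v) sd(v) > 0)
  if (!any(keep)) stop("expression matrix is constant; PCA undefined")
  x <- x[, keep, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(pc$x))
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = ve)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((Ct_target_case - Ct_ref_case) - (Ct_target_ctrl -
#' Ct_ref_ctrl))`: fold change of a target gene in the case condition
#' relative to control, each normalized to a reference gene.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl cycle
#'   thresholds (finite numerics; vectors recycle).
#' @return fold change(s).
#' @export
ddct_relative_expression <- function(ct_target_case, ct_ref_case,
                                     ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(all(is.finite(c(ct_target_case, ct_ref_case,
                            ct_target_ctrl, ct_ref_ctrl))))
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
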