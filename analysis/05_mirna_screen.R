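#!/usr/bin/env Rscript
# Plasma miRNA screen on the simulated 11-vs-14 cohort (from
# 01_simulate_fields.R): expression filter, TMM normalization, the NB
# exact-style test with BH-FDR, DEM selection at |log2FC| > 1 and
# FDR < 0.05, the control-interval signature rule, and PCA scores.

suppressMessages(library(periplaque))
src <- "results/synthetic"
out <- "results/mirna"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
if (!file.exists(file.path(src, "mirna_counts.tsv")))
  stop("run analysis/01_simulate_fields.R first")

counts <- as.matrix(read.table(file.path(src, "mirna_counts.tsv"),
                               header = TRUE, row.names = 1, sep = "\t",
                               check.names = FALSE))
samples <- read.table(file.path(src, "mirna_samples.tsv"), header = TRUE,
                      sep = "\t")
groups <- factor(samples$group[match(colnames(counts), samples$sample_id)],
                 levels = c("case", "control"))
truth <- read_result_table(file.path(src, "mirna_truth.csv"))

filtered <- filter_by_expression(counts, groups)
message(nrow(filtered), " of ", nrow(counts),
        " miRNAs pass the expression filter")

nf <- tmm_normalize(filtered)
write_result_table(
  data.frame(sample_id = colnames(filtered), factor = nf$factors,
             effective_lib_size = nf$effective_lib_sizes),
  file.path(out, "norm_factors.csv"), config = list(trim_m = 0.3,
                                                    trim_a = 0.05))

dem <- select_dems(de_test(filtered, groups, nf))
write_result_table(dem, file.path(out, "dem_table.csv"),
                   config = list(log2fc_cut = 1, fdr_cut = 0.05))
message(attr(dem, "n_up"), " up + ", attr(dem, "n_down"),
        " down DEMs at |log2FC| > 1 and FDR < 0.05")
tr <- truth[match(dem$feature_id, truth$feature_id), ]
sens <- mean(dem$status[tr$is_de] != "ns")
called <- dem$status != "ns"
fdp <- if (any(called)) mean(!tr$is_de[called]) else 0
message("vs ground truth: sensitivity ", round(sens, 3),
        ", false discovery proportion ", round(fdp, 3))

logcpm <- cpm_matrix(filtered, nf, log = TRUE)
sig <- ci_signature(logcpm, groups, counts = filtered)
write_result_table(sig, file.path(out, "signature_table.csv"),
                   config = list(level = 0.95, type = "prediction"))
message(sum(sig$flagged), " miRNA(s) with every case outside the 95% ",
        "control interval; ", sum(sig$exclusive_to_cases),
        " detected exclusively in cases")

pc <- pca_scores(logcpm)
scores <- data.frame(sample_id = colnames(filtered),
                     group = as.character(groups), pc$scores)
write_result_table(scores, file.path(out, "pca_scores.csv"),
                   config = list(scale = FALSE))
sep <- sign(scores$PC1[groups == "case"])
message("PCA: PC1 explains ",
        round(100 * pc$variance_explained[1], 1), "% of variance")

## qPCR-style validation arithmetic on two DEMs (2^-ddCt)
top <- head(dem$feature_id[order(dem$fdr)], 2)
message("top DEMs by FDR: ", paste(top, collapse = ", "),
        "; example 2^-ddCt fold change for Ct (24, 18 | 26, 18): ",
        ddct_relative_expression(24, 18, 26, 18))
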