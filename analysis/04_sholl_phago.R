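#!/usr/bin/env Rscript
# Sholl analysis of the simulated control vs hypotrophic morphologies
# (from 01_simulate_fields.R) and phagocytosis scoring of the simulated
# co-culture field.

suppressMessages(library(periplaque))
src <- "results/synthetic"
out <- "results/sholl_phago"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
if (!dir.exists(file.path(src, "swc")))
  stop("run analysis/01_simulate_fields.R first")

## Sholl: per-neuron profiles and AUC by group
files <- list.files(file.path(src, "swc"), full.names = TRUE)
rows <- lapply(files, function(f) {
  prof <- sholl_from_swc(read_swc(f), delta_r_um = 5)
  data.frame(neuron = basename(f),
             group = sub("_.*", "", basename(f)),
             max_intersections = max(prof$intersections),
             auc = profile_auc(prof))
})
sholl_tab <- do.call(rbind, rows)
write_result_table(sholl_tab, file.path(out, "sholl_auc.csv"),
                   config = list(delta_r_um = 5))
ctrl <- sholl_tab$auc[sholl_tab$group == "control"]
hypo <- sholl_tab$auc[sholl_tab$group == "hypotrophic"]
tt <- t.test(ctrl, hypo)
message("Sholl AUC: control ", round(mean(ctrl), 1), " vs hypotrophic ",
        round(mean(hypo), 1), " um x crossings (t-test p = ",
        signif(tt$p.value, 3), ")")

## phagocytosis: segment cells and score FITC engulfment
roles <- c(iba1 = 1, nuclei = 2, fitc = 3)
stack <- read_stack_tiff(file.path(src, "phago_field.tif"), n_channels = 3,
                         pixel_size_um = 0.5, channel_roles = roles)
seg <- segment_cells(get_channel(stack, "iba1"),
                     get_channel(stack, "nuclei"), stack$pixel_size_um)
q <- quantify_phagocytosis(seg, get_channel(stack, "fitc"))
write_result_table(q$per_cell, file.path(out, "phago_per_cell.csv"),
                   config = list(min_punctum_area_um2 = 1))
write_result_table(
  data.frame(n_cells = q$n_cells, n_positive = q$n_positive,
             proportion_positive = q$proportion_positive,
             mean_fitc_positive = q$mean_fitc_positive,
             threshold = q$threshold),
  file.path(out, "phago_summary.csv"), config = list())
message(sprintf("phagocytosis: %d/%d cells positive (%.0f%%), mean FITC %.3f",
                q$n_positive, q$n_cells, 100 * q$proportion_positive,
                q$mean_fitc_positive))
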