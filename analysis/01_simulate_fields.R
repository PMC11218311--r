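#!/usr/bin/env Rscript
# Generates the synthetic study inputs used by the downstream analysis
# scripts: one example multi-channel histology field (written as TIFF +
# ground truth), a set of neuron morphologies (SWC), a phagocytosis
# field, and a case/control miRNA count matrix (TSV).

suppressMessages(library(periplaque))
seed <- 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## example peri-plaque field: half-covered plaque, uncovered-biased halo
cfg <- sim_config(field_size_um = c(80, 80), seed = seed)
spec <- plaque_spec(center_um = c(40, 40), radius_um = 8,
                    covered_intervals_deg = list(c(20, 200)),
                    lamp1_density_covered = 0.05,
                    lamp1_density_uncovered = 0.5,
                    lamp1_outer_radius_um = 18,
                    n_somata_within_25um = 3, n_somata_background = 6)
sim <- simulate_histology_stack(cfg, list(spec))
write_stack_tiff(sim$stack, file.path(out, "example_field.tif"))
write_result_table(sim$truth, file.path(out, "example_field_truth.csv"),
                   config = list(seed = seed, field_um = 80))
write_result_table(sim$somata, file.path(out, "example_field_somata.csv"),
                   config = list(seed = seed))
message("example field: ", nrow(sim$truth), " plaque, ",
        nrow(sim$somata), " somata -> ", out)

## neuron morphologies: a "control" and a "hypotrophic" group
dir.create(file.path(out, "swc"), showWarnings = FALSE)
for (i in 1:10) {
  ctrl <- simulate_neuron_swc(branch_depth = 4, segment_len_um = 9,
                              seed = 100 + i, n_primary = 3)
  hypo <- simulate_neuron_swc(branch_depth = 3, segment_len_um = 7,
                              seed = 200 + i, n_primary = 3)
  write_swc(ctrl, file.path(out, "swc", sprintf("control_%02d.swc", i)))
  write_swc(hypo, file.path(out, "swc", sprintf("hypotrophic_%02d.swc", i)))
}
message("morphologies: 10 control + 10 hypotrophic SWC files")

## phagocytosis field (40% engulfing cells, as in an active co-culture)
phago <- simulate_phagocytosis_image(100, frac_positive = 0.4,
                                     puncta_intensity = 0.8, seed = seed)
write_stack_tiff(phago$stack, file.path(out, "phago_field.tif"))
write_result_table(phago$truth, file.path(out, "phago_truth.csv"),
                   config = list(seed = seed, n_cells = 100,
                                 frac_positive = 0.4))
message("phagocytosis field: ", nrow(phago$truth), " cells, ",
        sum(phago$truth$positive), " true positives")

## plasma-like miRNA counts: 11 cases vs 14 controls, 10% DE at |lfc| 2
cspec <- count_sim_spec(n_case = 11, n_control = 14, n_mirna = 400,
                        dispersion = 0.1, frac_de = 0.1, log2fc_de = 2,
                        lib_size_factor_sd = 0.2, seed = seed)
cm <- simulate_count_matrix(cspec)
write.table(cm$counts, file.path(out, "mirna_counts.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)
write.table(data.frame(sample_id = colnames(cm$counts),
                       group = as.character(cm$groups)),
            file.path(out, "mirna_samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_result_table(cm$truth, file.path(out, "mirna_truth.csv"),
                   config = as.list(unclass(cspec)))
message("miRNA counts: ", nrow(cm$counts), " features x ",
        ncol(cm$counts), " samples (", sum(cm$truth$is_de), " true DE)")
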