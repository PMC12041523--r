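#!/usr/bin/env Rscript
# Generate one synthetic example of each assay input with known ground truth
# and write them under results/simulated/. Later scripts re-generate their
# own (larger) inputs in code; these files exist so the raw inputs of each
# assay can be inspected directly.

suppressMessages(library(tcellipid))
out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# Co-localization field: 25 T cells, 70% of them with PLIN2-coupled
# aggregates, the coupling and SNR regime used throughout the analyses.
coloc <- gen_coloc_field(coloc_sim_params(n_cells = 25,
                                          field_shape = c(384, 384),
                                          seed = 101))
write.csv(coloc$truth$cells, file.path(out_dir, "coloc_truth_cells.csv"),
          row.names = FALSE)

# Raft fields: a dispersed (clustering 0) and a clustered (clustering 0.9)
# condition at identical total CT-B signal per cell.
for (cl in c(0, 0.9)) {
  sim <- gen_raft_field(raft_sim_params(n_cells = 25,
                                        field_shape = c(384, 384),
                                        clustering = cl, seed = 101))
  write.csv(sim$truth$cells,
            file.path(out_dir, sprintf("raft_truth_cells_c%02d.csv",
                                       round(100 * cl))),
            row.names = FALSE)
}

# TIFF export of the example fields when the 'tiff' package is available.
if (requireNamespace("tiff", quietly = TRUE)) {
  write_field_image(coloc$image, file.path(out_dir, "coloc_field.tif"))
}

# Dye-dilution events: a stimulated profile plus its unstimulated control.
stim <- gen_ctv_events(ctv_sim_params(n_events = 20000, seed = 101))
ctrl <- gen_ctv_events(ctv_sim_params(n_events = 10000,
                                      generation_fractions = 1, seed = 102))
write.csv(cbind(stim$events, stim$truth),
          file.path(out_dir, "ctv_stimulated.csv"), row.names = FALSE)
write.csv(ctrl$events, file.path(out_dir, "ctv_unstimulated.csv"),
          row.names = FALSE)

# Lipid intensity table with two seeded fold-changes between groups.
fc <- c("PC(32:1)" = 3, "TAG(34:2)" = -2.5)
lip <- gen_lipid_table(lipid_sim_params(cv = 0.2, group_log2fc = fc,
                                        seed = 101))
write.csv(lip$table$intensity, file.path(out_dir, "lipid_intensities.csv"))
write.csv(lip$table$species, file.path(out_dir, "lipid_species.csv"),
          row.names = FALSE)
write.csv(lip$truth$species, file.path(out_dir, "lipid_truth.csv"),
          row.names = FALSE)

cat("simulated inputs written to", out_dir, "\n")
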