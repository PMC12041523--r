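#!/usr/bin/env Rscript
# Per-cell Bodipy/PLIN2 co-localization on simulated fields emulating a
# healthy-donor-like condition (all cells coupled) and a CLL-like condition
# (a fraction of cells with PLIN2-negative aggregates). For each condition:
# detect cells, take the 50 brightest Bodipy pixels per cell, regress PLIN2
# on Bodipy, and report the percentage of cells with a significant positive
# slope.

suppressMessages(library(tcellipid))
dir.create("results", showWarnings = FALSE)

conditions <- list(HD_like = 1.0, CLL_like = 0.7)
summaries <- list()
cells <- list()
for (nm in names(conditions)) {
  sim <- gen_coloc_field(coloc_sim_params(n_cells = 200,
                                          field_shape = c(1024, 1024),
                                          coloc_fraction = conditions[[nm]],
                                          seed = 11))
  rois <- detect_cells(sim$image, "membrane")
  res <- classify_cells(rois, sim$image)
  res$condition <- nm
  cells[[nm]] <- res
  summaries[[nm]] <- summarize_coloc(res, nm)
  cat(sprintf("%s: %d cells detected, %.1f%% with significant positive Bodipy-PLIN2 slope (truth %.1f%%)\n",
              nm, length(rois), summaries[[nm]]$percent_positive,
              100 * mean(sim$truth$cells$coupled)))
}

write.csv(do.call(rbind, cells), "results/coloc_cells.csv",
          row.names = FALSE)
write.csv(do.call(rbind, summaries), "results/coloc_summary.csv",
          row.names = FALSE)

# cross-sectional diagnostic: gray-value traces through one detected cell
sim <- gen_coloc_field(coloc_sim_params(n_cells = 10,
                                        field_shape = c(256, 256),
                                        coloc_fraction = 1, seed = 12))
roi <- detect_cells(sim$image, "membrane")[[1]]
ctr <- round(roi$centroid)
pr <- intensity_profile(sim$image,
                        c(ctr[1], max(ctr[2] - 15, 1)),
                        c(ctr[1], min(ctr[2] + 15, 256)),
                        channels = c("bodipy", "plin2"))
write.csv(pr, "results/coloc_profile_example.csv", row.names = FALSE)
cat("per-cell table, summaries and an example spatial profile written to results/\n")
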