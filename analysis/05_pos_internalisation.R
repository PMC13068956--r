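#!/usr/bin/env Rscript
# POS internalisation assay: apical-actin cut-off, 3D particle segmentation,
# internalised-vs-bound classification and per-field summaries.
#
# The control condition internalises more, smaller fragments; the
# density-reduced condition fewer, larger ones. Ground-truth counts and
# volume ranges encode that contrast; the pipeline recovers it.

suppressMessages(library(epimech))
dir.create("results", showWarnings = FALSE)
set.seed(55)

conditions <- list(
  iRPE = list(n_int = 24, n_bound = 10, vol = c(0.3, 0.9)),
  `dr-iRPE` = list(n_int = 12, n_bound = 10, vol = c(0.6, 1.6)))
cells_per_field <- 60  # cells in a 40 x 40 µm field at day-20 densities

rows <- list()
for (cond in names(conditions)) {
  cfg <- conditions[[cond]]
  for (rep_i in 1:3) {
    st <- gen_pos_stack(n_internalised = cfg$n_int, n_bound = cfg$n_bound,
                        particle_volume_range = cfg$vol,
                        monolayer_height = if (cond == "iRPE") 11.6 else 9.1,
                        noise_level = 0.02, seed = sample.int(1e6, 1))
    surf <- build_apical_surface(st)
    parts <- classify_particles(segment_particles(st), surf)
    s <- summarize_internalisation(parts, cell_count = cells_per_field)
    rows[[length(rows) + 1]] <- data.frame(
      condition = cond, replicate = rep_i, cutoff_um = surf$cutoff_um,
      n_internalised = s$n_internalised, n_bound = s$n_bound,
      per_cell = s$per_cell,
      mean_vol_internalised_um3 = s$mean_volume_internalised,
      mean_vol_bound_um3 = s$mean_volume_bound,
      truth_internalised = cfg$n_int, truth_bound = cfg$n_bound)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/pos_internalisation_per_field.csv",
          row.names = FALSE)

agg <- aggregate(cbind(n_internalised, per_cell,
                       mean_vol_internalised_um3) ~ condition, tab, mean)
write.csv(agg, "results/pos_internalisation_summary.csv", row.names = FALSE)
cat("Internalisation per condition (means over 3 fields):\n")
print(agg, digits = 3, row.names = FALSE)
cat(sprintf("Classification matched generator truth in %d/%d fields\n",
            sum(tab$n_internalised == tab$truth_internalised &
                tab$n_bound == tab$truth_bound), nrow(tab)))
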