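#!/usr/bin/env Rscript
# Replicate statistics: aggregate the per-replicate tables produced by the
# upstream analyses and run the paired tests used for the figure panels.

suppressMessages(library(epimech))
dir.create("results", showWarnings = FALSE)

need <- c("results/indentation_per_replicate.csv",
          "results/dma_moduli_per_replicate.csv")
if (!all(file.exists(need)))
  stop("run analysis/01 and analysis/02 first", call. = FALSE)

ind <- read.csv("results/indentation_per_replicate.csv")
dma <- read.csv("results/dma_moduli_per_replicate.csv")

# one tidy replicate table across measurements
tab <- rbind(
  data.frame(replicate = ind$replicate, condition = ind$condition,
             measurement = "E_eff_Pa", value = ind$E_eff_Pa),
  data.frame(replicate = dma$replicate, condition = dma$condition,
             measurement = paste0("E_storage_", dma$frequency_Hz, "Hz"),
             value = dma$E_storage_Pa),
  data.frame(replicate = dma$replicate, condition = dma$condition,
             measurement = paste0("E_loss_", dma$frequency_Hz, "Hz"),
             value = dma$E_loss_Pa))
agg <- aggregate_technical(tab)

report <- stats_report(agg, test = "paired")
write.csv(report, "results/stats_report.csv", row.names = FALSE)
cat("Paired comparisons (condition means, two-sided paired t):\n")
print(report, digits = 3, row.names = FALSE)
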