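#!/usr/bin/env Rscript
# Seven AMMI stability indices (ASV, SIPC, EV, Za, MASV, D, WAAS), their
# ranks, and the simultaneous selection indices combining each stability
# rank with the yield rank. Small ssi = stable AND high yielding.

suppressMessages(library(metstab))

data <- read_met_csv("results/data/trial.csv")
dir.create("results", showWarnings = FALSE)

an <- combined_anova(data)
am <- gollob_test(ammi_decompose(compute_ge_means(data)), an)
tab <- stability_indices(am)
write.csv(tab, "results/stability.csv", row.names = FALSE)

best <- function(col) tab$genotype[order(tab[[col]])][1:4]
cat("top-4 by ssi_ASV: ", paste(best("ssi_ASV"), collapse = " "), "\n")
cat("top-4 by ssi_WAAS:", paste(best("ssi_WAAS"), collapse = " "), "\n")
cat("top-4 by ssi_D:   ", paste(best("ssi_D"), collapse = " "), "\n")
cat("highest yielding: ", tab$genotype[tab$RY == 1], "\n")
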