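#!/usr/bin/env Rscript
# Mixed-model (BLUP) route to stability and adaptability: REML variance
# components, shrunken genotypic values GV_ij = u_j + g_i + ge_ij, and the
# harmonic-mean / relative-performance statistics HMGV, RPGV, HMRPGV.

suppressMessages(library(metstab))

data <- read_met_csv("results/data/trial.csv")
dir.create("results", showWarnings = FALSE)

fit <- fit_met_mixed_model(data)
vc <- fit$varcomp
tab <- hmrpgv_table(fit$gv)
write.csv(tab, "results/hmrpgv.csv", row.names = FALSE)
write.csv(data.frame(component = c("genotype", "genotype_x_environment",
                                   "residual"),
                     variance = c(vc$sigma2_g, vc$sigma2_ge, vc$sigma2_e)),
          "results/varcomp.csv", row.names = FALSE)

cat(sprintf("variance components: sigma2_g %.0f, sigma2_ge %.0f, sigma2_e %.0f\n",
            vc$sigma2_g, vc$sigma2_ge, vc$sigma2_e))
top4 <- tab[order(tab$rank_HMRPGV), ][1:4, ]
cat("top-4 by HMRPGV:", paste(top4$genotype, collapse = " "), "\n")
cat(sprintf("their HMRPGV*mu: %s kg/ha\n",
            paste(sprintf("%.0f", top4$HMRPGV_x_mu), collapse = ", ")))
gain <- 100 * (mean(top4$HMRPGV_x_mu) - fit$gv$grand_mean) / fit$gv$grand_mean
cat(sprintf("selecting them gains %.2f%% over the general mean (%.2f kg/ha)\n",
            gain, fit$gv$grand_mean))
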