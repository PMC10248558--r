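#!/usr/bin/env Rscript
# Generate the study trial: 16 chickpea-scale genotypes x 8 rainfed
# site-year environments x 3 blocks, with additive main effects, an
# interaction driven by six seasonal climate covariates (three rainfall,
# three temperature) plus a small unstructured residual, and plot noise.
# Writes the trial and covariate CSVs consumed by every later step.

suppressMessages(library(metstab))

seed <- 1L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- sim_spec(seed = seed, interaction_singular_values = numeric(0),
                 plot_noise_sd = 120)
set.seed(seed + 1000L)
xi_true <- matrix(rnorm(16 * 6), 16, 6) %*% diag(c(1.2, 0.3, 0.8, 12, 3, 8))
sim <- suppressWarnings(generate_covariate_linked(spec, xi_true,
                                                  residual_sd = 25))

write_met_csv(sim$data, file.path(out_dir, "trial.csv"))
write_covariates_csv(sim$covariates, file.path(out_dir, "covariates.csv"))
write.csv(data.frame(genotype = rownames(sim$truth$xi), sim$truth$xi),
          file.path(out_dir, "true_sensitivities.csv"), row.names = FALSE)

cat(sprintf("simulated %d plots (%d genotypes x %d environments x 3 blocks)\n",
            nrow(sim$data$records), length(sim$data$genotypes),
            length(sim$data$environments)))
cat(sprintf("overall mean yield %.1f kg/ha\n", mean(sim$data$records$yield)))
cat("wrote trial.csv, covariates.csv, true_sensitivities.csv to", out_dir, "\n")
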