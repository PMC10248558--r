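# Brute-force RCBD partition from the textbook definitions, as an oracle
# independent of the aov-based implementation. Uniform replication only.
brute_anova_ss <- function(records) {
  y <- records$yield
  gbar <- mean(y)
  ybar_ij <- tapply(y, list(records$genotype, records$environment), mean)
  ybar_i <- tapply(y, records$genotype, mean)
  ybar_j <- tapply(y, records$environment, mean)
  ybar_jk <- tapply(y, list(records$environment, records$replicate), mean)
  g <- length(ybar_i); e <- length(ybar_j)
  r <- nrow(records) / (g * e)
  list(
    env = g * r * sum((ybar_j - gbar)^2),
    rep_env = g * sum(sweep(ybar_jk, 1, as.vector(ybar_j[rownames(ybar_jk)]))^2),
    gen = e * r * sum((ybar_i - gbar)^2),
    gxe = r * sum((sweep(sweep(ybar_ij, 1, ybar_i), 2, ybar_j) + gbar)^2),
    total = sum((y - gbar)^2)
  )
}

test_that("combined ANOVA matches explicit sums of squared deviations", {
  set.seed(31)
  for (dims in list(c(2, 2, 2), c(5, 3, 4))) {
    means <- matrix(rnorm(dims[1] * dims[2], 100, 10), dims[1], dims[2])
    d <- dataset_from_means(means, r = dims[3], noise_sd = 5, seed = dims[3])
    an <- combined_anova(d)
    oracle <- brute_anova_ss(d$records)
    tab <- an$table
    ss <- setNames(tab$SS, tab$source)
    expect_equal(unname(ss["environment"]), oracle$env, tolerance = 1e-8)
    expect_equal(unname(ss["replicate_within_environment"]), oracle$rep_env,
                 tolerance = 1e-8)
    expect_equal(unname(ss["genotype"]), oracle$gen, tolerance = 1e-8)
    expect_equal(unname(ss["genotype_x_environment"]), oracle$gxe,
                 tolerance = 1e-8)
    expect_equal(unname(ss["total"]), oracle$total, tolerance = 1e-8)
    # conservation: components add to the total
    expect_equal(sum(tab$SS[tab$source != "total"]), unname(ss["total"]),
                 tolerance = 1e-8)
    expect_equal(sum(tab$df[tab$source != "total"]),
                 tab$df[tab$source == "total"])
    expect_equal(sum(tab$percent_of_total[tab$source != "total"]), 100,
                 tolerance = 1e-8)
  }
})

test_that("a constant response has zero SS everywhere", {
  d <- dataset_from_means(matrix(42, 3, 3), r = 2)
  tab <- combined_anova(d)$table
  expect_equal(max(tab$SS[tab$source != "total"]), 0)
})

test_that("single-replicate trials return the partition without F tests", {
  d <- dataset_from_means(matrix(rnorm(12, 50), 4, 3), r = 1)
  an <- combined_anova(d)
  expect_false(an$has_error_term)
  expect_true(all(is.na(an$table$F)))
})

test_that("AMMI on a 2x2 interaction matches the closed-form SVD", {
  # means built so the interaction is [[1,-1],[-1,1]]: single axis, lambda 2
  means <- matrix(c(10, 20, 30, 40), 2, byrow = TRUE) +
    matrix(c(1, -1, -1, 1), 2, byrow = TRUE)
  gem <- compute_ge_means(dataset_from_means(means))
  am <- ammi_decompose(gem, replicates = 1)
  expect_equal(am$singular_values[1], 2, tolerance = 1e-12)
  expect_equal(am$percent_explained[1], 100, tolerance = 1e-12)
})

test_that("additive means give a flagged all-zero decomposition", {
  means <- outer(c(-10, 0, 10), c(-5, 0, 5), `+`) + 100
  am <- ammi_decompose(compute_ge_means(dataset_from_means(means)),
                       replicates = 1)
  expect_true(am$zero_interaction)
  expect_equal(max(abs(am$genotype_scores)), 0, tolerance = 1e-12)
  expect_equal(sum(am$percent_explained), 0)
})

test_that("SVD identities hold on random interactions", {
  set.seed(77)
  for (i in 1:5) {
    means <- matrix(rnorm(48, 100, 20), 8, 6)
    gem <- compute_ge_means(dataset_from_means(means))
    am <- ammi_decompose(gem, replicates = 3)
    # eigenvalues sum to the squared Frobenius norm of the interaction
    expect_equal(sum(am$eigenvalues), sum(gem$interaction^2),
                 tolerance = 1e-10)
    # theta sums to 100 over all axes
    expect_equal(sum(am$percent_explained), 100, tolerance = 1e-10)
    # per-axis score SS equals lambda on both sides
    expect_equal(colSums(am$genotype_scores^2), am$singular_values,
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(colSums(am$environment_scores^2), am$singular_values,
                 tolerance = 1e-10, ignore_attr = TRUE)
    # score columns are orthogonal
    cp <- crossprod(am$genotype_scores)
    expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8 * am$singular_values[1])
    # retaining every axis reconstructs the cell means (AMMIF)
    rebuilt <- gem$grand_mean +
      outer(gem$genotype_effects, gem$environment_effects, `+`) +
      am$genotype_scores %*% t(am$environment_scores)
    expect_lt(max(abs(rebuilt - gem$means)), 1e-8 * gem$grand_mean)
  }
})

test_that("interaction SS is conserved between ANOVA and AMMI", {
  sim <- quiet_generate(sim_spec(seed = 13))
  an <- combined_anova(sim$data)
  am <- ammi_decompose(compute_ge_means(sim$data))
  ss_gei <- an$table$SS[an$table$source == "genotype_x_environment"]
  expect_equal(3 * sum(am$eigenvalues), ss_gei, tolerance = 1e-8)
})

test_that("Gollob degrees of freedom and the significance scan behave", {
  sim <- quiet_generate(sim_spec(seed = 4))   # 16 x 8 x 3
  an <- combined_anova(sim$data)
  am <- gollob_test(ammi_decompose(compute_ge_means(sim$data)), an)
  expect_equal(am$gollob$df[1:2], c(21, 19))  # g + e - 1 - 2n
  expect_error(gollob_test(am, an, alpha = 1.2), "alpha")

  # zero interaction: nothing significant, N' floored at 1
  means <- outer(c(-10, 0, 10, 20), c(-5, 0, 5), `+`) + 100
  d0 <- dataset_from_means(means, r = 2, noise_sd = 1, seed = 8)
  an0 <- combined_anova(d0)
  am0 <- gollob_test(ammi_decompose(compute_ge_means(d0)), an0)
  expect_equal(am0$n_significant, 1)
})

test_that("a strong rank-1 interaction is called with one significant axis", {
  hits <- 0L
  for (seed in 1:20) {
    sim <- quiet_generate(sim_spec(g = 10, e = 6, r = 3, seed = seed,
                                   interaction_singular_values = 800,
                                   plot_noise_sd = 100))
    an <- combined_anova(sim$data)
    am <- gollob_test(ammi_decompose(compute_ge_means(sim$data)), an)
    if (am$n_significant == 1) hits <- hits + 1L
  }
  expect_gte(hits, 19)
})

test_that("biplot coordinates agree with a direct SVD oracle", {
  set.seed(101)
  means <- matrix(rnorm(9, 50, 8), 3, 3)
  gem <- compute_ge_means(dataset_from_means(means))
  am <- ammi_decompose(gem, replicates = 1)
  sv <- svd(gem$interaction)
  c1 <- ammi1_coords(am)
  gen_rows <- c1[c1$type == "genotype", ]
  expect_equal(gen_rows$mean, unname(rowMeans(gem$means)))
  expect_equal(abs(gen_rows$IPC1), abs(sqrt(sv$d[1]) * sv$u[, 1]),
               tolerance = 1e-10)
  expect_equal(attr(c1, "grand_mean"), gem$grand_mean)

  c2 <- ammi2_coords(am)
  env_rows <- c2[c2$type == "environment", ]
  expect_equal(abs(env_rows$IPC2), abs(sqrt(sv$d[2]) * sv$v[, 2]),
               tolerance = 1e-10)
  expect_equal(c2$distance, sqrt(c2$IPC1^2 + c2$IPC2^2))

  # additive data: every AMMI1 ordinate is zero
  add <- ammi_decompose(compute_ge_means(
    dataset_from_means(outer(1:3, c(0, 5, 9), `+`) + 50)), replicates = 1)
  expect_equal(max(abs(ammi1_coords(add)$IPC1)), 0, tolerance = 1e-12)
  # rank-1 interaction: all IPC2 coordinates vanish
  r1 <- generate_met(sim_spec(g = 5, e = 4, r = 1, seed = 3,
                              interaction_singular_values = 30,
                              plot_noise_sd = 0))
  amr1 <- ammi_decompose(compute_ge_means(r1$data), replicates = 1)
  expect_lt(max(abs(ammi2_coords(amr1)$IPC2)), 1e-6)
})
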