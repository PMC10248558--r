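centered_cov <- function(values) center_covariates(covariate_matrix(values))

test_that("factorial regression recovers an exact covariate-linked truth", {
  spec <- sim_spec(g = 12, e = 7, r = 1, seed = 6, plot_noise_sd = 0)
  xi <- matrix(rnorm(12, 0, 3), 12, 1)
  sim <- generate_covariate_linked(spec, xi, covariate_means = 150,
                                   covariate_sds = 40, variable_names = "Rain")
  gem <- compute_ge_means(sim$data)
  fr <- fit_factorial_regression(gem$interaction,
                                 center_covariates(sim$covariates))
  expect_equal(unname(fr$xi[, "Rain"]), unname(sim$truth$xi[, "Rain"]),
               tolerance = 1e-6)
  expect_lt(fr$residual_SS, 1e-6 * fr$total_SS + 1e-12)
  # sensitivity columns are centered across genotypes
  expect_lt(max(abs(colSums(fr$xi))), 1e-8)
})

# rank-2 interaction over 5 environments plus a centered environment vector
# orthogonal to both interaction axes (possible only because rank < e - 1)
lowrank_case <- function(seed = 1) {
  set.seed(seed)
  V <- qr.Q(qr(cbind(1, matrix(rnorm(5 * 3), 5, 3))))[, -1]  # centered o.n.
  U <- qr.Q(qr(cbind(1, matrix(rnorm(4 * 2), 4, 2))))[, -1]
  ge <- 10 * U[, 1] %*% t(V[, 1]) + 4 * U[, 2] %*% t(V[, 2])
  dimnames(ge) <- list(paste0("G", 1:4), paste0("E", 1:5))
  list(ge = ge, orth = V[, 3])
}

test_that("orthogonal covariates get zero sensitivities and the empty model fits nothing", {
  case <- lowrank_case(1)
  cov <- centered_cov(cbind(orth = case$orth))
  expect_lt(max(abs(case$ge %*% cov$values)), 1e-10)
  fr <- fit_factorial_regression(case$ge, cov)
  expect_lt(max(abs(fr$xi)), 1e-8)
  fr0 <- fit_factorial_regression(case$ge, cov, variables = character(0))
  expect_equal(fr0$residual_SS, sum(case$ge^2))
  expect_equal(max(abs(fr0$fitted_interaction)), 0)
})

test_that("sequential SS decomposition conserves the interaction SS", {
  set.seed(12)
  ge <- toy_interaction()
  cov <- centered_cov(matrix(rnorm(4 * 2), 4, 2,
                             dimnames = list(paste0("E", 1:4), c("a", "b"))))
  fr <- fit_factorial_regression(ge, cov)
  expect_equal(sum(fr$explained_SS_per_variable) + fr$residual_SS,
               fr$total_SS, tolerance = 1e-8)
})

test_that("a saturated set of e-1 independent covariates reproduces the interaction", {
  set.seed(14)
  ge <- toy_interaction()  # 5 x 4
  cov <- centered_cov(matrix(rnorm(4 * 3), 4, 3))
  fr <- fit_factorial_regression(ge, cov)
  expect_lt(fr$residual_SS, 1e-10 * max(fr$total_SS, 1))
  expect_equal(fr$fitted_interaction, ge, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-deficient covariate designs are refused by name", {
  ge <- toy_interaction()
  z <- rnorm(4)
  cov <- centered_cov(cbind(a = z, b = 2 * z))
  expect_error(fit_factorial_regression(ge, cov), "collinear")
  expect_error(fit_factorial_regression(ge, cov, variables = "missing"),
               "unknown covariate")
  uncentered <- covariate_matrix(cbind(a = rnorm(4)))
  expect_error(fit_factorial_regression(ge, uncentered), "centered")
})

test_that("stepwise AIC finds a strongly active covariate first", {
  first_hits <- 0L
  n_seeds <- 40L
  for (seed in seq_len(n_seeds)) {
    spec <- sim_spec(g = 16, e = 8, r = 1, seed = 900 + seed,
                     plot_noise_sd = 0)
    xi <- cbind(rnorm(16, 0, 4), 0, 0, 0)
    sim <- generate_covariate_linked(
      spec, xi, covariate_means = c(100, 100, 100, 100),
      covariate_sds = c(30, 30, 30, 30),
      variable_names = c("active", "n1", "n2", "n3"),
      residual_sd = 2)
    gem <- compute_ge_means(sim$data)
    fr <- stepwise_fr_aic(gem$interaction, center_covariates(sim$covariates))
    if (length(fr$selected_variables) >= 1 &&
        fr$selected_variables[1] == "active") first_hits <- first_hits + 1L
  }
  expect_gte(first_hits, ceiling(0.95 * n_seeds))
})

test_that("stepwise AIC selects nothing when covariates explain nothing", {
  case <- lowrank_case(2)
  cov <- centered_cov(cbind(orth = case$orth))
  expect_lt(max(abs(case$ge %*% cov$values)), 1e-10)
  fr <- stepwise_fr_aic(case$ge, cov)
  expect_equal(fr$selected_variables, character(0))
})

test_that("duplicate covariates: the first column wins the tie", {
  spec <- sim_spec(g = 8, e = 6, r = 1, seed = 8, plot_noise_sd = 0)
  xi <- cbind(rnorm(8, 0, 3))
  sim <- generate_covariate_linked(spec, xi, covariate_means = 100,
                                   covariate_sds = 25, variable_names = "z1")
  gem <- compute_ge_means(sim$data)
  z <- sim$covariates$values[, 1]
  cov <- centered_cov(cbind(z1 = z, z1copy = z))
  fr <- stepwise_fr_aic(gem$interaction, cov)
  expect_equal(fr$selected_variables[1], "z1")
  expect_false("z1copy" %in% fr$selected_variables)
})

test_that("stepwise AIC flags a numerically perfect fit and stops", {
  spec <- sim_spec(g = 6, e = 5, r = 1, seed = 10, plot_noise_sd = 0)
  xi <- cbind(rnorm(6, 0, 2))
  sim <- generate_covariate_linked(spec, xi, covariate_means = 50,
                                   covariate_sds = 10, variable_names = "only")
  gem <- compute_ge_means(sim$data)
  fr <- stepwise_fr_aic(gem$interaction, center_covariates(sim$covariates))
  expect_true(fr$perfect_fit)
  expect_equal(fr$selected_variables, "only")
})

test_that("PLSR recovers a rank-1 response built from one covariate", {
  set.seed(41)
  # uncorrelated predictors: the response direction is then exactly the
  # first latent factor (with correlated columns it is provably diluted)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(7 * 4), 7, 4))))[, -1]
  q <- rnorm(10)
  Y <- outer(X[, 2], q)
  m <- fit_plsr(X, Y, n_factors = 2)
  expect_gte(m$percent_Y_explained[1], 99.9)
  expect_lt(max(abs(crossprod(m$T)[1, 2])), 1e-8)
  # second coordinates of the biplot vanish on a rank-1 problem
  rownames(X) <- paste0("E", 1:7); colnames(X) <- paste0("z", 1:4)
  colnames(Y) <- paste0("G", 1:10)
  bc <- plsr_biplot_coords(fit_plsr(X, Y, n_factors = 2))
  expect_lt(max(abs(bc$Factor2)), 1e-6 * max(abs(bc$Factor1)))
})

test_that("PLSR on a zero response explains nothing", {
  set.seed(43)
  X <- scale(matrix(rnorm(6 * 3), 6, 3))
  m <- fit_plsr(X, matrix(0, 6, 5), n_factors = 2)
  expect_equal(m$percent_Y_explained, c(0, 0))
})

test_that("PLSR factor shares are non-negative, non-decreasing and reach 100", {
  set.seed(47)
  X <- scale(matrix(rnorm(6 * 5), 6, 5))
  Y <- matrix(rnorm(6 * 4), 6, 4)
  Y <- sweep(Y, 2, colMeans(Y))   # column-centered response, rank <= 5
  A <- 5
  m <- fit_plsr(X, Y, n_factors = A)
  expect_true(all(m$percent_Y_explained >= -1e-10))
  expect_true(all(diff(m$cumulative_percent) >= -1e-10))
  expect_lte(m$cumulative_percent[A], 100 + 1e-6)
  expect_equal(m$cumulative_percent[A], 100, tolerance = 1e-6)
  # T columns pairwise orthogonal
  cp <- crossprod(m$T)
  offdiag <- abs(cp[upper.tri(cp)])
  expect_lt(max(offdiag), 1e-8 * max(diag(cp)))
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(53)
  X <- matrix(rnorm(7 * 3), 7, 3,
              dimnames = list(paste0("E", 1:7), paste0("z", 1:3)))
  Y <- matrix(rnorm(7 * 5), 7, 5,
              dimnames = list(paste0("E", 1:7), paste0("G", 1:5)))
  Xs <- scale(X); Ys <- sweep(Y, 2, colMeans(Y))
  m <- fit_plsr(Xs, Ys, n_factors = 2)
  ref <- mixOmics::pls(Xs, Ys, ncomp = 2, scale = FALSE, mode = "regression")
  # scores agree up to per-factor sign
  for (a in 1:2) {
    r <- abs(cor(m$T[, a], ref$variates$X[, a]))
    expect_gt(r, 1 - 1e-6)
  }
})

test_that("PLSR sign convention makes repeated fits identical", {
  set.seed(59)
  X <- scale(matrix(rnorm(6 * 4), 6, 4))
  Y <- matrix(rnorm(6 * 3), 6, 3)
  m1 <- fit_plsr(X, Y, n_factors = 2)
  m2 <- fit_plsr(X, Y, n_factors = 2)
  expect_identical(m1$T, m2$T)
  expect_identical(m1$Q, m2$Q)
  # the largest-|loading| covariate is positive on each factor
  for (a in 1:2) expect_gt(m1$P[which.max(abs(m1$P[, a])), a], 0)
})

test_that("covariate-linked rank-1 truth maps onto the first PLSR factor", {
  spec <- sim_spec(g = 10, e = 7, r = 1, seed = 16, plot_noise_sd = 0)
  xi <- cbind(rnorm(10, 0, 3))
  sim <- generate_covariate_linked(spec, xi, covariate_means = 100,
                                   covariate_sds = 30,
                                   variable_names = "Rain")
  gem <- compute_ge_means(sim$data)
  std <- center_covariates(sim$covariates, standardize = TRUE)
  m <- fit_plsr(std, t(gem$interaction), n_factors = 1)
  expect_gte(m$percent_Y_explained[1], 99.9)
  # genotype loadings align with the true sensitivity profile
  expect_gt(abs(cor(m$Q[, 1], sim$truth$xi[, 1])), 0.99)
})
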