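#' Specification for a synthetic multi-environment trial
#'
#' Defines the generative model for a g x e x r randomized complete block
#' trial: yield = mu + alpha_i + beta_j + sum_n lambda_n gamma_in delta_jn
#' + block_jk + eps_ijk, with main effects drawn normal then centered,
#' interaction axes gamma/delta random orthonormal vectors orthogonal to the
#' ones vector (so the low-rank truth is exact), and i.i.d. plot noise.
#' Defaults emulate the chickpea trial scale this package targets: 16
#' genotypes, 8 environments, 3 blocks, overall mean 1069.25 kg/ha, with
#' effect scales calibrated so the expected sum-of-squares shares of
#' environment, genotype and interaction sit near 37, 17 and 31 percent of
#' the total and the first two interaction axes carry about 85 and 10
#' percent of the interaction.
#'
#' @param g,e,r genotypes, environments, replicates (blocks) per environment.
#' @param grand_mean overall mean yield, kg/ha.
#' @param genotype_effect_sd,environment_effect_sd sd of the drawn main
#'   effects, kg/ha.
#' @param interaction_singular_values decreasing non-negative singular values
#'   lambda_n of the true interaction matrix; at most min(g-1, e-1) of them.
#' @param block_effect_sd sd of block (replicate-within-environment) effects;
#'   0 by default.
#' @param plot_noise_sd sd of plot residuals, kg/ha.
#' @param seed integer seed controlling the single generator stream.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(g = 16, e = 8, r = 3,
                     grand_mean = 1069.25,
                     genotype_effect_sd = 135,
                     environment_effect_sd = 200,
                     interaction_singular_values = c(1900, 660),
                     block_effect_sd = 0,
                     plot_noise_sd = 150,
                     seed = 1L) {
  stopifnot(g >= 2, e >= 2, r >= 1)
  sv <- sort(as.numeric(interaction_singular_values), decreasing = TRUE)
  if (length(sv) > 0 && (any(sv < 0) || any(!is.finite(sv)))) {
    stop("singular values must be finite and non-negative")
  }
  if (length(sv) > min(g - 1, e - 1)) {
    stop(sprintf("rank request %d infeasible: at most min(g-1, e-1) = %d axes",
                 length(sv), min(g - 1, e - 1)))
  }
  sds <- c(genotype_effect_sd, environment_effect_sd, block_effect_sd, plot_noise_sd)
  if (any(sds < 0) || any(!is.finite(sds))) stop("sds must be finite and >= 0")
  structure(
    list(g = as.integer(g), e = as.integer(e), r = as.integer(r),
         grand_mean = grand_mean,
         genotype_effect_sd = genotype_effect_sd,
         environment_effect_sd = environment_effect_sd,
         interaction_singular_values = sv,
         block_effect_sd = block_effect_sd,
         plot_noise_sd = plot_noise_sd,
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# n orthonormal columns orthogonal to the ones vector, from QR of
# standard-normal draws stacked behind 1.
.orthonormal_vs_ones <- function(dim, n) {
  if (n == 0) return(matrix(0, dim, 0))
  if (n > dim - 1) stop("cannot draw ", n, " orthonormal vectors orthogonal to ones in dim ", dim)
  M <- cbind(rep(1, dim), matrix(stats::rnorm(dim * n), dim, n))
  Q <- qr.Q(qr(M))[, -1, drop = FALSE]
  Q
}

# centered normal draws rescaled to exact sample sd, so the realized
# effect variance equals the requested one (mirrors the exact low-rank
# interaction: the spec values ARE the ground truth, not just its
# expectation); exact zeros when sd == 0
.centered_rnorm <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

#' Generate a synthetic trial with known ground truth
#'
#' Draws every component of the model in a fixed, documented order
#' (genotype effects, environment effects, interaction axes, block effects,
#' plot noise) from a single stream seeded by `spec$seed`, so the same spec
#' always yields a bit-identical dataset.
#'
#' @param spec a [sim_spec()].
#' @return list with `data` (a [met_dataset()]) and `truth` (list: mu,
#'   alpha, beta, gamma, delta, lambda, interaction, block_effects).
#' @export
generate_met <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  g <- spec$g; e <- spec$e; r <- spec$r
  set.seed(spec$seed)
  alpha <- .centered_rnorm(g, spec$genotype_effect_sd)
  beta <- .centered_rnorm(e, spec$environment_effect_sd)
  nsv <- length(spec$interaction_singular_values)
  gamma <- .orthonormal_vs_ones(g, nsv)
  delta <- .orthonormal_vs_ones(e, nsv)
  ge <- if (nsv > 0) {
    gamma %*% diag(spec$interaction_singular_values, nsv) %*% t(delta)
  } else matrix(0, g, e)
  blocks <- matrix(if (spec$block_effect_sd == 0) 0 else
    stats::rnorm(e * r, 0, spec$block_effect_sd), e, r)
  blocks <- blocks - rowMeans(blocks)  # blocks centered within environment
  noise <- if (spec$plot_noise_sd == 0) rep(0, g * e * r) else
    stats::rnorm(g * e * r, 0, spec$plot_noise_sd)

  gen_id <- sprintf("G%02d", seq_len(g))
  env_id <- sprintf("E%d", seq_len(e))
  rep_id <- sprintf("R%d", seq_len(r))
  grid <- expand.grid(gi = seq_len(g), ej = seq_len(e), rk = seq_len(r),
                      KEEP.OUT.ATTRS = FALSE)
  yield <- spec$grand_mean + alpha[grid$gi] + beta[grid$ej] +
    ge[cbind(grid$gi, grid$ej)] + blocks[cbind(grid$ej, grid$rk)] + noise
  records <- data.frame(
    genotype = gen_id[grid$gi],
    environment = env_id[grid$ej],
    replicate = rep_id[grid$rk],
    yield = yield
  )
  truth <- list(
    mu = spec$grand_mean, alpha = stats::setNames(alpha, gen_id),
    beta = stats::setNames(beta, env_id),
    lambda = spec$interaction_singular_values,
    gamma = gamma, delta = delta,
    interaction = `dimnames<-`(ge, list(gen_id, env_id)),
    block_effects = blocks
  )
  list(data = met_dataset(records), truth = truth)
}

#' Generate a trial whose interaction is driven by environmental covariates
#'
#' Builds the interaction as ge_ij = sum_k xi_ik ztilde_jk from centered
#' covariates and genotype sensitivities, plus an optional unstructured
#' low-amplitude residual, so factorial regression and PLSR can be validated
#' against a known sensitivity matrix.
#'
#' Covariates are drawn i.i.d. normal per variable around `covariate_means`
#' with `covariate_sds` (defaults emulate three seasonal rainfall totals in
#' mm and three seasonal mean temperatures in degrees C). The sensitivity
#' matrix `xi` has its columns centered across genotypes so the product is
#' exactly doubly centered.
#'
#' @param spec a [sim_spec()]; its `interaction_singular_values` are ignored
#'   here (the interaction comes from the covariate link).
#' @param xi g x K matrix of true sensitivities; columns are centered if not
#'   already. K must be < e.
#' @param covariate_means,covariate_sds length-K numerics for the covariate
#'   draws.
#' @param variable_names length-K identifiers.
#' @param residual_sd sd of an unstructured doubly-centered interaction
#'   residual added on top of the covariate-linked part; 0 by default.
#' @return list with `data` (a [met_dataset()]), `covariates` (an uncentered
#'   `covariate_matrix`) and `truth` (includes `xi` and the interaction).
#' @export
generate_covariate_linked <- function(spec, xi,
                                      covariate_means = c(180, 260, 120, 14, 7, 16),
                                      covariate_sds = c(60, 80, 50, 2.5, 2, 2.5),
                                      variable_names = c("FallR", "WinterR", "SpringR",
                                                         "FallT", "WinterT", "SpringT"),
                                      residual_sd = 0) {
  stopifnot(inherits(spec, "sim_spec"))
  xi <- as.matrix(xi)
  g <- spec$g; e <- spec$e; r <- spec$r; K <- ncol(xi)
  if (nrow(xi) != g) stop("xi must have g rows")
  if (K >= e) stop("K >= e: covariate link unidentifiable")
  covariate_means <- rep_len(covariate_means, K)
  covariate_sds <- rep_len(covariate_sds, K)
  variable_names <- rep_len(variable_names, K)

  set.seed(spec$seed)
  alpha <- .centered_rnorm(g, spec$genotype_effect_sd)
  beta <- .centered_rnorm(e, spec$environment_effect_sd)
  Z <- matrix(stats::rnorm(e * K), e, K)
  Z <- sweep(Z, 2, covariate_sds, `*`)
  Z <- sweep(Z, 2, covariate_means, `+`)
  colnames(Z) <- variable_names
  Ztilde <- sweep(Z, 2, colMeans(Z))
  xi <- sweep(xi, 2, colMeans(xi))  # center sensitivities across genotypes
  ge <- xi %*% t(Ztilde)
  if (residual_sd > 0) {
    res <- matrix(stats::rnorm(g * e, 0, residual_sd), g, e)
    res <- res - outer(rowMeans(res), colMeans(res), `+`) + mean(res)
    ge <- ge + res
  }
  noise <- if (spec$plot_noise_sd == 0) rep(0, g * e * r) else
    stats::rnorm(g * e * r, 0, spec$plot_noise_sd)

  gen_id <- sprintf("G%02d", seq_len(g))
  env_id <- sprintf("E%d", seq_len(e))
  rep_id <- sprintf("R%d", seq_len(r))
  grid <- expand.grid(gi = seq_len(g), ej = seq_len(e), rk = seq_len(r),
                      KEEP.OUT.ATTRS = FALSE)
  yield <- spec$grand_mean + alpha[grid$gi] + beta[grid$ej] +
    ge[cbind(grid$gi, grid$ej)] + noise
  records <- data.frame(
    genotype = gen_id[grid$gi],
    environment = env_id[grid$ej],
    replicate = rep_id[grid$rk],
    yield = yield
  )
  rownames(Z) <- env_id
  rownames(xi) <- gen_id; colnames(xi) <- variable_names
  list(
    data = met_dataset(records),
    covariates = covariate_matrix(Z),
    truth = list(mu = spec$grand_mean,
                 alpha = stats::setNames(alpha, gen_id),
                 beta = stats::setNames(beta, env_id),
                 xi = xi, Z = Z,
                 interaction = `dimnames<-`(ge, list(gen_id, env_id)))
  )
}
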