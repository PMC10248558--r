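#' Factorial regression of the interaction on environmental covariates
#'
#' Regresses each genotype's interaction row on the centered covariate
#' columns: ge_ij ~ sum_k xi_ik * z_jk, estimating the sensitivity xi_ik of
#' genotype i to environmental variable k by ordinary least squares (no
#' intercept; both sides are centered). Because the same design matrix
#' serves every genotype, the full sensitivity matrix is
#' Xi = GE Z (Z'Z)^-1.
#'
#' The explained sum of squares is decomposed sequentially over the
#' variables in the order given, so per-variable contributions add up with
#' the residual to the total interaction SS even when covariates are
#' correlated.
#'
#' @param interaction g x e doubly-centered interaction matrix.
#' @param cov a centered `covariate_matrix` (see [center_covariates()]).
#' @param variables which covariate columns to use, in order; defaults to
#'   all.
#' @return An `fr_model`: list with `selected_variables`, `xi` (g x K
#'   matrix), `fitted_interaction`, `residual_SS`, `total_SS`,
#'   `explained_SS_per_variable` (sequential), `percent_explained`.
#' @export
fit_factorial_regression <- function(interaction, cov,
                                     variables = cov$variables) {
  stopifnot(inherits(cov, "covariate_matrix"))
  if (!cov$centered) stop("covariates must be centered first (center_covariates)")
  GE <- as.matrix(interaction)
  e <- ncol(GE)
  if (nrow(cov$values) != e) stop("covariate rows must match interaction columns")
  total_SS <- sum(GE^2)
  if (length(variables) == 0) {
    return(structure(
      list(selected_variables = character(0),
           xi = matrix(0, nrow(GE), 0, dimnames = list(rownames(GE), NULL)),
           fitted_interaction = GE * 0, residual_SS = total_SS,
           total_SS = total_SS, explained_SS_per_variable = numeric(0),
           percent_explained = numeric(0)),
      class = "fr_model"))
  }
  miss <- setdiff(variables, cov$variables)
  if (length(miss) > 0) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  if (length(variables) >= e) {
    stop("at least as many covariates as environments; unidentifiable")
  }
  Z <- cov$values[, variables, drop = FALSE]
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    dep <- variables[-seq_len(qrZ$rank)]
    stop("collinear covariates (rank-deficient design), dependent set includes: ",
         paste(utils::tail(variables, ncol(Z) - qrZ$rank), collapse = ", "))
  }
  xi <- t(qr.solve(qrZ, t(GE)))          # g x K least-squares sensitivities
  colnames(xi) <- variables
  fitted <- xi %*% t(Z)
  residual_SS <- sum((GE - fitted)^2)
  # sequential decomposition in the given variable order
  expl <- numeric(length(variables))
  rss_prev <- total_SS
  for (k in seq_along(variables)) {
    Zk <- cov$values[, variables[seq_len(k)], drop = FALSE]
    rss_k <- sum(qr.resid(qr(Zk), t(GE))^2)
    expl[k] <- rss_prev - rss_k
    rss_prev <- rss_k
  }
  names(expl) <- variables
  structure(
    list(selected_variables = variables, xi = xi,
         fitted_interaction = fitted, residual_SS = residual_SS,
         total_SS = total_SS, explained_SS_per_variable = expl,
         percent_explained = 100 * expl / total_SS),
    class = "fr_model"
  )
}

#' @export
print.fr_model <- function(x, ...) {
  cat("Factorial regression:", length(x$selected_variables), "covariate(s)\n")
  if (length(x$selected_variables) > 0) {
    print(data.frame(variable = x$selected_variables,
                     SS = x$explained_SS_per_variable,
                     percent = x$percent_explained, row.names = NULL),
          digits = 4)
  }
  cat(sprintf("residual SS %.4g of total %.4g\n", x$residual_SS, x$total_SS))
  invisible(x)
}

#' Forward stepwise factorial regression by AIC
#'
#' Starting from the empty model, repeatedly adds the covariate that most
#' lowers AIC = N ln(RSS/N) + 2P, where N = g*e interaction cells and P is
#' the number of fitted sensitivity parameters (g per covariate in the
#' model); stops when no candidate lowers AIC. Ties are broken by column
#' order. If the fit becomes numerically perfect (RSS ~ 0) selection stops
#' with a `perfect_fit` flag rather than chasing AIC to -Inf.
#'
#' @param interaction g x e doubly-centered interaction matrix.
#' @param cov a centered `covariate_matrix`.
#' @return An `fr_model` for the selected variables, with an `aic_trace`
#'   data.frame (step, variable, AIC, RSS) and `perfect_fit` flag attached.
#' @export
stepwise_fr_aic <- function(interaction, cov) {
  stopifnot(inherits(cov, "covariate_matrix"))
  if (!cov$centered) stop("covariates must be centered first (center_covariates)")
  GE <- as.matrix(interaction)
  g <- nrow(GE); e <- ncol(GE)
  N <- g * e
  total_SS <- sum(GE^2)
  aic_of <- function(rss, n_vars) N * log(rss / N) + 2 * (g * n_vars)
  rss_floor <- max(total_SS, 1) * 1e-12

  selected <- character(0)
  current_rss <- total_SS
  current_aic <- if (total_SS <= rss_floor) -Inf else aic_of(total_SS, 0)
  trace <- data.frame(step = 0L, variable = "<empty>",
                      AIC = current_aic, RSS = current_rss)
  perfect <- total_SS <= rss_floor
  candidates <- cov$variables
  step <- 0L
  while (!perfect && length(candidates) > 0 && length(selected) < e - 1) {
    rss_cand <- rep(NA_real_, length(candidates))
    for (ci in seq_along(candidates)) {
      Zk <- cov$values[, c(selected, candidates[ci]), drop = FALSE]
      qrZ <- qr(Zk)
      if (qrZ$rank < ncol(Zk)) next  # candidate collinear with current set
      rss_cand[ci] <- sum(qr.resid(qrZ, t(GE))^2)
    }
    if (all(is.na(rss_cand))) break
    aic_cand <- aic_of(pmax(rss_cand, rss_floor), length(selected) + 1)
    best <- which.min(aic_cand)  # which.min takes the first on ties
    if (!is.finite(aic_cand[best]) || aic_cand[best] >= current_aic) break
    step <- step + 1L
    selected <- c(selected, candidates[best])
    current_rss <- rss_cand[best]
    current_aic <- aic_cand[best]
    trace <- rbind(trace, data.frame(step = step, variable = candidates[best],
                                     AIC = current_aic, RSS = current_rss))
    if (current_rss <= rss_floor) perfect <- TRUE
    candidates <- candidates[-best]
  }
  model <- fit_factorial_regression(GE, cov, selected)
  model$aic_trace <- trace
  model$perfect_fit <- perfect
  model
}

#' NIPALS partial least squares regression of the interaction on covariates
#'
#' Extracts paired latent factors from the centered-and-standardized
#' covariate matrix X (environments x variables) and the response matrix Y
#' (environments x genotypes, the transposed doubly-centered interaction) by
#' the iterative NIPALS sequence: weight vector w from the X-projection of a
#' Y column, score t = Xw, loadings p = X't/t't and q = Y't/t't, then
#' deflation of both matrices by t. The share of interaction sum of squares
#' captured by factor a is SS(t_a q_a') / SS(Y) * 100.
#'
#' Sign convention: each factor is flipped so the covariate with the largest
#' absolute X-loading is positive.
#'
#' @param X a centered (typically standardized) `covariate_matrix`, or an
#'   e x K numeric matrix.
#' @param Y e x g response matrix (environments in rows).
#' @param n_factors number of factors A, at most min(e - 1, K).
#' @param tol,max_iter NIPALS inner-loop convergence tolerance on the score
#'   vector and iteration cap.
#' @param ss_floor treat Y as zero when its total SS is at or below this
#'   (an absolute threshold on the response scale); a degenerate all-zero
#'   interaction then reports 0% explained instead of chasing rounding
#'   noise. Default 0 (off).
#' @return A `plsr_model`: list with `T` (e x A X-scores), `P` (K x A
#'   X-loadings), `Q` (g x A Y-loadings), `W` (K x A weights),
#'   `percent_Y_explained`, `cumulative_percent`, residual matrices `E` (X)
#'   and `F` (Y).
#' @export
fit_plsr <- function(X, Y, n_factors = 2, tol = 1e-10, max_iter = 1e4,
                     ss_floor = 0) {
  if (inherits(X, "covariate_matrix")) {
    if (!X$centered) stop("X must be centered (center_covariates)")
    X <- X$values
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  e <- nrow(X); K <- ncol(X)
  if (nrow(Y) != e) stop("X and Y must have the same number of rows")
  if (n_factors > min(e - 1, K)) {
    stop(sprintf("n_factors must be <= min(e-1, K) = %d", min(e - 1, K)))
  }
  ss_y0 <- sum(Y^2)
  if (ss_y0 <= ss_floor) ss_y0 <- 0
  Tm <- matrix(0, e, n_factors); Pm <- matrix(0, K, n_factors)
  Qm <- matrix(0, ncol(Y), n_factors); Wm <- matrix(0, K, n_factors)
  pct <- numeric(n_factors)
  Xa <- X; Ya <- Y
  for (a in seq_len(n_factors)) {
    if (ss_y0 == 0 || sum(Ya^2) <= ss_y0 * 1e-24 || sum(Xa^2) == 0) {
      # response (or predictors) exhausted: remaining factors are null
      break
    }
    u <- Ya[, which.max(colSums(Ya^2))]
    t_old <- rep(Inf, e)
    it <- 0L
    repeat {
      it <- it + 1L
      w <- drop(crossprod(Xa, u))
      w <- w / sqrt(sum(w^2))
      t_new <- drop(Xa %*% w)
      q <- drop(crossprod(Ya, t_new)) / sum(t_new^2)
      u <- drop(Ya %*% q) / sum(q^2)
      if (sqrt(sum((t_new - t_old)^2)) < tol * max(sqrt(sum(t_new^2)), 1e-300)) break
      if (it >= max_iter) {
        stop("NIPALS failed to converge for factor ", a)
      }
      t_old <- t_new
    }
    p <- drop(crossprod(Xa, t_new)) / sum(t_new^2)
    # sign convention: largest-|loading| covariate positive
    k <- which.max(abs(p))
    if (p[k] < 0) {
      w <- -w; t_new <- -t_new; p <- -p; q <- -q
    }
    Tm[, a] <- t_new; Pm[, a] <- p; Qm[, a] <- q; Wm[, a] <- w
    pct[a] <- 100 * sum(outer(t_new, q)^2) / ss_y0
    Xa <- Xa - outer(t_new, p)
    Ya <- Ya - outer(t_new, q)
  }
  fac <- paste0("Factor", seq_len(n_factors))
  dimnames(Tm) <- list(rownames(X), fac)
  dimnames(Pm) <- list(colnames(X), fac)
  dimnames(Qm) <- list(colnames(Y), fac)
  dimnames(Wm) <- list(colnames(X), fac)
  structure(
    list(T = Tm, P = Pm, Q = Qm, W = Wm,
         percent_Y_explained = pct, cumulative_percent = cumsum(pct),
         E = Xa, F = Ya),
    class = "plsr_model"
  )
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("NIPALS PLSR:", ncol(x$T), "factor(s)\n")
  print(data.frame(factor = colnames(x$T),
                   percent_Y = x$percent_Y_explained,
                   cumulative = x$cumulative_percent, row.names = NULL),
        digits = 4)
  invisible(x)
}

#' PLSR biplot coordinates
#'
#' Places environments at their X-scores (t1, t2), covariates at their
#' X-loadings (p1, p2) and genotypes at their Y-loadings (q1, q2) on the
#' first two PLSR factors.
#'
#' @param model a [fit_plsr()] result with at least 2 factors.
#' @return data.frame: `label`, `type` (environment / covariate / genotype),
#'   `Factor1`, `Factor2`; per-factor percent of interaction SS explained is
#'   attached as attribute `percent_Y_explained`.
#' @export
plsr_biplot_coords <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  if (ncol(model$T) < 2) stop("need at least 2 PLSR factors for a biplot")
  out <- rbind(
    data.frame(label = rownames(model$T), type = "environment",
               Factor1 = model$T[, 1], Factor2 = model$T[, 2], row.names = NULL),
    data.frame(label = rownames(model$P), type = "covariate",
               Factor1 = model$P[, 1], Factor2 = model$P[, 2], row.names = NULL),
    data.frame(label = rownames(model$Q), type = "genotype",
               Factor1 = model$Q[, 1], Factor2 = model$Q[, 2], row.names = NULL)
  )
  attr(out, "percent_Y_explained") <- model$percent_Y_explained[1:2]
  out
}
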