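#' Mixed-model (BLUP) genotypic values for a multi-environment trial
#'
#' Fits the MET mixed model with environment and replicate-within-environment
#' as fixed effects and genotype and genotype-by-environment as random
#' effects:
#'
#'   y_ijk = env_j + rep(env)_jk + g_i + ge_ij + eps_ijk,
#'   g_i ~ N(0, sigma2_g), ge_ij ~ N(0, sigma2_ge), eps ~ N(0, sigma2_e).
#'
#' Variance components are estimated by REML and the genotype and
#' interaction effects are BLUPs, i.e. the random-effect predictions shrunk
#' toward zero in proportion to their noise. The genotypic value of genotype
#' i in environment j is GV_ij = u_j + g_i + ge_ij, where u_j is the
#' fixed-effect environment mean (averaged over its blocks).
#'
#' @param data a [met_dataset()] with a complete two-way table and at least
#'   two replicates in some environment.
#' @return list with `varcomp` (sigma2_g, sigma2_ge, sigma2_e, loglik_reml,
#'   converged, singular_fit) and `gv` (class `genotypic_values`: list with
#'   `environment_means` u_j, `g_blup`, `ge_blup` g x e matrix, `GV` g x e
#'   matrix, `grand_mean`).
#' @export
fit_met_mixed_model <- function(data) {
  stopifnot(inherits(data, "met_dataset"))
  if (!any(data$replicates >= 2)) {
    stop("mixed model needs >= 2 replicates in at least one environment")
  }
  rec <- data$records
  rec$genotype <- factor(rec$genotype, levels = data$genotypes)
  rec$environment <- factor(rec$environment, levels = data$environments)
  rec$replicate <- factor(rec$replicate)
  fit <- lme4::lmer(
    yield ~ environment + environment:replicate +
      (1 | genotype) + (1 | genotype:environment),
    data = rec, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    i <- match(grp, vc$grp)
    if (is.na(i)) 0 else vc$vcov[i]
  }
  varcomp <- list(
    sigma2_g = getv("genotype"),
    sigma2_ge = getv("genotype:environment"),
    sigma2_e = getv("Residual"),
    loglik_reml = as.numeric(stats::logLik(fit)),
    converged = length(fit@optinfo$conv$lme4$messages) == 0,
    singular_fit = lme4::isSingular(fit)
  )

  g_id <- data$genotypes; e_id <- data$environments
  g <- length(g_id); e <- length(e_id)
  re <- lme4::ranef(fit)
  g_blup <- stats::setNames(rep(0, g), g_id)
  got <- re$genotype
  g_blup[rownames(got)] <- got[, 1]
  ge_blup <- matrix(0, g, e, dimnames = list(g_id, e_id))
  gxe <- re$`genotype:environment`
  if (!is.null(gxe) && nrow(gxe) > 0) {
    parts <- strsplit(rownames(gxe), ":", fixed = TRUE)
    for (k in seq_along(parts)) {
      ge_blup[parts[[k]][1], parts[[k]][2]] <- gxe[k, 1]
    }
  }
  # fixed-effect environment means, averaged over that environment's blocks
  fixed_fit <- stats::setNames(
    as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit)),
    as.character(rec$environment))
  u <- vapply(e_id, function(env) mean(fixed_fit[names(fixed_fit) == env]), 0)
  GV <- sweep(ge_blup + g_blup, 2, u, `+`)
  gv <- structure(
    list(environment_means = u, g_blup = g_blup, ge_blup = ge_blup,
         GV = GV, grand_mean = mean(u)),
    class = "genotypic_values"
  )
  list(varcomp = varcomp, gv = gv)
}

.check_gv <- function(gv) stopifnot(inherits(gv, "genotypic_values"))

#' Harmonic mean of genotypic values (HMGV)
#'
#' HMGV_i = e / sum_j (1 / GV_ij): the harmonic mean over environments of
#' the genotypic values. The harmonic mean penalizes genotypes whose value
#' collapses in any environment, so high HMGV reads as yield plus stability
#' on the kg/ha scale.
#'
#' @param gv a `genotypic_values` object (all GV must be positive).
#' @return named per-genotype vector, kg/ha; larger = better.
#' @export
hmgv <- function(gv) {
  .check_gv(gv)
  bad <- which(gv$GV <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("harmonic mean undefined: GV <= 0 at (%s, %s)",
                 rownames(gv$GV)[bad[1, 1]], colnames(gv$GV)[bad[1, 2]]))
  }
  ncol(gv$GV) / rowSums(1 / gv$GV)
}

#' Relative performance of genotypic values (RPGV)
#'
#' RPGV_i = (1/e) sum_j GV_ij / u_j: each genotypic value expressed relative
#' to its environment mean, then averaged. Dimensionless; 1 means average
#' performance, and the statistic is invariant to rescaling all yields.
#'
#' @param gv a `genotypic_values` object (environment means must be
#'   positive).
#' @return named per-genotype vector; larger = better adaptability.
#' @export
rpgv <- function(gv) {
  .check_gv(gv)
  if (any(gv$environment_means <= 0)) {
    stop("RPGV undefined: non-positive environment mean(s): ",
         paste(names(gv$environment_means)[gv$environment_means <= 0], collapse = ", "))
  }
  rowMeans(sweep(gv$GV, 2, gv$environment_means, `/`))
}

#' Harmonic mean of relative performance of genotypic values (HMRPGV)
#'
#' HMRPGV_i = e / sum_j (u_j / GV_ij): the harmonic mean over environments
#' of the per-environment relative values GV_ij / u_j. Combines yield level,
#' stability (harmonic-mean penalty) and adaptability (relative scale) in
#' one statistic; multiplied by the grand mean it returns to kg/ha.
#'
#' @param gv a `genotypic_values` object.
#' @param grand_mean mean used for the kg/ha rescaling; defaults to the
#'   mean of the environment means.
#' @return data.frame with per-genotype `HMRPGV` and `HMRPGV_x_mu`.
#' @export
hmrpgv <- function(gv, grand_mean = gv$grand_mean) {
  .check_gv(gv)
  ratios <- sweep(gv$GV, 2, gv$environment_means, `/`)
  if (any(ratios <= 0)) stop("HMRPGV undefined: non-positive GV/u ratio")
  h <- ncol(ratios) / rowSums(1 / ratios)
  data.frame(genotype = rownames(gv$GV), HMRPGV = unname(h),
             HMRPGV_x_mu = unname(h * grand_mean), row.names = NULL)
}

#' BLUP stability-adaptability table
#'
#' Assembles HMGV, RPGV and HMRPGV (and HMRPGV times the grand mean) with
#' descending ranks (rank 1 = best).
#'
#' @param gv a `genotypic_values` object.
#' @return data.frame: genotype, HMGV, RPGV, HMRPGV, HMRPGV_x_mu and a rank
#'   column per statistic.
#' @export
hmrpgv_table <- function(gv) {
  .check_gv(gv)
  h <- hmgv(gv); r <- rpgv(gv); hr <- hmrpgv(gv)
  out <- data.frame(genotype = rownames(gv$GV),
                    HMGV = unname(h), RPGV = unname(r),
                    HMRPGV = hr$HMRPGV, HMRPGV_x_mu = hr$HMRPGV_x_mu,
                    row.names = NULL)
  out$rank_HMGV <- as.integer(rank(-out$HMGV, ties.method = "min"))
  out$rank_RPGV <- as.integer(rank(-out$RPGV, ties.method = "min"))
  out$rank_HMRPGV <- as.integer(rank(-out$HMRPGV, ties.method = "min"))
  out
}
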