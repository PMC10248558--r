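#' Run the full stability-analysis pipeline
#'
#' Orchestrates every stage over one trial: combined ANOVA, AMMI
#' decomposition with Gollob tests and biplot coordinates, the AMMI
#' stability indices with simultaneous selection indices, the BLUP mixed
#' model with the HMGV/RPGV/HMRPGV table, and — when covariates are supplied
#' — factorial regression with AIC forward selection and NIPALS PLSR. The
#' analytical stages are skipped with a notice when `covariates` is `NULL`.
#'
#' @param data a [met_dataset()] (or a path to a trial CSV).
#' @param covariates optional `covariate_matrix` (or path to a covariate
#'   CSV), uncentered; centering/standardization happens internally.
#' @param alpha significance level for the Gollob scan.
#' @param plsr_factors number of PLSR factors to extract.
#' @param out_dir optional directory; when given, every stage's table is
#'   written as CSV plus a consolidated `report.json`.
#' @return A `met_report` list with elements `anova`, `ammi`, `stability`,
#'   `blup`, `fr`, `plsr` (the last two `NULL` without covariates) and
#'   `skipped` naming stages not run.
#' @export
run_met_pipeline <- function(data, covariates = NULL, alpha = 0.05,
                             plsr_factors = 2, out_dir = NULL) {
  if (is.character(data)) data <- read_met_csv(data)
  stopifnot(inherits(data, "met_dataset"))
  if (is.character(covariates)) {
    covariates <- read_covariates_csv(covariates, data$environments)
  }

  gem <- compute_ge_means(data)
  anova <- combined_anova(data)
  am <- ammi_decompose(gem)
  if (anova$has_error_term) am <- gollob_test(am, anova, alpha)
  stab <- stability_indices(am)
  bl <- fit_met_mixed_model(data)
  hm <- hmrpgv_table(bl$gv)
  skipped <- character(0)
  fr <- NULL; pl <- NULL
  if (is.null(covariates)) {
    message("no covariates supplied: skipping factorial regression and PLSR")
    skipped <- c("factorial_regression", "plsr")
  } else {
    cen <- center_covariates(covariates)
    fr <- stepwise_fr_aic(gem$interaction, cen)
    std <- center_covariates(covariates, standardize = TRUE)
    A <- min(plsr_factors, ncol(std$values), ncol(gem$interaction) - 1)
    floor_ss <- (1e-9 * max(1, abs(gem$grand_mean)))^2 *
      length(gem$interaction)
    pl <- fit_plsr(std, t(gem$interaction), n_factors = A,
                   ss_floor = floor_ss)
  }
  report <- structure(
    list(means = gem, anova = anova, ammi = am, stability = stab,
         varcomp = bl$varcomp, gv = bl$gv, hmrpgv = hm,
         fr = fr, plsr = pl, skipped = skipped, alpha = alpha),
    class = "met_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write every pipeline table plus a consolidated JSON report
#'
#' @param report a `met_report` from [run_met_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "met_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  w(report$anova$table, "anova.csv")
  scores <- data.frame(genotype = rownames(report$ammi$genotype_scores),
                       report$ammi$genotype_scores, check.names = FALSE)
  w(scores, "ammi_genotype_scores.csv")
  escores <- data.frame(environment = rownames(report$ammi$environment_scores),
                        report$ammi$environment_scores, check.names = FALSE)
  w(escores, "ammi_environment_scores.csv")
  if (!is.null(report$ammi$gollob)) w(report$ammi$gollob, "gollob.csv")
  w(ammi1_coords(report$ammi), "ammi1_coords.csv")
  if (length(report$ammi$singular_values) >= 2) {
    w(ammi2_coords(report$ammi), "ammi2_coords.csv")
  }
  w(report$stability, "stability.csv")
  w(report$hmrpgv, "hmrpgv.csv")
  if (!is.null(report$fr)) {
    w(report$fr$aic_trace, "fr_steps.csv")
    xi <- data.frame(genotype = rownames(report$fr$xi), report$fr$xi,
                     check.names = FALSE)
    w(xi, "fr_sensitivities.csv")
  }
  if (!is.null(report$plsr)) {
    w(plsr_biplot_coords(report$plsr), "plsr_biplot.csv")
  }
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Summarize a pipeline report as a plain list (JSON-ready)
#'
#' Full-precision values plus display-rounded (2 dp) copies of the headline
#' numbers.
#'
#' @param report a `met_report`.
#' @return nested list with a versioned `schema` field.
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "met_report"))
  at <- report$anova$table
  pct <- stats::setNames(at$percent_of_total, at$source)
  theta <- report$ammi$percent_explained
  out <- list(
    schema = "metstab-report/1",
    grand_mean = report$means$grand_mean,
    anova_percent_of_total = as.list(pct[names(pct) != "total"]),
    theta_percent = theta,
    theta_percent_rounded = round(theta, 2),
    n_significant_axes = report$ammi$n_significant,
    variance_components = report$varcomp[c("sigma2_g", "sigma2_ge", "sigma2_e")],
    stability = report$stability,
    hmrpgv = report$hmrpgv,
    analytical = if (length(report$skipped) > 0) NULL else list(
      fr_selected = report$fr$selected_variables,
      fr_percent_explained = as.list(report$fr$percent_explained),
      fr_aic_trace = report$fr$aic_trace,
      plsr_percent_Y_explained = report$plsr$percent_Y_explained,
      plsr_percent_rounded = round(report$plsr$percent_Y_explained, 2)
    ),
    skipped = report$skipped
  )
  out
}

#' @export
print.met_report <- function(x, ...) {
  cat("MET stability report\n")
  cat(sprintf("grand mean %.2f kg/ha; theta: %s\n", x$means$grand_mean,
              paste(sprintf("%.1f%%", x$ammi$percent_explained), collapse = " ")))
  if (!is.null(x$ammi$n_significant))
    cat("significant axes:", x$ammi$n_significant, "\n")
  if (length(x$skipped) > 0)
    cat("skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
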