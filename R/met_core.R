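#' Construct a multi-environment trial dataset
#'
#' Validates and packages long-format plot records from a multi-environment
#' trial (MET): one record per plot with genotype, environment, replicate
#' (block) and yield. The trial must be a randomized complete block design
#' within each environment: every genotype observed the same number of times
#' in a given environment. Replicate counts may differ across environments
#' (site-years with different block numbers are common).
#'
#' @param records data.frame with columns `genotype`, `environment`,
#'   `replicate`, `yield`. Yields are in kg/ha and must be finite; negative
#'   yields are flagged with a warning here and rejected outright by
#'   [read_met_csv()] (field data should never contain them, but a synthetic
#'   spec with heavy noise can produce stray negatives).
#' @return An object of class `met_dataset`: a list with `records` (the
#'   validated data.frame with factor-free character identifiers),
#'   `genotypes`, `environments` (identifier vectors in first-appearance
#'   order), and `replicates` (named integer vector, replicate count per
#'   environment).
#' @export
met_dataset <- function(records) {
  req <- c("genotype", "environment", "replicate", "yield")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, req]
  records$genotype <- as.character(records$genotype)
  records$environment <- as.character(records$environment)
  records$replicate <- as.character(records$replicate)
  if (any(!nzchar(records$genotype)) || any(!nzchar(records$environment)) ||
      any(!nzchar(records$replicate))) {
    stop("genotype, environment and replicate identifiers must be non-empty")
  }
  if (!is.numeric(records$yield)) {
    bad <- which(is.na(suppressWarnings(as.numeric(records$yield))))
    stop("non-numeric yield at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(!is.finite(records$yield))) {
    stop("non-finite yield at row(s): ",
         paste(utils::head(which(!is.finite(records$yield)), 5), collapse = ", "))
  }
  if (any(records$yield < 0)) {
    warning("negative yield at row(s): ",
            paste(utils::head(which(records$yield < 0), 5), collapse = ", "))
  }
  key <- paste(records$genotype, records$environment, records$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[which(duplicated(key))[1], ]
    stop(sprintf("duplicate plot record (%s, %s, %s)",
                 d$genotype, d$environment, d$replicate))
  }
  genotypes <- unique(records$genotype)
  environments <- unique(records$environment)
  if (length(genotypes) < 2 || length(environments) < 2) {
    stop("need at least 2 genotypes and 2 environments")
  }
  # within-environment balance: every genotype present with equal replication
  reps <- integer(length(environments))
  names(reps) <- environments
  for (env in environments) {
    sub <- records[records$environment == env, ]
    tab <- table(sub$genotype)
    if (length(tab) < length(genotypes) || length(unique(as.integer(tab))) != 1) {
      stop(sprintf("unequal replicate counts within environment %s", env))
    }
    reps[env] <- as.integer(tab[1])
  }
  structure(
    list(records = records, genotypes = genotypes,
         environments = environments, replicates = reps),
    class = "met_dataset"
  )
}

#' @export
print.met_dataset <- function(x, ...) {
  cat(sprintf("MET dataset: %d genotypes x %d environments, %d plots\n",
              length(x$genotypes), length(x$environments), nrow(x$records)))
  cat("replicates per environment:",
      paste(sprintf("%s=%d", names(x$replicates), x$replicates), collapse = " "), "\n")
  invisible(x)
}

#' Read a multi-environment trial from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row. Default column
#' names are `genotype,environment,replicate,yield`; `column_map` renames
#' them (e.g. `c(genotype = "gen", yield = "GY")`).
#'
#' @param path path to the CSV file.
#' @param column_map optional named character vector mapping the canonical
#'   names to the file's column names.
#' @return A validated [met_dataset()]. Genotype and environment order is
#'   first appearance in the file.
#' @export
read_met_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("genotype", "environment", "replicate", "yield")
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(raw)) {
        stop("mapped column not in file: ", column_map[[nm]])
      }
      names(raw)[names(raw) == column_map[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(canonical, names(raw))
  if (length(missing_cols) > 0) {
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.numeric(raw$yield) && any(raw$yield < 0, na.rm = TRUE)) {
    stop("negative yield at row(s): ",
         paste(utils::head(which(raw$yield < 0), 5), collapse = ", "))
  }
  met_dataset(raw[, canonical])
}

#' Write a multi-environment trial to CSV
#'
#' Inverse of [read_met_csv()]: writes the plot records with the canonical
#' column order so that write-then-read round-trips the dataset.
#'
#' @param data a [met_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_met_csv <- function(data, path) {
  stopifnot(inherits(data, "met_dataset"))
  utils::write.csv(data$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Genotype-by-environment means and the additive decomposition
#'
#' Averages plot yields over replicates into the g x e cell-means matrix and
#' splits it into grand mean, genotype main effects, environment main effects
#' and the doubly-centered interaction: means = mu + alpha_i + beta_j + ge_ij.
#' Main effects each sum to zero; every row and column of the interaction
#' matrix sums to zero. This interaction matrix is the substrate of the AMMI
#' decomposition, factorial regression and PLSR.
#'
#' @param data a [met_dataset()]. The two-way table must be complete.
#' @return An object of class `ge_means`: list with `means` (g x e matrix,
#'   genotypes in rows), `grand_mean`, `genotype_effects`,
#'   `environment_effects`, `interaction` (g x e doubly-centered matrix),
#'   and `replicates` carried over from the dataset.
#' @export
compute_ge_means <- function(data) {
  stopifnot(inherits(data, "met_dataset"))
  g <- length(data$genotypes); e <- length(data$environments)
  rec <- data$records
  gi <- match(rec$genotype, data$genotypes)
  ej <- match(rec$environment, data$environments)
  sums <- matrix(0, g, e, dimnames = list(data$genotypes, data$environments))
  counts <- matrix(0L, g, e)
  for (k in seq_len(nrow(rec))) {
    sums[gi[k], ej[k]] <- sums[gi[k], ej[k]] + rec$yield[k]
    counts[gi[k], ej[k]] <- counts[gi[k], ej[k]] + 1L
  }
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)
    cells <- apply(empty, 1, function(ix)
      paste0("(", data$genotypes[ix[1]], ",", data$environments[ix[2]], ")"))
    stop("incomplete two-way table; empty cell(s): ",
         paste(utils::head(cells, 10), collapse = " "))
  }
  means <- sums / counts
  mu <- mean(means)
  alpha <- rowMeans(means) - mu
  beta <- colMeans(means) - mu
  interaction <- means - outer(alpha, beta, `+`) - mu
  structure(
    list(means = means, grand_mean = mu, genotype_effects = alpha,
         environment_effects = beta, interaction = interaction,
         replicates = data$replicates),
    class = "ge_means"
  )
}

#' Write the cell means and additive decomposition to CSV
#'
#' One row per genotype: the e cell means followed by the genotype main
#' effect; trailing rows carry the environment effects and grand mean.
#'
#' @param gem a [compute_ge_means()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ge_means_csv <- function(gem, path) {
  stopifnot(inherits(gem, "ge_means"))
  df <- data.frame(genotype = rownames(gem$means),
                   gem$means, check.names = FALSE)
  df$genotype_effect <- gem$genotype_effects
  env_row <- data.frame(genotype = "<environment_effect>",
                        t(gem$environment_effects), check.names = FALSE)
  env_row$genotype_effect <- NA_real_
  mu_row <- df[1, ]; mu_row[,] <- NA
  mu_row$genotype <- "<grand_mean>"
  mu_row[[2]] <- gem$grand_mean
  out <- rbind(df, env_row, mu_row)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read environment-level covariates from CSV
#'
#' The file has one row per environment: a column named `environment` plus
#' one numeric column per climatic variable (e.g. seasonal rainfall in mm,
#' seasonal mean temperature in degrees C). Rows are reordered to match the
#' trial's environment order.
#'
#' @param path path to the CSV file.
#' @param environments environment identifiers in trial order.
#' @param strict if `TRUE` (default), a file row whose environment is not in
#'   `environments` is an error; if `FALSE` it is dropped with a warning.
#' @return A `covariate_matrix`: list with `values` (e x K numeric matrix,
#'   rownames = environments), `variables`, and flags `centered`,
#'   `standardized` (both `FALSE`).
#' @export
read_covariates_csv <- function(path, environments, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"environment" %in% names(raw)) stop("covariate CSV needs an 'environment' column")
  raw$environment <- as.character(raw$environment)
  extra <- setdiff(raw$environment, environments)
  if (length(extra) > 0) {
    if (strict) stop("covariate file has unknown environment(s): ",
                     paste(extra, collapse = ", "))
    warning("dropping covariate rows for unknown environment(s): ",
            paste(extra, collapse = ", "))
    raw <- raw[raw$environment %in% environments, ]
  }
  miss <- setdiff(environments, raw$environment)
  if (length(miss) > 0) stop("covariate file lacks environment(s): ",
                             paste(miss, collapse = ", "))
  raw <- raw[match(environments, raw$environment), ]
  vars <- setdiff(names(raw), "environment")
  if (anyDuplicated(vars)) stop("duplicate covariate variable names")
  values <- as.matrix(raw[, vars, drop = FALSE])
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("covariate values must be finite numerics")
  }
  rownames(values) <- environments
  covariate_matrix(values)
}

#' Construct a covariate matrix object
#'
#' @param values e x K numeric matrix with environment rownames.
#' @param centered,standardized processing flags.
#' @return A `covariate_matrix` object.
#' @export
covariate_matrix <- function(values, centered = FALSE, standardized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("z", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate covariate variable names")
  structure(
    list(values = values, variables = colnames(values),
         centered = centered, standardized = standardized),
    class = "covariate_matrix"
  )
}

#' Center (and optionally standardize) covariate columns
#'
#' Column-centers each environmental variable to mean zero, as required
#' before regressing the doubly-centered interaction on covariates. With
#' `standardize = TRUE` each column is additionally scaled to unit sample
#' standard deviation (used by PLSR, where rainfall in mm and temperature in
#' degrees C would otherwise carry incommensurate weight). Idempotent.
#'
#' @param cov a `covariate_matrix`.
#' @param standardize scale columns to unit sample sd as well.
#' @return A centered `covariate_matrix`.
#' @export
center_covariates <- function(cov, standardize = FALSE) {
  stopifnot(inherits(cov, "covariate_matrix"))
  v <- sweep(cov$values, 2, colMeans(cov$values))
  if (standardize) {
    sds <- apply(v, 2, stats::sd)
    zero <- sds < .Machine$double.eps^0.5
    if (any(zero)) {
      stop("zero-variance covariate column under standardize: ",
           paste(colnames(v)[zero], collapse = ", "))
    }
    v <- sweep(v, 2, sds, `/`)
  }
  covariate_matrix(v, centered = TRUE,
                   standardized = standardize || cov$standardized)
}

#' Write a covariate matrix to CSV
#' @param cov a `covariate_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_covariates_csv <- function(cov, path) {
  stopifnot(inherits(cov, "covariate_matrix"))
  df <- data.frame(environment = rownames(cov$values), cov$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
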