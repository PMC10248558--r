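#' Combined analysis of variance for a multi-environment RCBD trial
#'
#' Least-squares partition of plot yields combined over environments:
#' environment, replicate-within-environment, genotype, genotype x
#' environment, and pooled error. Genotype and the interaction are tested
#' against the pooled error; environment is tested against the
#' replicate-within-environment mean square, the standard choice when blocks
#' are the replication unit for environments.
#'
#' With a single replicate everywhere the error term is undefined: the
#' partition is still returned (with the interaction absorbing what would be
#' error) but F and p are `NA` and `has_error_term` is `FALSE`.
#'
#' @param data a [met_dataset()] with a complete two-way table.
#' @return A `combined_anova` object: list with `table` (data.frame: source,
#'   df, SS, MS, F, p, percent_of_total) and `has_error_term`.
#' @export
combined_anova <- function(data) {
  stopifnot(inherits(data, "met_dataset"))
  rec <- data$records
  rec$genotype <- factor(rec$genotype, levels = data$genotypes)
  rec$environment <- factor(rec$environment, levels = data$environments)
  rec$replicate <- factor(rec$replicate)
  has_error <- any(data$replicates >= 2)

  form <- if (nlevels(rec$replicate) >= 2) {
    yield ~ environment + environment:replicate +
      genotype + genotype:environment
  } else {
    yield ~ environment + genotype + genotype:environment
  }
  fit <- stats::aov(form, data = rec)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  pick <- function(...) {
    i <- stats::na.omit(match(c(...), rn))[1]
    if (is.na(i)) c(df = 0, ss = 0) else c(df = tab[i, "Df"], ss = tab[i, "Sum Sq"])
  }
  env <- pick("environment")
  repw <- pick("environment:replicate", "replicate:environment")
  gen <- pick("genotype")
  gxe <- pick("genotype:environment", "environment:genotype")
  err <- pick("Residuals")

  df <- c(env["df"], repw["df"], gen["df"], gxe["df"], err["df"])
  ss <- c(env["ss"], repw["ss"], gen["ss"], gxe["ss"], err["ss"])
  src <- c("environment", "replicate_within_environment", "genotype",
           "genotype_x_environment", "error")
  ms <- ifelse(df > 0, ss / df, NA_real_)
  names(ms) <- src
  Fv <- rep(NA_real_, 5); pv <- rep(NA_real_, 5)
  if (has_error && df[5] > 0) {
    for (i in c(3, 4)) {  # genotype, GxE vs pooled error
      Fv[i] <- ms[i] / ms[5]
      pv[i] <- stats::pf(Fv[i], df[i], df[5], lower.tail = FALSE)
    }
    if (df[2] > 0) {
      Fv[1] <- ms[1] / ms[2]  # environment vs rep-within-env
      pv[1] <- stats::pf(Fv[1], df[1], df[2], lower.tail = FALSE)
      Fv[2] <- ms[2] / ms[5]
      pv[2] <- stats::pf(Fv[2], df[2], df[5], lower.tail = FALSE)
    }
  }
  ss_total <- sum(ss); df_total <- sum(df)
  out <- data.frame(
    source = c(src, "total"),
    df = c(df, df_total),
    SS = c(ss, ss_total),
    MS = c(ms, NA_real_),
    F = c(Fv, NA_real_),
    p = c(pv, NA_real_),
    percent_of_total = c(if (ss_total > 0) 100 * ss / ss_total else rep(0, 5), 100),
    row.names = NULL
  )
  structure(list(table = out, has_error_term = has_error),
            class = "combined_anova")
}

#' @export
print.combined_anova <- function(x, ...) {
  cat("Combined ANOVA (RCBD over environments)\n")
  print(x$table, digits = 5)
  invisible(x)
}

#' AMMI decomposition of the genotype-by-environment interaction
#'
#' Singular value decomposition of the doubly-centered g x e interaction
#' matrix from [compute_ge_means()]. Scores use the symmetric scaling:
#' genotype scores s_in = sqrt(lambda_n) gamma_in and environment scores
#' sqrt(lambda_n) delta_jn, so that each axis' score sum of squares equals
#' lambda_n on both sides. The percentage of interaction sum of squares
#' explained by axis n is theta_n = lambda_n^2 / sum(lambda^2) * 100, and the
#' interaction SS carried by axis n on the plot-data scale is r * lambda_n^2.
#'
#' Sign convention: each axis is flipped so that the genotype with the
#' largest absolute eigenvector entry has a positive score (the SVD sign is
#' otherwise arbitrary).
#'
#' @param means a [compute_ge_means()] result.
#' @param replicates replicate count r used to put axis SS on the plot-data
#'   scale; defaults to the mean replicate count of the dataset.
#' @return An `ammi_result`: list with `singular_values`, `eigenvalues`,
#'   `genotype_scores` (g x p), `environment_scores` (e x p),
#'   `genotype_eigenvectors` (unit-norm gamma), `environment_eigenvectors`,
#'   `percent_explained` (theta, %), `cumulative_percent`, `ss_ipc`
#'   (r * lambda^2), `replicates`, `zero_interaction` flag, and the parent
#'   `means` object.
#' @export
ammi_decompose <- function(means, replicates = NULL) {
  stopifnot(inherits(means, "ge_means"))
  if (is.null(replicates)) replicates <- mean(means$replicates)
  ge <- means$interaction
  g <- nrow(ge); e <- ncol(ge)
  p <- min(g - 1, e - 1)
  sv <- svd(ge, nu = p, nv = p)
  lambda <- sv$d[seq_len(p)]
  U <- sv$u; V <- sv$v
  # sign convention: largest |gamma| entry positive on each axis
  for (n in seq_len(p)) {
    k <- which.max(abs(U[, n]))
    if (U[k, n] < 0) {
      U[, n] <- -U[, n]; V[, n] <- -V[, n]
    }
  }
  zero_int <- sqrt(sum(lambda^2)) <
    1e-9 * max(1, abs(means$grand_mean)) * sqrt(g * e)
  sqrt_l <- sqrt(lambda)
  gsc <- sweep(U, 2, sqrt_l, `*`)
  esc <- sweep(V, 2, sqrt_l, `*`)
  axis <- paste0("IPC", seq_len(p))
  dimnames(gsc) <- list(rownames(ge), axis)
  dimnames(esc) <- list(colnames(ge), axis)
  dimnames(U) <- dimnames(gsc); dimnames(V) <- dimnames(esc)
  theta <- if (zero_int) rep(0, p) else 100 * lambda^2 / sum(lambda^2)
  structure(
    list(singular_values = lambda, eigenvalues = lambda^2,
         genotype_scores = gsc, environment_scores = esc,
         genotype_eigenvectors = U, environment_eigenvectors = V,
         percent_explained = theta, cumulative_percent = cumsum(theta),
         ss_ipc = replicates * lambda^2, replicates = replicates,
         zero_interaction = zero_int, means = means,
         gollob = NULL, n_significant = NULL),
    class = "ammi_result"
  )
}

#' @export
print.ammi_result <- function(x, ...) {
  p <- length(x$singular_values)
  cat(sprintf("AMMI decomposition: %d axes\n", p))
  df <- data.frame(axis = paste0("IPC", seq_len(p)),
                   singular_value = x$singular_values,
                   percent_explained = x$percent_explained,
                   cumulative = x$cumulative_percent)
  if (!is.null(x$gollob)) df <- cbind(df, x$gollob[, c("df", "F", "p")])
  print(df, digits = 4)
  if (!is.null(x$n_significant))
    cat("significant axes (Gollob):", x$n_significant, "\n")
  invisible(x)
}

#' Gollob F-tests for the interaction principal components
#'
#' Tests each IPC against the pooled error from the combined ANOVA using
#' Gollob's degrees of freedom df_n = g + e - 1 - 2n, with axis mean square
#' r * lambda_n^2 / df_n. The number of significant axes N' is found by
#' scanning axes in order and stopping at the first non-significant one;
#' N' has a floor of 1 so downstream indices are always defined.
#'
#' @param ammi an [ammi_decompose()] result.
#' @param anova the matching [combined_anova()].
#' @param alpha significance level in (0, 1).
#' @return The `ammi_result` with `gollob` (data.frame: axis, df, SS, MS, F,
#'   p, significant) and `n_significant` filled in.
#' @export
gollob_test <- function(ammi, anova, alpha = 0.05) {
  stopifnot(inherits(ammi, "ammi_result"), inherits(anova, "combined_anova"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tab <- anova$table
  err <- tab[tab$source == "error", ]
  if (!anova$has_error_term || err$df == 0) {
    stop("Gollob test needs a pooled error term (>= 2 replicates somewhere)")
  }
  g <- nrow(ammi$genotype_scores); e <- nrow(ammi$environment_scores)
  p <- length(ammi$singular_values)
  n <- seq_len(p)
  df_n <- g + e - 1 - 2 * n
  ss_n <- ammi$ss_ipc
  ms_n <- ss_n / df_n
  Fv <- ms_n / err$MS
  pv <- stats::pf(Fv, df_n, err$df, lower.tail = FALSE)
  sig <- pv < alpha
  # scan from axis 1, stop at first non-significant; floor of 1
  n_sig <- 0L
  for (i in n) {
    if (isTRUE(sig[i])) n_sig <- i else break
  }
  n_sig <- max(n_sig, 1L)
  ammi$gollob <- data.frame(axis = paste0("IPC", n), df = df_n, SS = ss_n,
                            MS = ms_n, F = Fv, p = pv, significant = sig)
  ammi$n_significant <- n_sig
  ammi
}

#' AMMI1 biplot coordinates (mean yield vs IPC1 score)
#'
#' @param ammi an [ammi_decompose()] result.
#' @return data.frame with one row per genotype and per environment:
#'   `label`, `type`, `mean` (genotype mean over environments, or environment
#'   mean), `IPC1`. The grand mean is attached as attribute `grand_mean`
#'   (the vertical reference line of the biplot).
#' @export
ammi1_coords <- function(ammi) {
  stopifnot(inherits(ammi, "ammi_result"))
  m <- ammi$means
  gdf <- data.frame(label = rownames(m$means), type = "genotype",
                    mean = rowMeans(m$means),
                    IPC1 = ammi$genotype_scores[, 1], row.names = NULL)
  edf <- data.frame(label = colnames(m$means), type = "environment",
                    mean = colMeans(m$means),
                    IPC1 = ammi$environment_scores[, 1], row.names = NULL)
  out <- rbind(gdf, edf)
  attr(out, "grand_mean") <- m$grand_mean
  out
}

#' AMMI2 biplot coordinates (IPC1 vs IPC2)
#'
#' @param ammi an [ammi_decompose()] result with at least two axes.
#' @return data.frame with one row per genotype and environment: `label`,
#'   `type`, `IPC1`, `IPC2`, `distance` from the origin (the stability /
#'   vector-length reading of the biplot).
#' @export
ammi2_coords <- function(ammi) {
  stopifnot(inherits(ammi, "ammi_result"))
  if (length(ammi$singular_values) < 2) {
    stop("fewer than 2 interaction axes; use ammi1_coords()")
  }
  gdf <- data.frame(label = rownames(ammi$genotype_scores), type = "genotype",
                    IPC1 = ammi$genotype_scores[, 1],
                    IPC2 = ammi$genotype_scores[, 2], row.names = NULL)
  edf <- data.frame(label = rownames(ammi$environment_scores), type = "environment",
                    IPC1 = ammi$environment_scores[, 1],
                    IPC2 = ammi$environment_scores[, 2], row.names = NULL)
  out <- rbind(gdf, edf)
  out$distance <- sqrt(out$IPC1^2 + out$IPC2^2)
  out
}
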