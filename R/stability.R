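#' AMMI stability value (ASV)
#'
#' ASV_i = sqrt( ((SS_IPC1/SS_IPC2) * IPC1_i)^2 + IPC2_i^2 ): the distance
#' from the origin in the plane of the first two interaction axes, with the
#' first axis stretched by the ratio of the two axes' sums of squares so
#' that its larger share of the interaction carries more weight.
#'
#' @param scores g x p matrix of scaled genotype IPC scores (p >= 2).
#' @param ss_ipc1,ss_ipc2 interaction sums of squares of axes 1 and 2.
#' @return named per-genotype vector; smaller = more stable.
#' @export
asv <- function(scores, ss_ipc1, ss_ipc2) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("ASV needs at least 2 IPC axes")
  if (ss_ipc2 <= 0) stop("SS of IPC2 is zero (rank-1 interaction); ASV undefined")
  w <- ss_ipc1 / ss_ipc2
  sqrt((w * scores[, 1])^2 + scores[, 2]^2)
}

#' Sum of absolute IPC scores (SIPC)
#'
#' SIPC_i = sum over the first `n_axes` axes of |s_in| on the scaled scores.
#' With `n_axes = 1` this is SIPC1; with all retained axes it is SIPCF.
#'
#' @param scores g x p matrix of scaled genotype IPC scores.
#' @param n_axes number of axes to sum over (defaults to all).
#' @return named per-genotype vector; smaller = more stable.
#' @export
sipc <- function(scores, n_axes = ncol(scores)) {
  scores <- as.matrix(scores)
  .check_axes(n_axes, ncol(scores))
  rowSums(abs(scores[, seq_len(n_axes), drop = FALSE]))
}

#' Averaged squared eigenvector values (EV)
#'
#' EV_i = sum_{n=1..N'} gamma_in^2 / N' on the unit-norm genotype
#' eigenvectors; each column has unit sum of squares, so EV sums to 1 over
#' genotypes.
#'
#' @param gamma g x p matrix of unit-norm genotype eigenvectors.
#' @param n_axes number of significant axes N'.
#' @return named per-genotype vector; smaller = more stable.
#' @export
ev <- function(gamma, n_axes = ncol(gamma)) {
  gamma <- as.matrix(gamma)
  .check_axes(n_axes, ncol(gamma))
  rowSums(gamma[, seq_len(n_axes), drop = FALSE]^2) / n_axes
}

#' Absolute contribution to the interaction (Za)
#'
#' Za_i = sum_{n=1..N'} |theta_n * gamma_in|, the eigenvector entries
#' weighted by each axis' share theta_n of the interaction sum of squares
#' (as a proportion in [0, 1]).
#'
#' @param gamma g x p matrix of unit-norm genotype eigenvectors.
#' @param theta per-axis proportion of interaction SS, in [0, 1].
#' @param n_axes number of significant axes N'.
#' @return named per-genotype vector; smaller = more stable.
#' @export
za <- function(gamma, theta, n_axes = length(theta)) {
  gamma <- as.matrix(gamma)
  .check_axes(n_axes, ncol(gamma))
  if (any(theta[seq_len(n_axes)] < 0) || any(theta[seq_len(n_axes)] > 1)) {
    stop("theta must be proportions in [0, 1]")
  }
  idx <- seq_len(n_axes)
  rowSums(abs(sweep(gamma[, idx, drop = FALSE], 2, theta[idx], `*`)))
}

#' Modified AMMI stability value (MASV)
#'
#' MASV_i = sqrt( sum_{n=1..N'-1} ((SS_n/SS_{n+1}) * PC_ni)^2 + PC_N'i^2 ):
#' the ASV construction extended over the first N' axes, each score
#' stretched by its axis' SS relative to the next before squaring. With
#' N' = 2 it reduces exactly to ASV.
#'
#' @param scores g x p matrix of scaled genotype IPC scores.
#' @param ss_ipc per-axis interaction sums of squares (at least N' entries).
#' @param n_axes number of significant axes N' (>= 2).
#' @return named per-genotype vector; smaller = more stable.
#' @export
masv <- function(scores, ss_ipc, n_axes) {
  scores <- as.matrix(scores)
  if (n_axes < 2) stop("MASV needs N' >= 2")
  .check_axes(n_axes, ncol(scores))
  if (any(ss_ipc[seq_len(n_axes)] <= 0)) {
    stop("MASV undefined: zero SS among the first ", n_axes, " axes")
  }
  acc <- scores[, n_axes]^2
  for (n in seq_len(n_axes - 1)) {
    acc <- acc + ((ss_ipc[n] / ss_ipc[n + 1]) * scores[, n])^2
  }
  sqrt(acc)
}

#' AMMI distance from the origin (D)
#'
#' D_i = sqrt( sum_{n=1..N'} s_in^2 ): the Euclidean distance of genotype i
#' from the origin in the space of the first N' scaled interaction axes.
#'
#' @param scores g x p matrix of scaled genotype IPC scores.
#' @param n_axes number of axes N'.
#' @return named per-genotype vector; smaller = more stable.
#' @export
ammi_distance <- function(scores, n_axes = ncol(scores)) {
  scores <- as.matrix(scores)
  .check_axes(n_axes, ncol(scores))
  sqrt(rowSums(scores[, seq_len(n_axes), drop = FALSE]^2))
}

#' Weighted average of absolute scores (WAAS)
#'
#' WAAS_i = sum_k |IPC_ik| * theta_k / sum_k theta_k: the absolute scaled
#' scores averaged with each axis' explained variance as weight. The
#' normalization makes the result invariant to expressing theta as
#' percentages or proportions. Defaults to all retained axes (the weights
#' already downplay minor axes).
#'
#' @param scores g x p matrix of scaled genotype IPC scores.
#' @param theta per-axis explained variance weights (>= 0, sum > 0).
#' @param n_axes number of axes to include (defaults to all).
#' @return named per-genotype vector; smaller = more stable.
#' @export
waas <- function(scores, theta, n_axes = ncol(scores)) {
  scores <- as.matrix(scores)
  .check_axes(n_axes, ncol(scores))
  idx <- seq_len(n_axes)
  th <- theta[idx]
  if (sum(th) <= 0) stop("theta weights sum to zero")
  rowSums(abs(scores[, idx, drop = FALSE]) %*% diag(th, length(th))) / sum(th)
}

.check_axes <- function(n_axes, p) {
  if (n_axes < 1 || n_axes > p) {
    stop(sprintf("n_axes must be in 1..%d, got %s", p, n_axes))
  }
}

#' Rank genotypes and form simultaneous selection indices
#'
#' Each stability index is ranked ascending (rank 1 = lowest index = most
#' stable); yields are ranked descending (RY = 1 for the highest-yielding
#' genotype). The simultaneous selection index for index X is
#' ssi_X = rank_X + RY, so small ssi identifies genotypes that are both
#' stable and high yielding. Ties receive the minimum ("competition") rank,
#' keeping ranks integral so the ssi sums stay comparable.
#'
#' @param indices named list (or data.frame) of per-genotype index vectors,
#'   all in the same genotype order.
#' @param mean_yields per-genotype mean yield over environments, kg/ha.
#' @param genotypes genotype identifiers; defaults to names of `mean_yields`.
#' @return A `stability_table` data.frame: genotype, mean_yield, RY, then for
#'   every index X the columns `X`, `rank_X`, `ssi_X`.
#' @export
rank_and_ssi <- function(indices, mean_yields, genotypes = names(mean_yields)) {
  indices <- as.list(indices)
  g <- length(mean_yields)
  if (is.null(genotypes)) genotypes <- paste0("G", seq_len(g))
  stopifnot(all(vapply(indices, length, 0L) == g))
  RY <- rank(-mean_yields, ties.method = "min")
  out <- data.frame(genotype = genotypes, mean_yield = unname(mean_yields),
                    RY = as.integer(RY), row.names = NULL)
  for (nm in names(indices)) {
    v <- indices[[nm]]
    r <- as.integer(rank(v, ties.method = "min"))
    out[[nm]] <- unname(v)
    out[[paste0("rank_", nm)]] <- r
    out[[paste0("ssi_", nm)]] <- r + out$RY
  }
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Compute the full AMMI stability table
#'
#' Convenience wrapper: computes ASV, SIPC, EV, Za, MASV, D and WAAS from a
#' Gollob-tested AMMI result, then ranks them and forms the simultaneous
#' selection indices. SIPC, EV, Za, D and MASV use the N' significant axes
#' from the Gollob scan; WAAS uses all retained axes (its weights already
#' discount minor ones); ASV always uses the first two. Each choice can be
#' overridden.
#'
#' @param ammi an [ammi_decompose()] result that has been through
#'   [gollob_test()] (or supply `n_axes` explicitly).
#' @param n_axes override for the number of significant axes N'.
#' @param waas_axes override for the axes included in WAAS.
#' @return A `stability_table` (see [rank_and_ssi()]). MASV and ASV are
#'   omitted (with a message) when the interaction has fewer than 2 axes of
#'   signal; all indices are 0 for a zero interaction.
#' @export
stability_indices <- function(ammi, n_axes = NULL, waas_axes = NULL) {
  stopifnot(inherits(ammi, "ammi_result"))
  p <- length(ammi$singular_values)
  if (is.null(n_axes)) {
    n_axes <- if (!is.null(ammi$n_significant)) ammi$n_significant else p
  }
  .check_axes(n_axes, p)
  if (is.null(waas_axes)) waas_axes <- p
  sc <- ammi$genotype_scores
  gam <- ammi$genotype_eigenvectors
  theta_prop <- ammi$percent_explained / 100
  idx <- list()
  if (ammi$zero_interaction) {
    z <- stats::setNames(rep(0, nrow(sc)), rownames(sc))
    idx <- list(ASV = z, SIPC = z, EV = z, Za = z, MASV = z, D = z, WAAS = z)
  } else {
    if (p >= 2 && ammi$ss_ipc[2] > 0) {
      idx$ASV <- asv(sc, ammi$ss_ipc[1], ammi$ss_ipc[2])
    } else {
      message("skipping ASV/MASV: interaction has rank < 2")
    }
    idx$SIPC <- sipc(sc, p)  # SIPC-F: all retained axes
    idx$EV <- ev(gam, n_axes)
    idx$Za <- za(gam, theta_prop, n_axes)
    if (!is.null(idx$ASV) && n_axes >= 2) {
      idx$MASV <- masv(sc, ammi$ss_ipc, n_axes)
    } else if (!is.null(idx$ASV)) {
      idx$MASV <- idx$ASV  # N' < 2: MASV falls back to the 2-axis ASV form
    }
    idx$D <- ammi_distance(sc, n_axes)
    idx$WAAS <- waas(sc, ammi$percent_explained, waas_axes)
  }
  rank_and_ssi(idx, rowMeans(ammi$means$means))
}
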