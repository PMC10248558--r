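# Shared fixture builders for the test suite.

# Build a met_dataset directly from a g x e cell-means matrix, replicating
# each cell r times with optional i.i.d. noise.
dataset_from_means <- function(means, r = 1, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- nrow(means); e <- ncol(means)
  gen <- if (is.null(rownames(means))) sprintf("G%02d", seq_len(g)) else rownames(means)
  env <- if (is.null(colnames(means))) sprintf("E%d", seq_len(e)) else colnames(means)
  grid <- expand.grid(gi = seq_len(g), ej = seq_len(e), rk = seq_len(r))
  y <- means[cbind(grid$gi, grid$ej)] +
    if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
  met_dataset(data.frame(
    genotype = gen[grid$gi], environment = env[grid$ej],
    replicate = paste0("R", grid$rk), yield = y
  ))
}

# A fixed doubly-centered interaction matrix (5 genotypes x 4 environments)
# used wherever a deterministic non-trivial interaction is needed.
toy_interaction <- function() {
  m <- matrix(c(
     4, -2, -1, -1,
    -3,  5, -1, -1,
     1, -1,  2, -2,
    -1, -1, -1,  3,
    -1, -1,  1,  1
  ), nrow = 5, byrow = TRUE)
  m <- m - rowMeans(m)
  m <- sweep(m, 2, colMeans(m))
  dimnames(m) <- list(sprintf("G%02d", 1:5), paste0("E", 1:4))
  m
}

# Quietly run the pipeline (drops the skip notice and stray warnings about
# negative synthetic yields).
quiet_pipeline <- function(...) {
  suppressMessages(suppressWarnings(run_met_pipeline(...)))
}

quiet_generate <- function(spec) suppressWarnings(generate_met(spec))
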