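#' Standardize a population-level variable
#'
#' Subtract the mean and divide by the (n-1) standard deviation, so the
#' association model sees every environmental or phenotypic variable on a
#' common scale.
#'
#' @param values numeric vector of per-population values.
#' @return Standardized numeric vector (mean 0, sd 1).
#' @export
standardize_variable <- function(values) {
  if (length(unique(values)) < 2) abort("variable has zero variance")
  as.numeric((values - mean(values)) / sd(values))
}

#' Estimate population allele-frequency covariance matrices
#'
#' The neutral covariance structure among populations is estimated from
#' standardized allele-frequency deviations
#' `x_ij = (p_ij - pbar_i) / sqrt(pbar_i (1 - pbar_i))`, averaging outer
#' products over loci. Seeded bootstrap resampling over loci provides
#' `n_matrices` variants, giving the association scan run-to-run
#' variability analogous to repeated estimation under different priors.
#' Pooled frequencies are shrunk toward 1/2 by one pseudo-allele
#' (`(count + 1/2) / (2N + 1)`) to avoid 0/1 degeneracy.
#'
#' @param geno a filtered [geno_matrix()].
#' @param n_matrices number of bootstrap covariance matrices.
#' @param seed integer seed.
#' @return A list of `n_matrices` symmetric positive-semidefinite
#'   population covariance matrices. The first is additionally computed on
#'   the full (unresampled) locus set when `n_matrices = 1`.
#' @export
estimate_pop_covariance <- function(geno, n_matrices = 10, seed = 1) {
  ac <- allele_counts(geno)
  if (nrow(ac$count) < 50) abort("need at least 50 loci for a stable covariance estimate")
  p_hat <- ac$count / pmax(ac$n, 1L)
  pbar <- (rowSums(ac$count) + 0.5) / (rowSums(ac$n) + 1)
  x <- (p_hat - pbar) / sqrt(pbar * (1 - pbar))
  L <- nrow(x)
  withr::with_seed(as.integer(seed), {
    map(seq_len(n_matrices), function(k) {
      idx <- if (n_matrices == 1) seq_len(L) else sample.int(L, L, replace = TRUE)
      om <- crossprod(x[idx, , drop = FALSE]) / length(idx)
      dimnames(om) <- list(ac$pops, ac$pops)
      om
    })
  })
}

# log-density kernel machinery for one covariance matrix: the transformed
# per-population frequency deviations z ~ MVN(beta * E, Omega); the Bayes
# factor against beta = 0 only needs u = E' Omega^-1 z and v = E' Omega^-1 E
bf_for_matrix <- function(z, env, omega, beta_grid, w) {
  ev <- eigen(omega, symmetric = TRUE)
  if (any(ev$values < -1e-10)) abort("covariance matrix is not positive semi-definite")
  inv <- ev$vectors %*% diag(1 / pmax(ev$values, 1e-10)) %*% t(ev$vectors)
  u <- as.numeric(z %*% inv %*% env)    # per-SNP
  v <- as.numeric(t(env) %*% inv %*% env)
  # BF = sum_k w_k exp(beta_k u - beta_k^2 v / 2)
  lw <- outer(u, beta_grid) - matrix(beta_grid^2 * v / 2, length(u),
                                     length(beta_grid), byrow = TRUE)
  as.numeric(exp(lw) %*% w)
}

#' Covariance-aware Bayes-factor scan for one variable
#'
#' For each SNP, the standardized population frequency deviations
#' `z_j = (p_hat_ij - pbar_i) / sqrt(pbar_i (1 - pbar_i))` are modelled as
#' multivariate normal with the neutral population covariance; the
#' alternative adds a linear environmental effect `beta * E_j` to the mean.
#' The Bayes factor integrates the likelihood ratio over a symmetric
#' uniform prior on beta by fixed-node quadrature. Each of the `n_runs`
#' runs pairs one covariance matrix (cycling through `covariances`) with
#' the run index; ranks are aggregated with [aggregate_ranks()].
#'
#' @param geno a filtered [geno_matrix()].
#' @param variable per-population values, in `populations(geno)` order
#'   (standardized internally).
#' @param covariances list of covariance matrices from
#'   [estimate_pop_covariance()].
#' @param n_runs number of runs.
#' @param beta_max half-width of the uniform prior on beta.
#' @param n_nodes quadrature nodes across `[-beta_max, beta_max]`.
#' @return Object of class `bf_scan`: list with `bf` (loci x runs matrix),
#'   `ranks` (the [aggregate_ranks()] tibble) and `variable` name.
#' @export
bayes_factor_scan <- function(geno, variable, covariances, n_runs = 20,
                              beta_max = 0.3, n_nodes = 201) {
  stopifnot(length(covariances) >= 1)
  env <- standardize_variable(variable)
  ac <- allele_counts(geno)
  if (length(env) != ncol(ac$count)) {
    abort("variable must have one value per population")
  }
  p_hat <- ac$count / pmax(ac$n, 1L)
  pbar <- (rowSums(ac$count) + 0.5) / (rowSums(ac$n) + 1)
  z <- (p_hat - pbar) / sqrt(pbar * (1 - pbar))
  beta_grid <- seq(-beta_max, beta_max, length.out = n_nodes)
  # trapezoid weights normalized to a proper prior
  w <- c(0.5, rep(1, n_nodes - 2), 0.5)
  w <- w / sum(w)
  bf <- vapply(seq_len(n_runs), function(r) {
    om <- covariances[[(r - 1L) %% length(covariances) + 1L]]
    bf_for_matrix(z, env, om, beta_grid, w)
  }, numeric(nrow(z)))
  rownames(bf) <- rownames(ac$count)
  structure(
    list(bf = bf, ranks = aggregate_ranks(bf),
         variable = deparse(substitute(variable))),
    class = "bf_scan"
  )
}

#' @export
print.bf_scan <- function(x, ...) {
  cat(sprintf("<bf_scan> %d SNPs x %d runs; %d outliers at mean rank > 0.99\n",
              nrow(x$bf), ncol(x$bf), sum(x$ranks$outlier)))
  invisible(x)
}

#' @export
tidy.bf_scan <- function(x, ...) {
  mutate(x$ranks, median_bf = apply(x$bf, 1, median))
}

#' Aggregate per-run Bayes-factor ranks
#'
#' Within each run, SNPs are ranked by Bayes factor ascending and the rank
#' scaled to `[0, 1]` as `(rank - 1) / (L - 1)` (average ranks for ties, so
#' an all-tied run scores 0.5 everywhere); the scaled ranks are then
#' averaged over runs. SNPs with mean rank above 0.99 are flagged as
#' outliers.
#'
#' @param bf_runs numeric matrix, SNPs in rows, runs in columns (rownames
#'   are SNP ids).
#' @param threshold mean-rank outlier threshold.
#' @return A tibble: `snp_id`, `mean_rank`, `outlier`.
#' @export
aggregate_ranks <- function(bf_runs, threshold = 0.99) {
  bf_runs <- as.matrix(bf_runs)
  L <- nrow(bf_runs)
  if (L < 2) abort("need at least two SNPs to rank")
  scaled <- apply(bf_runs, 2, function(col) (rank(col) - 1) / (L - 1))
  mean_rank <- unname(rowMeans(scaled))
  tibble(
    snp_id = rownames(bf_runs) %||% as.character(seq_len(L)),
    mean_rank = mean_rank,
    outlier = mean_rank > threshold
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
autoplot.bf_scan <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$mean_rank, y = log10(.data$median_bf))) +
    geom_point(aes(colour = .data$outlier), alpha = 0.6) +
    geom_vline(xintercept = 0.99, colour = "red") +
    labs(x = "mean rank", y = "log10 median BF") +
    theme_minimal()
}
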