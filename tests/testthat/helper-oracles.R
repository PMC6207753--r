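# Independent brute-force oracles. These are deliberately written as plain
# transcriptions of the textbook formulas, structured differently from the
# package implementations they check.

# Weir & Cockerham (1984) theta via explicit per-locus loops over genotype
# counts. `geno_list` is a list of per-population dosage matrices
# (clones x loci).
oracle_wc_theta <- function(geno_list) {
  L <- ncol(geno_list[[1]])
  num <- den <- 0
  for (l in seq_len(L)) {
    ns <- ps <- hs <- c()
    for (d in geno_list) {
      x <- d[, l]
      x <- x[!is.na(x)]
      if (length(x) == 0) next
      ns <- c(ns, length(x))
      ps <- c(ps, sum(x) / (2 * length(x)))
      hs <- c(hs, mean(x == 1))
    }
    r <- length(ns)
    if (r < 2) next
    n_bar <- mean(ns)
    n_c <- (r * n_bar - sum(ns^2) / (r * n_bar)) / (r - 1)
    p_bar <- sum(ns * ps) / sum(ns)
    s2 <- sum(ns * (ps - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(ns * hs) / sum(ns)
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Exact HWE p-value by full enumeration of the conditional distribution of
# heterozygote counts (probabilities via exact products, no log-space
# shortcuts)
oracle_hwe_p <- function(n_het, n, n_a) {
  n_b <- 2 * n - n_a
  if (n_a == 0 || n_b == 0) return(1)
  ks <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  pr <- sapply(ks, function(k) {
    exp(lchoose(n, (n_a - k) / 2) + lchoose(n - (n_a - k) / 2, k) +
          lchoose(n - (n_a - k) / 2 - k, (n_b - k) / 2) + k * log(2) -
          (lchoose(2 * n, n_a)))
  })
  pr <- pr / sum(pr)
  obs <- pr[ks == n_het]
  sum(pr[pr <= obs + 1e-12])
}

# Tajima's D transcribed directly from the original constants, for a
# complete (no-missing) dosage matrix treated as one window
oracle_tajima_d <- function(dosage) {
  n <- 2 * nrow(dosage)
  ac <- colSums(dosage)
  seg <- ac > 0 & ac < n
  S <- sum(seg)
  if (S < 2) return(NA_real_)
  # average pairwise differences
  pi_hat <- 0
  for (l in which(seg)) {
    j <- ac[l]
    pi_hat <- pi_hat + j * (n - j) / choose(n, 2)
  }
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Two-tailed Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small deterministic genotype fixture builder
toy_geno <- function(dosage_by_pop, depth = NULL) {
  dosage <- do.call(rbind, dosage_by_pop)
  pops <- rep(names(dosage_by_pop), vapply(dosage_by_pop, nrow, 0L))
  L <- ncol(dosage)
  clones <- tibble::tibble(
    clone = sprintf("c%03d", seq_len(nrow(dosage))), population = pops)
  snps <- tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(L)),
    scaffold = "scaf1", pos = as.integer(seq_len(L) * 1000L),
    ref = "A", alt = "T")
  geno_matrix(dosage, depth, clones, snps)
}
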