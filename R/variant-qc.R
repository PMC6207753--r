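#' Mask genotypes supported by too few reads
#'
#' Genotypes with read depth strictly below `min_depth` are set to missing
#' (treated as not genotyped); depths themselves are retained so the later
#' mean-depth site filter still sees them.
#'
#' @param geno a [geno_matrix()] with a depth matrix.
#' @param min_depth minimum reads supporting a genotype call; the default
#'   of 6 drops anything supported by fewer than six reads.
#' @return The masked [geno_matrix()].
#' @export
mask_low_depth <- function(geno, min_depth = 6) {
  if (is.null(geno$depth)) abort("geno has no depth matrix to mask on")
  geno$dosage[geno$depth < min_depth] <- NA_integer_
  geno
}

#' Site-filter thresholds
#'
#' The five-site filter cascade, in order: (1) call rate of at least
#' `call_rate` within every population; (2) pooled minor allele frequency
#' strictly above `min_maf`; (3) exactly `n_alleles` distinct alleles among
#' called genotypes; (4) mean read depth over called genotypes strictly
#' below `max_mean_depth` (guards against collapsed repeats); (5)
#' heterozygote fraction among called genotypes strictly below `max_het`.
#'
#' @param call_rate minimum per-population call rate (inclusive).
#' @param min_maf pooled MAF threshold (exclusive).
#' @param n_alleles required number of distinct alleles.
#' @param max_mean_depth mean-depth ceiling (exclusive).
#' @param max_het heterozygote-fraction ceiling (exclusive).
#' @param het_per_population if `TRUE`, apply the heterozygosity ceiling in
#'   every population separately instead of pooled.
#' @param maf_per_population if `TRUE`, require the MAF threshold in every
#'   population separately instead of pooled.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(call_rate = 0.50, min_maf = 0.01, n_alleles = 2,
                          max_mean_depth = 150, max_het = 0.60,
                          het_per_population = FALSE,
                          maf_per_population = FALSE) {
  structure(
    list(call_rate = call_rate, min_maf = min_maf, n_alleles = n_alleles,
         max_mean_depth = max_mean_depth, max_het = max_het,
         het_per_population = het_per_population,
         maf_per_population = maf_per_population),
    class = "qc_thresholds"
  )
}

#' Apply the five-site filter cascade
#'
#' Filters are applied sequentially in the stated order, so the attrition
#' report attributes each removed SNP to the first filter it fails:
#' per-population call rate, MAF, biallelic, mean depth, heterozygote
#' excess. Apply [mask_low_depth()] first so calls reflect confidently
#' genotyped samples.
#'
#' @param geno a depth-masked [geno_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return A list with `geno` (the filtered matrix) and `report`, a tibble
#'   with one row per filter: `filter`, `entering`, `removed`, `remaining`.
#' @export
apply_site_filters <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  th <- thresholds
  pops <- populations(geno)
  pop_of <- geno$clones$population
  if (anyNA(pop_of)) abort("unknown population in clone map")

  steps <- list(
    call_rate = function(g) {
      ok <- rep(TRUE, ncol(g$dosage))
      for (p in pops) {
        d <- g$dosage[pop_of == p, , drop = FALSE]
        ok <- ok & (colMeans(!is.na(d)) >= th$call_rate)
      }
      ok
    },
    maf = function(g) {
      if (th$maf_per_population) {
        ok <- rep(TRUE, ncol(g$dosage))
        for (p in pops) {
          d <- g$dosage[pop_of == p, , drop = FALSE]
          pq <- colSums(d, na.rm = TRUE) / pmax(2 * colSums(!is.na(d)), 1L)
          ok <- ok & (pmin(pq, 1 - pq) > th$min_maf)
        }
        ok
      } else {
        pooled_maf(g) > th$min_maf
      }
    },
    biallelic = function(g) n_distinct_alleles(g) == th$n_alleles,
    mean_depth = function(g) {
      if (is.null(g$depth)) return(rep(TRUE, ncol(g$dosage)))
      called <- !is.na(g$dosage)
      md <- colSums(g$depth * called) / pmax(colSums(called), 1L)
      md < th$max_mean_depth
    },
    het_excess = function(g) {
      if (th$het_per_population) {
        ok <- rep(TRUE, ncol(g$dosage))
        for (p in pops) {
          d <- g$dosage[pop_of == p, , drop = FALSE]
          ok <- ok & (colSums(d == 1L, na.rm = TRUE) /
                        pmax(colSums(!is.na(d)), 1L) < th$max_het)
        }
        ok
      } else {
        colSums(g$dosage == 1L, na.rm = TRUE) /
          pmax(colSums(!is.na(g$dosage)), 1L) < th$max_het
      }
    }
  )

  report <- tibble(filter = character(), entering = integer(),
                   removed = integer(), remaining = integer())
  for (nm in names(steps)) {
    entering <- ncol(geno$dosage)
    keep <- steps[[nm]](geno)
    geno <- geno[, keep]
    report <- add_row(report, filter = nm, entering = entering,
                      removed = entering - sum(keep),
                      remaining = as.integer(sum(keep)))
  }
  list(geno = geno, report = report)
}

# distinct-allele count per SNP among called genotypes: derived from the
# dosage spectrum (ref present if any dosage < 2, alt present if any > 0);
# monomorphic columns therefore count 1. An `n_alleles` metadata column
# (e.g. a third allele recorded in the VCF ALT field but absent from the
# biallelic dosage encoding) can only raise the count.
n_distinct_alleles <- function(geno) {
  has_ref <- colSums(geno$dosage < 2L, na.rm = TRUE) > 0
  has_alt <- colSums(geno$dosage > 0L, na.rm = TRUE) > 0
  n <- as.integer(has_ref) + as.integer(has_alt)
  extra <- geno$snps[["n_alleles"]]
  if (!is.null(extra)) {
    n <- pmax(n, ifelse(is.na(extra), 0L, as.integer(extra)))
  }
  n
}
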