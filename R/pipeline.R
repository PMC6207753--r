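#' Configuration of a full pipeline run
#'
#' Either file inputs (`vcf`, `pop_map`, plus optional `lake_tsv`,
#' `trait_tsv`, `gff3`, `go_tsv`) or a simulation block (`sim` = a
#' [sim_config()]) must be present. Thresholds and chain settings for
#' every stage have the package defaults.
#'
#' @param vcf,pop_map,lake_tsv,trait_tsv,gff3,go_tsv input file paths
#'   (`NULL` to omit a stage's input).
#' @param sim a [sim_config()] to generate the inputs instead of reading
#'   files.
#' @param out_dir output directory for stage TSVs and the JSON summary.
#' @param qc a [qc_thresholds()].
#' @param mcmc an [mcmc_config()].
#' @param fdr F-model q-value threshold.
#' @param n_cov_matrices,n_bf_runs covariance matrices and runs for the
#'   association scan.
#' @param k_pcs principal components for the GWAS stage.
#' @param min_depth genotype depth mask threshold.
#' @param seed master seed for every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, pop_map = NULL, lake_tsv = NULL,
                       trait_tsv = NULL, gff3 = NULL, go_tsv = NULL,
                       sim = NULL, out_dir = tempfile("predscan_run_"),
                       qc = qc_thresholds(), mcmc = NULL, fdr = 0.05,
                       n_cov_matrices = 10, n_bf_runs = 20, k_pcs = 10,
                       min_depth = 6, seed = 1) {
  if (is.null(sim) && (is.null(vcf) || is.null(pop_map))) {
    abort("provide either a simulation block or vcf + pop_map paths")
  }
  if (is.null(mcmc)) {
    mcmc <- mcmc_config(n_pilot = 5, pilot_iter = 200, burn_in = 1500,
                        n_samples = 600, thin = 2, seed = seed)
  }
  structure(
    list(vcf = vcf, pop_map = pop_map, lake_tsv = lake_tsv,
         trait_tsv = trait_tsv, gff3 = gff3, go_tsv = go_tsv, sim = sim,
         out_dir = out_dir, qc = qc, mcmc = mcmc, fdr = fdr,
         n_cov_matrices = n_cov_matrices, n_bf_runs = n_bf_runs,
         k_pcs = k_pcs, min_depth = min_depth, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full scan pipeline
#'
#' End-to-end orchestration in the order of the analysis chain: depth
#' masking and site filters; diversity, FST, PCA, HWE and Tajima's D
#' summaries; the F-model outlier scan with q-values; the covariance-aware
#' Bayes-factor scan over the available lake variables with rank
#' aggregation; the EIGENSTRAT scan over clone-level traits; selection
#' classification with balancing-consistency flags; and (when gene models
#' are supplied) SNP-to-gene assignment with GO enrichment. All stage
#' tables are written as TSVs under `out_dir` together with a JSON summary
#' of per-stage counts and between-method outlier overlaps. Reruns with
#' the same config are byte-identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the stage results and the `summary`
#'   list written to JSON.
#' @export
run_full_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  log_lines <- c(sprintf("predscan %s", as.character(utils::packageVersion("predscan"))),
                 sprintf("seed: %d", config$seed))

  # ---- inputs ----
  if (!is.null(config$sim)) {
    study <- simulate_study(config$sim)
    geno <- study$geno
    traits <- study$phenotype
    lakes <- NULL
    log_lines <- c(log_lines, sprintf("simulated input, sim seed %d", config$sim$seed))
  } else {
    geno <- read_geno_vcf(config$vcf, config$pop_map)
    traits <- if (!is.null(config$trait_tsv)) {
      readr::read_tsv(config$trait_tsv, col_types = readr::cols())
    }
    lakes <- if (!is.null(config$lake_tsv)) {
      readr::read_tsv(config$lake_tsv, col_types = readr::cols())
    }
    log_lines <- c(log_lines, sprintf("input: %s", config$vcf))
  }

  # ---- QC ----
  geno <- mask_low_depth(geno, config$min_depth)
  qc <- apply_site_filters(geno, config$qc)
  geno <- qc$geno
  readr::write_tsv(qc$report, out("filter_report.tsv"))
  if (ncol(geno$dosage) < 50) abort("fewer than 50 SNPs survive filtering")
  # drop loci that became monomorphic (the F-model cannot place them)
  maf <- pooled_maf(geno)
  geno <- geno[, maf > 0]

  # ---- population summaries ----
  div <- diversity_per_population(geno)
  readr::write_tsv(div, out("diversity.tsv"))
  fst <- wc_fst(geno)
  readr::write_tsv(tidy(fst), out("pairwise_fst.tsv"))
  pca <- pca_genotypes(geno)
  readr::write_tsv(pca$scores, out("pca_scores.tsv"))
  hwe <- hwe_exact(geno)
  readr::write_tsv(hwe, out("hwe.tsv"))
  taj <- tajimas_d(geno)
  readr::write_tsv(taj$windows, out("tajima_windows.tsv"))
  ld <- ld_decay(geno)
  readr::write_tsv(ld$bins, out("ld_decay_bins.tsv"))

  # ---- F-model scan ----
  fit <- fit_f_model(geno, config$mcmc)
  calls <- classify_selection(fit, maf = snp_meta(geno), tajima = taj$snps,
                              fdr = config$fdr)
  readr::write_tsv(calls, out("fmodel_calls.tsv"))

  # ---- environmental association ----
  env_outliers <- list()
  if (!is.null(config$sim)) {
    vars <- list(environment = config$sim$env_values)
  } else if (!is.null(lakes)) {
    vars <- as.list(lakes[intersect(
      c("salinity_g_l", "hydroperiod", "predictability",
        "propensity_for_sex", "hatching_fraction_pct"), names(lakes))])
  } else {
    vars <- list()
  }
  if (length(vars)) {
    covs <- estimate_pop_covariance(geno, config$n_cov_matrices,
                                    seed = config$seed + 10L)
    for (v in names(vars)) {
      scan <- bayes_factor_scan(geno, vars[[v]], covs, config$n_bf_runs)
      readr::write_tsv(tidy(scan), out(sprintf("bf_%s.tsv", v)))
      env_outliers[[v]] <- scan$ranks$snp_id[scan$ranks$outlier]
    }
  }

  # ---- GWAS ----
  gwas_hits <- character()
  if (!is.null(traits)) {
    gw <- eigenstrat_scan(geno, traits, min(config$k_pcs, nrow(geno$dosage) - 3L))
    readr::write_tsv(tidy(gw), out("gwas.tsv"))
    gwas_hits <- with(tidy(gw), snp_id[!is.na(p_bonferroni) & p_bonferroni < 0.05])
  }

  # ---- gene context ----
  genes_out <- NULL
  if (!is.null(config$gff3)) {
    genes <- read_gene_models(config$gff3, config$go_tsv)
    cand <- unique(c(calls$snp_id[calls$class != "neutral"],
                     unlist(env_outliers), gwas_hits))
    genes_out <- snps_to_genes(geno$snps[geno$snps$snp_id %in% cand, ],
                               genes)
    readr::write_tsv(genes_out$assignments, out("snp_genes.tsv"))
    if (!is.null(config$go_tsv) && nrow(genes_out$assignments)) {
      go_map <- readr::read_tsv(config$go_tsv, col_types = readr::cols(.default = "c"))
      enr <- go_enrichment(unique(genes_out$assignments$gene_id),
                           unique(go_map$gene_id), go_map)
      readr::write_tsv(enr, out("go_enrichment.tsv"))
    }
  } else {
    log_lines <- c(log_lines, "gene-context stage skipped: no GFF3 supplied")
  }

  # ---- summary & overlaps ----
  fmodel_sel <- calls$snp_id[calls$class != "neutral"]
  overlaps <- list()
  for (v in names(env_outliers)) {
    overlaps[[paste0("fmodel_x_", v)]] <- length(intersect(fmodel_sel, env_outliers[[v]]))
  }
  if (length(env_outliers) > 1) {
    nm <- names(env_outliers)
    for (i in seq_along(nm)[-1]) for (j in seq_len(i - 1)) {
      overlaps[[paste(nm[j], nm[i], sep = "_x_")]] <-
        length(intersect(env_outliers[[nm[j]]], env_outliers[[nm[i]]]))
    }
  }
  summary <- list(
    seed = config$seed,
    n_snps_input = qc$report$entering[1],
    n_snps_filtered = qc$report$remaining[nrow(qc$report)],
    overall_fst = fst$overall,
    n_fmodel_selected = length(fmodel_sel),
    n_fmodel_diversifying = sum(calls$class == "diversifying"),
    n_fmodel_balancing = sum(calls$class == "balancing/purifying"),
    n_env_outliers = purrr::map_int(env_outliers, length),
    n_gwas_hits = length(gwas_hits),
    overlaps = overlaps
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, out("run.log"))
  invisible(list(geno = geno, report = qc$report, diversity = div,
                 fst = fst, pca = pca, hwe = hwe, tajima = taj,
                 fmodel = fit, calls = calls, env_outliers = env_outliers,
                 gwas_hits = gwas_hits, genes = genes_out,
                 summary = summary))
}
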