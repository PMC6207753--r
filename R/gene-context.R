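#' Read gene models and GO annotations
#'
#' Gene models come from a GFF3 (1-based inclusive intervals, `gene`
#' features), GO annotations from a two-column TSV (`gene_id`, `go_id`;
#' one row per gene-term pair).
#'
#' @param gff3_path path to a GFF3 file.
#' @param go_path optional path to the GO TSV.
#' @param feature_type GFF3 feature type to keep.
#' @return A tibble of gene models: `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, and a `go` list-column of term ids (empty when no GO file).
#' @export
read_gene_models <- function(gff3_path, go_path = NULL,
                             feature_type = "gene") {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  genes <- tibble(
    gene_id = as.character(ids),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  go_map <- if (!is.null(go_path)) {
    readr::read_tsv(go_path, col_types = readr::cols(.default = "c"))
  } else {
    tibble(gene_id = character(), go_id = character())
  }
  genes$go <- map(genes$gene_id, function(g) go_map$go_id[go_map$gene_id == g])
  genes
}

#' Assign SNPs to genes by flanking windows
#'
#' A SNP is assigned to every gene whose interval, extended by `flank_bp`
#' up- and downstream (strand-agnostic), contains its position; intervals
#' are 1-based inclusive as in GFF3. All flank levels are reported, and
#' SNPs hitting no gene at the widest flank are returned with the distance
#' to the nearest gene on their scaffold.
#'
#' @param snps tibble with `snp_id`, `scaffold`, `pos`.
#' @param genes tibble with `gene_id`, `scaffold`, `start`, `end` (e.g.
#'   [read_gene_models()]).
#' @param flank_bp numeric vector of flank widths in bp; the convention is
#'   0, 2500 and 5000.
#' @return A list with `assignments` (tibble: snp_id, gene_id, flank_bp —
#'   one row per SNP-gene-flank hit) and `unassigned` (tibble: snp_id,
#'   nearest_gene, distance_bp for SNPs with no hit at the widest flank;
#'   distance is `NA` when the scaffold has no gene).
#' @export
snps_to_genes <- function(snps, genes, flank_bp = c(0, 2500, 5000)) {
  snp_gr <- GenomicRanges::GRanges(
    snps$scaffold, IRanges::IRanges(snps$pos, snps$pos))
  out <- map(flank_bp, function(fl) {
    gene_gr <- GenomicRanges::GRanges(
      genes$scaffold,
      IRanges::IRanges(pmax(genes$start - fl, 1L), genes$end + fl))
    hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
    tibble(
      snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
      flank_bp = fl
    )
  })
  assignments <- bind_rows(out)
  widest <- max(flank_bp)
  hit_ids <- unique(assignments$snp_id[assignments$flank_bp == widest])
  missed <- snps[!snps$snp_id %in% hit_ids, , drop = FALSE]
  unassigned <- map(seq_len(nrow(missed)), function(i) {
    g <- genes[genes$scaffold == missed$scaffold[i], , drop = FALSE]
    if (nrow(g) == 0) {
      return(tibble(snp_id = missed$snp_id[i], nearest_gene = NA_character_,
                    distance_bp = NA_integer_))
    }
    d <- pmax(g$start - missed$pos[i], missed$pos[i] - g$end, 0L)
    tibble(snp_id = missed$snp_id[i],
           nearest_gene = g$gene_id[which.min(d)],
           distance_bp = as.integer(min(d)))
  }) |> bind_rows()
  if (nrow(missed) == 0) {
    unassigned <- tibble(snp_id = character(), nearest_gene = character(),
                         distance_bp = integer())
  }
  list(assignments = assignments, unassigned = unassigned)
}

#' GO-term enrichment of a candidate gene set
#'
#' Per GO term, a 2x2 Fisher exact test (two-tailed) of candidate
#' membership against term annotation over the gene universe, with
#' Benjamini-Hochberg FDR across terms. Both over- and under-representation
#' are reported through the odds-ratio direction.
#'
#' @param candidate_genes character vector of candidate gene ids (must be a
#'   subset of the universe).
#' @param universe_genes character vector of universe gene ids (e.g. all
#'   annotated genes).
#' @param go_map tibble with `gene_id`, `go_id`.
#' @param fdr significance threshold on the adjusted q.
#' @return A tibble: `go_id`, the 2x2 counts (`in_set_with`,
#'   `in_set_without`, `out_set_with`, `out_set_without`), `odds_ratio`,
#'   `p`, `q`, `significant`.
#' @export
go_enrichment <- function(candidate_genes, universe_genes, go_map,
                          fdr = 0.05) {
  candidate_genes <- unique(candidate_genes)
  universe_genes <- unique(universe_genes)
  if (length(candidate_genes) == 0) abort("empty candidate set")
  if (!all(candidate_genes %in% universe_genes)) {
    abort("candidates must be a subset of the universe")
  }
  go_map <- go_map[go_map$gene_id %in% universe_genes, , drop = FALSE]
  terms <- unique(go_map$go_id)
  n_cand <- length(candidate_genes)
  n_univ <- length(universe_genes)
  rows <- map(terms, function(tm) {
    with_term <- unique(go_map$gene_id[go_map$go_id == tm])
    a <- sum(candidate_genes %in% with_term)
    b <- n_cand - a
    c_ <- length(with_term) - a
    d <- (n_univ - n_cand) - c_
    if (c_ + d == 0 || a + b == 0) {
      # degenerate universe split (candidate set = universe): no contrast
      or <- 1; pv <- 1
    } else {
      ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      or <- unname(ft$estimate); pv <- ft$p.value
    }
    tibble(go_id = tm, in_set_with = a, in_set_without = b,
           out_set_with = c_, out_set_without = d,
           odds_ratio = or, p = pv)
  })
  out <- bind_rows(rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  arrange(out, .data$p)
}
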