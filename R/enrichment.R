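#' One-sided hypergeometric upper-tail probability
#'
#' Probability of drawing at least `k` successes in `n` draws without
#' replacement from a universe of `M` items of which `K` are successes
#' (the one-sided Fisher exact test for over-representation). Computed
#' with the hypergeometric distribution function.
#'
#' @param M universe size.
#' @param K successes in the universe.
#' @param n draw size.
#' @param k observed successes in the draw.
#' @return upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(M, K, n, k) {
  if (K < 0 || K > M) stop("K must satisfy 0 <= K <= M")
  if (n < 0 || n > M) stop("n must satisfy 0 <= n <= M")
  if (k < 0 || k > min(K, n))
    stop("k must satisfy 0 <= k <= min(K, n)")
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Gene-level over-representation of significant SNPs
#'
#' For each gene, asks whether the SNPs assigned to it carry more
#' genome-wide significant models than expected given the gene's size.
#' The universe is the set of distinct SNPs mapped to at least one gene
#' (a SNP in several overlapping windows counts once in the universe but
#' contributes to each of its genes' draws); `K` of them are significant
#' at `alpha`. Each gene's draw is its mapped SNPs, and the p-value is
#' the one-sided hypergeometric upper tail. Genes with no mapped SNP are
#' excluded. No multiple-testing adjustment is applied; replication
#' across cohorts is the intended false-positive control.
#'
#' @param mapping a [map_snps_to_genes()] result.
#' @param scores per-SNP score table from [best_model_per_snp()].
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `entity_id`, `n_members`,
#'   `n_significant`, `p_value`, `significant`, ordered by p-value.
#' @export
gene_enrichment <- function(mapping, scores, alpha = 0.05) {
  stopifnot(inherits(mapping, "gene_mapping"))
  asg <- mapping$assignments
  if (!nrow(asg)) stop("empty mapping: no SNP assigned to any gene")
  missing <- setdiff(asg$snp_id, scores$snp_id)
  if (length(missing))
    stop("mapped SNPs without scores: ",
         paste(utils::head(missing, 5), collapse = ", "))
  universe <- unique(asg$snp_id)
  M <- length(universe)
  sig_snps <- scores$snp_id[scores$p_value <= alpha]
  sig_snps <- intersect(sig_snps, universe)
  K <- length(sig_snps)
  by_gene <- split(asg$snp_id, asg$gene_id)
  n <- lengths(lapply(by_gene, unique))
  k <- vapply(by_gene,
              function(s) length(intersect(unique(s), sig_snps)),
              integer(1))
  p <- vapply(seq_along(n),
              function(i) hypergeom_upper_tail(M, K, n[i], k[i]),
              numeric(1))
  out <- data.frame(entity_id = names(by_gene),
                    n_members = unname(n), n_significant = unname(k),
                    p_value = unname(p), significant = unname(p <= alpha),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$entity_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-set over-representation of significant genes
#'
#' Second level of the cascade: for each gene set, asks whether genes
#' significant at the gene level are over-represented given the set's
#' size. The universe is the genes actually tested (those with at least
#' one mapped SNP), so set sizes reflect testable genes only; set
#' membership is intersected with this universe before counting, with
#' gene symbols matched case-insensitively. Sets with an empty
#' intersection get p-value 1 and are flagged `untestable`.
#'
#' @param gene_rows gene-level table from [gene_enrichment()].
#' @param sets a `gene_set_collection` from [read_gene_sets()].
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `entity_id`, `n_members`,
#'   `n_significant`, `p_value`, `significant`, `untestable`, ordered by
#'   p-value.
#' @export
pathway_enrichment <- function(gene_rows, sets, alpha = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (!nrow(gene_rows)) stop("empty gene-level table")
  universe <- toupper(gene_rows$entity_id)
  M <- length(universe)
  sig_genes <- toupper(gene_rows$entity_id[gene_rows$p_value <= alpha])
  K <- length(sig_genes)
  nm <- names(sets$sets)
  rows <- lapply(nm, function(s) {
    members <- intersect(toupper(sets$sets[[s]]), universe)
    n <- length(members)
    k <- length(intersect(members, sig_genes))
    p <- if (n == 0) 1.0 else hypergeom_upper_tail(M, K, n, k)
    data.frame(entity_id = s, n_members = n, n_significant = k,
               p_value = p, significant = p <= alpha,
               untestable = n == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$entity_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param table a [gene_enrichment()] or [pathway_enrichment()] result.
#' @param path output path.
#' @export
write_enrichment <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
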