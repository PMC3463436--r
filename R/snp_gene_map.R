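#' Collapse the pair scan to per-SNP scores
#'
#' Each SNP inherits the accuracy of its best pair (the strongest joint
#' effect it participates in) and the permutation p-value of that
#' accuracy against the genome-wide null of scan maxima. A SNP with no
#' valid (non-degenerate) pair gets p-value 1 and is flagged.
#'
#' @param scan an [scan_all_pairs()] result.
#' @param null a [build_null()] result from the same study.
#' @param alpha significance level; defaults to the level stored in
#'   `null`.
#' @return data.frame with columns `snp_id`, `best_accuracy`, `p_value`,
#'   `significant`, `no_valid_pair`.
#' @export
best_model_per_snp <- function(scan, null, alpha = null$alpha) {
  stopifnot(inherits(scan, "mdr_scan"), inherits(null, "null_max_dist"))
  best <- scan$best_per_snp
  p <- model_p_value(null, best)
  novalid <- !scan$has_valid_pair
  p[novalid] <- 1.0
  data.frame(snp_id = scan$snp_ids, best_accuracy = unname(best),
             p_value = p, significant = p <= alpha,
             no_valid_pair = novalid, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Assign SNPs to genes within a window
#'
#' A SNP is assigned to every gene on the same chromosome whose body,
#' extended by `window` base pairs on each side, contains the SNP
#' position: `start - W <= pos <= end + W`, inclusive at both
#' boundaries. The default 500 kb window is wide enough to capture
#' regulatory variants acting on the gene. The assignment is
#' many-to-many; strand is ignored. Overlap search uses interval trees
#' via GenomicRanges; SNPs on chromosomes absent from the annotation are
#' reported unassigned.
#'
#' @param snp_map data.frame from [read_snp_map()].
#' @param genes data.frame from [read_gene_annotation()].
#' @param window flank size W in base pairs (default 500000).
#' @return A `gene_mapping`: list with `assignments` (data.frame
#'   `snp_id`, `gene_id`), `window`, and `unassigned` (snp ids mapped to
#'   no gene).
#' @export
map_snps_to_genes <- function(snp_map, genes, window = 500000) {
  if (window < 0) stop("window must be >= 0")
  if (!nrow(genes)) {
    return(structure(list(
      assignments = data.frame(snp_id = character(),
                               gene_id = character(),
                               stringsAsFactors = FALSE),
      window = window, unassigned = snp_map$snp_id),
      class = "gene_mapping"))
  }
  gr_genes <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(start = pmax(1, genes$start - window),
                              end = genes$end + window))
  gr_snps <- GenomicRanges::GRanges(
    seqnames = snp_map$chromosome,
    ranges = IRanges::IRanges(start = snp_map$position,
                              width = 1))
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes))
  assignments <- data.frame(
    snp_id = snp_map$snp_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  assignments <- assignments[order(match(assignments$snp_id,
                                         snp_map$snp_id),
                                   match(assignments$gene_id,
                                         genes$gene_id)), ,
                             drop = FALSE]
  rownames(assignments) <- NULL
  structure(list(assignments = assignments, window = window,
                 unassigned = setdiff(snp_map$snp_id,
                                      assignments$snp_id)),
            class = "gene_mapping")
}

#' @export
print.gene_mapping <- function(x, ...) {
  cat("gene_mapping: window +/-", x$window, "bp;",
      nrow(x$assignments), "assignments,",
      length(unique(x$assignments$snp_id)), "SNPs mapped,",
      length(x$unassigned), "unassigned\n")
  invisible(x)
}
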