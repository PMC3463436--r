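#' Run the full three-phase analysis on one cohort
#'
#' Phase I: exhaustive pairwise MDR scan, permutation null of scan
#' maxima, per-SNP best-model p-values, SNP-to-gene window assignment.
#' Phase II: gene-level hypergeometric over-representation of
#' significant SNPs. Phase III: gene-set-level over-representation of
#' significant genes. The run is fully determined by `seed`.
#'
#' @param study a [genotype_study()].
#' @param snp_map data.frame from [read_snp_map()]; must cover exactly
#'   the SNPs in `study`.
#' @param genes data.frame from [read_gene_annotation()].
#' @param sets a `gene_set_collection` from [read_gene_sets()].
#' @param alpha significance level used at every phase (default 0.05).
#' @param window SNP-to-gene window in bp (default 500000).
#' @param n_permutations label permutations for the null (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param statistic,tie_rule scan settings; see [scan_all_pairs()].
#' @param outdir optional directory; when given, per-SNP scores, the
#'   null maxima, the mapping and both enrichment tables are written
#'   there as TSV.
#' @param verbose emit per-phase progress messages (default FALSE).
#' @return A `study_result`: list with `scan`, `null`, `snp_scores`,
#'   `mapping`, `gene_table`, `set_table`, `critical_value` and the
#'   settings used.
#' @export
run_study <- function(study, snp_map, genes, sets, alpha = 0.05,
                      window = 500000, n_permutations = 1000, seed = 1,
                      statistic = c("accuracy", "balanced_accuracy"),
                      tie_rule = c("high", "low"), outdir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(study, "genotype_study"))
  statistic <- match.arg(statistic)
  tie_rule <- match.arg(tie_rule)
  extra <- setdiff(study$snp_ids, snp_map$snp_id)
  if (length(extra))
    stop("SNPs in genotype data but not in the SNP map: ",
         paste(utils::head(extra, 10), collapse = ", "))
  snp_map <- snp_map[match(study$snp_ids, snp_map$snp_id), ,
                     drop = FALSE]
  say <- function(...) if (verbose) message(...)

  say("phase I: scanning ", pair_count(ncol(study$genotypes)),
      " SNP pairs over ", nrow(study$genotypes), " individuals")
  scan <- scan_all_pairs(study, statistic = statistic,
                         tie_rule = tie_rule)
  say("phase I: building null from ", n_permutations,
      " label permutations")
  null <- build_null(study, n_permutations = n_permutations, seed = seed,
                     alpha = alpha, statistic = statistic,
                     tie_rule = tie_rule)
  scores <- best_model_per_snp(scan, null, alpha = alpha)
  mapping <- map_snps_to_genes(snp_map, genes, window = window)
  say("phase I: ", length(unique(mapping$assignments$snp_id)),
      " of ", length(study$snp_ids), " SNPs mapped to genes")
  gene_table <- gene_enrichment(mapping, scores, alpha = alpha)
  say("phase II: ", nrow(gene_table), " genes tested, ",
      sum(gene_table$significant), " significant")
  set_table <- pathway_enrichment(gene_table, sets, alpha = alpha)
  say("phase III: ", nrow(set_table), " gene sets tested, ",
      sum(set_table$significant), " significant")

  res <- structure(list(scan = scan, null = null, snp_scores = scores,
                        mapping = mapping, gene_table = gene_table,
                        set_table = set_table,
                        critical_value = critical_value(null, alpha),
                        alpha = alpha, window = window, seed = seed),
                   class = "study_result")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(scores, file.path(outdir, "snp_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(mapping$assignments,
                       file.path(outdir, "snp_gene_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(format(null$maxima, digits = 17),
               file.path(outdir, "null_maxima.txt"))
    write_enrichment(gene_table, file.path(outdir, "gene_enrichment.tsv"))
    write_enrichment(set_table, file.path(outdir, "set_enrichment.tsv"))
  }
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result: critical accuracy",
      format(as.numeric(x$critical_value), digits = 4), "(alpha =",
      x$alpha, ")\n  ", sum(x$snp_scores$significant),
      "significant SNPs, ", sum(x$gene_table$significant),
      "significant genes, ", sum(x$set_table$significant),
      "significant gene sets\n")
  invisible(x)
}

#' Cross-cohort replication of gene-set findings
#'
#' A set replicates when its p-value is at or below `alpha` in both the
#' detection and the replication cohort (inclusive at exactly `alpha`).
#' Replication across independent cohorts is the pipeline's control for
#' false positives across many sets, in place of a within-study
#' multiple-testing adjustment. Sets present in only one table are kept
#' but marked non-comparable.
#'
#' @param detection,replication set-level tables from
#'   [pathway_enrichment()] (or the `set_table` of [run_study()]).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `entity_id`, `p_detection`,
#'   `p_replication`, `comparable`, `replicated`, ordered by the larger
#'   of the two p-values.
#' @export
replicate_sets <- function(detection, replication, alpha = 0.05) {
  if (inherits(detection, "study_result"))
    detection <- detection$set_table
  if (inherits(replication, "study_result"))
    replication <- replication$set_table
  all_sets <- union(detection$entity_id, replication$entity_id)
  pd <- detection$p_value[match(all_sets, detection$entity_id)]
  pr <- replication$p_value[match(all_sets, replication$entity_id)]
  comparable <- !is.na(pd) & !is.na(pr)
  replicated <- comparable & pd <= alpha & pr <= alpha
  out <- data.frame(entity_id = all_sets, p_detection = pd,
                    p_replication = pr, comparable = comparable,
                    replicated = replicated, stringsAsFactors = FALSE)
  out <- out[order(pmax(out$p_detection, out$p_replication,
                        na.rm = TRUE), out$entity_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run detection and replication cohorts and assess replication
#'
#' Convenience wrapper: runs [run_study()] on each cohort (each with its
#' own independent permutation null) against shared annotation and gene
#' sets, then applies the replication criterion.
#'
#' @param detection,replication [genotype_study()] objects.
#' @param snp_map,genes,sets shared inputs; see [run_study()].
#' @param seed base seed; the replication cohort uses `seed +
#'   n_permutations + 1` so the two permutation streams never overlap.
#' @param ... further arguments passed to [run_study()].
#' @inheritParams run_study
#' @return list with `detection`, `replication` (study_result) and
#'   `replication_table` from [replicate_sets()].
#' @export
run_cohort_pair <- function(detection, replication, snp_map, genes,
                            sets, alpha = 0.05,
                            n_permutations = 1000, seed = 1, ...) {
  det <- run_study(detection, snp_map, genes, sets, alpha = alpha,
                   n_permutations = n_permutations, seed = seed, ...)
  rep_ <- run_study(replication, snp_map, genes, sets, alpha = alpha,
                    n_permutations = n_permutations,
                    seed = seed + n_permutations + 1, ...)
  list(detection = det, replication = rep_,
       replication_table = replicate_sets(det$set_table, rep_$set_table,
                                          alpha = alpha))
}

#' Run the pipeline from a configuration list or YAML file
#'
#' The configuration mirrors [run_study()]: keys `alpha`, `window`,
#' `n_permutations`, `seed`, `statistic`, `tie_rule`, `outdir` and a
#' `files` block with `detection_genotypes`, `replication_genotypes`
#' (optional), `genotype_format`, `snp_map`, `annotation`, `gene_sets`.
#'
#' @param config named list, or path to a YAML file with these keys.
#' @return the [run_cohort_pair()] result when a replication cohort is
#'   configured, otherwise a single [run_study()] result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  f <- config$files
  if (is.null(f)) stop("config must contain a 'files' block")
  fmt <- f$genotype_format %||% "mdr_flat"
  det <- read_genotypes(f$detection_genotypes, format = fmt)
  snp_map <- read_snp_map(f$snp_map)
  genes <- read_gene_annotation(f$annotation)
  sets <- read_gene_sets(f$gene_sets)
  args <- list(snp_map = snp_map, genes = genes, sets = sets,
               alpha = config$alpha %||% 0.05,
               window = config$window %||% 500000,
               n_permutations = config$n_permutations %||% 1000,
               seed = config$seed %||% 1,
               statistic = config$statistic %||% "accuracy",
               tie_rule = config$tie_rule %||% "high")
  if (!is.null(f$replication_genotypes)) {
    rep_ <- read_genotypes(f$replication_genotypes, format = fmt)
    res <- do.call(run_cohort_pair,
                   c(list(detection = det, replication = rep_), args))
    if (!is.null(config$outdir)) {
      dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(res$replication_table,
                         file.path(config$outdir, "replication.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res
  } else {
    do.call(run_study, c(list(study = det), args,
                         list(outdir = config$outdir)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
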