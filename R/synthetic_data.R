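#' XOR penetrance model for a purely epistatic SNP pair
#'
#' Disease probability `baseline + effect` when the combined
#' minor-allele count of the two SNPs is odd, `baseline` otherwise. At
#' minor-allele frequency 0.5 at both loci the single-SNP marginal
#' penetrance is constant, so the pair is invisible to marginal tests —
#' the canonical nonadditive signal for validating interaction scans.
#'
#' @param maf1,maf2 minor-allele frequencies of the two functional SNPs
#'   (default 0.5, where the model is purely epistatic).
#' @param baseline baseline disease probability (default 0.1).
#' @param effect additive offset applied to odd-parity cells (default
#'   0.4); `baseline + effect` must stay within `[0, 1]`.
#' @return A `penetrance_model`: list with the 3x3 probability `table`
#'   (rows = genotype of SNP 1, columns = SNP 2), `maf1` and `maf2`.
#' @export
xor_penetrance <- function(maf1 = 0.5, maf2 = 0.5, baseline = 0.1,
                           effect = 0.4) {
  if (maf1 <= 0 || maf1 > 0.5 || maf2 <= 0 || maf2 > 0.5)
    stop("minor-allele frequencies must lie in (0, 0.5]")
  if (baseline < 0 || baseline > 1 || baseline + effect < 0 ||
      baseline + effect > 1)
    stop("penetrance out of range: baseline and baseline + effect must ",
         "lie in [0, 1]")
  g <- 0:2
  parity <- outer(g, g, function(a, b) (a + b) %% 2 == 1)
  tab <- matrix(baseline, 3, 3, dimnames = list(0:2, 0:2))
  tab[parity] <- baseline + effect
  structure(list(table = tab, maf1 = maf1, maf2 = maf2),
            class = "penetrance_model")
}

#' Lay out the shared ground truth for a pair of synthetic cohorts
#'
#' Builds the fixed, population-level side of a simulation: SNP
#' positions on synthetic chromosomes, gene models hosting them, a
#' target gene set containing the genes that host the functional SNP
#' pair, size-matched decoy sets, background minor-allele frequencies,
#' and the penetrance model. Both cohorts of a detection/replication
#' pair share one truth; only the genotype draws differ.
#'
#' Genes are 100 kb long and spaced so that adjacent +/-500 kb windows
#' never overlap: each SNP maps to exactly one gene. SNPs sit inside
#' gene bodies, `snps_per_gene` per gene. The two functional SNPs are
#' the first SNPs of the first two target-set genes.
#'
#' @param n_snps total SNP count (default 500).
#' @param snps_per_gene SNPs hosted per gene (default 5).
#' @param genes_per_set genes per gene set (default 3).
#' @param n_decoy_sets decoy sets of the same size as the target
#'   (default 20).
#' @param penetrance a [xor_penetrance()] model, or NULL for a null
#'   truth with no functional pair.
#' @param seed seed for the background allele-frequency draw.
#' @return A `synthetic_truth`: list with `snp_map`, `genes` (both in
#'   [read_snp_map()] / [read_gene_annotation()] layout), `sets`
#'   (`gene_set_collection`, target set first, named `TARGET`),
#'   `target_set`, `functional` (data.frame of functional SNP/gene
#'   pairs, zero rows for a null truth), `mafs`, `penetrance`, `n_snps`.
#' @export
make_synthetic_truth <- function(n_snps = 500, snps_per_gene = 5,
                                 genes_per_set = 3, n_decoy_sets = 20,
                                 penetrance = xor_penetrance(),
                                 seed = 1) {
  n_genes <- ceiling(n_snps / snps_per_gene)
  if ((1 + n_decoy_sets) * genes_per_set > n_genes)
    stop("not enough genes to form ", 1 + n_decoy_sets,
         " disjoint sets of ", genes_per_set)
  gene_len <- 100000
  gap <- 1200000   # > 2 * 500 kb so windows of adjacent genes are disjoint
  genes_per_chrom <- 10
  idx <- seq_len(n_genes) - 1
  chrom <- paste0("chr", idx %/% genes_per_chrom + 1)
  slot <- idx %% genes_per_chrom
  start <- as.integer(1 + slot * (gene_len + gap))
  genes <- data.frame(gene_id = sprintf("GENE%03d", idx + 1),
                      chromosome = chrom, start = start,
                      end = as.integer(start + gene_len - 1),
                      stringsAsFactors = FALSE)

  host <- rep(seq_len(n_genes), each = snps_per_gene)[seq_len(n_snps)]
  within <- (seq_len(n_snps) - 1) %% snps_per_gene
  pos <- genes$start[host] +
    as.integer(within * (gene_len / snps_per_gene)) + 10L
  snp_map <- data.frame(snp_id = sprintf("rs%05d", seq_len(n_snps)),
                        chromosome = genes$chromosome[host],
                        position = pos, stringsAsFactors = FALSE)

  set_genes <- split(genes$gene_id[seq_len((1 + n_decoy_sets) *
                                             genes_per_set)],
                     rep(seq_len(1 + n_decoy_sets), each = genes_per_set))
  set_names <- c("TARGET", sprintf("DECOY%02d", seq_len(n_decoy_sets)))
  names(set_genes) <- set_names
  sets <- structure(list(sets = set_genes,
                         branch = stats::setNames(
                           rep("unspecified", length(set_names)),
                           set_names)),
                    class = "gene_set_collection")

  functional <- data.frame(snp_id = character(), gene_id = character(),
                           stringsAsFactors = FALSE)
  if (!is.null(penetrance)) {
    stopifnot(inherits(penetrance, "penetrance_model"))
    # first SNP of target genes 1 and 2
    f_idx <- c(which(host == 1)[1], which(host == 2)[1])
    functional <- data.frame(snp_id = snp_map$snp_id[f_idx],
                             gene_id = genes$gene_id[host[f_idx]],
                             stringsAsFactors = FALSE)
  }
  mafs <- with_seed(seed, stats::runif(n_snps, 0.05, 0.5))
  if (!is.null(penetrance)) {
    f_idx <- match(functional$snp_id, snp_map$snp_id)
    mafs[f_idx] <- c(penetrance$maf1, penetrance$maf2)
  }
  structure(list(snp_map = snp_map, genes = genes, sets = sets,
                 target_set = "TARGET", functional = functional,
                 mafs = mafs, penetrance = penetrance, n_snps = n_snps,
                 seed = seed),
            class = "synthetic_truth")
}

#' Simulate one case-control cohort from a synthetic truth
#'
#' Background SNPs are drawn under Hardy-Weinberg equilibrium,
#' independent of phenotype. The functional pair (when the truth has
#' one) is drawn by rejection sampling from the penetrance model
#' conditional on case/control status, matching case-control
#' ascertainment: a candidate genotype pair from the HWE joint
#' distribution is accepted for a case with probability `f(g1, g2)` and
#' for a control with probability `1 - f(g1, g2)`.
#'
#' @param truth a [make_synthetic_truth()].
#' @param n_cases,n_controls cohort composition (defaults 250/250,
#'   matching typical single-site GWAS cohorts of a few hundred
#'   subjects per arm).
#' @param seed seed for the genotype draw; two cohorts from the same
#'   truth with different seeds are independent.
#' @param max_tries rejection-sampling attempts per individual before
#'   giving up (default 10000).
#' @return A `synthetic_cohort`: list with `study`
#'   ([genotype_study()]), and the truth's `snp_map`, `genes`, `sets`,
#'   `truth`.
#' @export
simulate_cohort <- function(truth, n_cases = 250, n_controls = 250,
                            seed = 1, max_tries = 10000) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_cases < 1 || n_controls < 1)
    stop("need at least one case and one control")
  n_ind <- n_cases + n_controls
  study <- with_seed(seed, {
    g <- vapply(truth$mafs,
                function(m) stats::rbinom(n_ind, 2, m),
                integer(n_ind))
    phenotype <- rep(c(1L, 0L), c(n_cases, n_controls))
    if (!is.null(truth$penetrance)) {
      f_idx <- match(truth$functional$snp_id, truth$snp_map$snp_id)
      fg <- draw_functional_pair(truth$penetrance, phenotype, max_tries)
      g[, f_idx[1]] <- fg[, 1]
      g[, f_idx[2]] <- fg[, 2]
    }
    genotype_study(g, truth$snp_map$snp_id, phenotype)
  })
  structure(list(study = study, snp_map = truth$snp_map,
                 genes = truth$genes, sets = truth$sets, truth = truth,
                 seed = seed),
            class = "synthetic_cohort")
}

# rejection-sample genotypes at the functional pair conditional on
# case/control status
draw_functional_pair <- function(penetrance, phenotype, max_tries) {
  n <- length(phenotype)
  out <- matrix(0L, n, 2)
  p1 <- stats::dbinom(0:2, 2, penetrance$maf1)
  p2 <- stats::dbinom(0:2, 2, penetrance$maf2)
  f <- penetrance$table
  for (r in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      g1 <- sample.int(3, 1, prob = p1) - 1L
      g2 <- sample.int(3, 1, prob = p2) - 1L
      pr <- f[g1 + 1, g2 + 1]
      acc <- if (phenotype[r] == 1L) pr else 1 - pr
      if (stats::runif(1) < acc) {
        out[r, ] <- c(g1, g2)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("rejection sampling failed after ", max_tries,
           " attempts; the penetrance model is incompatible with the ",
           "requested phenotype")
  }
  out
}

#' Write a synthetic cohort as the four pipeline input files
#'
#' Emits exactly the formats [read_genotypes()], [read_snp_map()],
#' [read_gene_annotation()] and [read_gene_sets()] consume, so
#' file-level runs can be exercised end to end.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.txt"),
             snp_map = file.path(dir, "snp_map.tsv"),
             annotation = file.path(dir, "genes.bed"),
             gene_sets = file.path(dir, "sets.gmt"))
  write_genotypes(cohort$study, paths[["genotypes"]])
  write_snp_map(cohort$snp_map, paths[["snp_map"]])
  write_gene_annotation(cohort$genes, paths[["annotation"]])
  write_gene_sets(cohort$sets, paths[["gene_sets"]])
  paths
}
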