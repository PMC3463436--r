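#' Two-SNP genotype contingency table
#'
#' Cross-tabulates cases and controls over the nine joint genotype
#' combinations of two SNPs. Individuals missing a call at either SNP are
#' dropped from this pair only (pairwise-complete deletion). The
#' case:control ratio among the retained individuals is the threshold T
#' against which cells are later pooled into HIGH/LOW risk classes.
#'
#' @param study a [genotype_study()].
#' @param i,j distinct SNP column indices.
#' @return A `pair_table`: list with 3x3 integer matrices `cases` and
#'   `controls` (rows = genotype of SNP i, columns = genotype of SNP j),
#'   totals `n_cases`, `n_controls`, the ratio `threshold`, and the SNP
#'   indices.
#' @export
build_pair_table <- function(study, i, j) {
  stopifnot(inherits(study, "genotype_study"))
  n_snp <- ncol(study$genotypes)
  if (i == j) stop("i and j must differ")
  if (i < 1 || j < 1 || i > n_snp || j > n_snp)
    stop("SNP index out of range")
  gi <- study$genotypes[, i]
  gj <- study$genotypes[, j]
  keep <- !is.na(gi) & !is.na(gj)
  if (!any(!is.na(gi)) || !any(!is.na(gj)))
    stop("degenerate pair: all individuals missing at a SNP")
  if (!any(keep))
    stop("degenerate pair: no individual observed at both SNPs")
  gi <- gi[keep]; gj <- gj[keep]
  ph <- study$phenotype[keep]
  cases <- matrix(0L, 3, 3, dimnames = list(0:2, 0:2))
  controls <- matrix(0L, 3, 3, dimnames = list(0:2, 0:2))
  for (r in seq_along(ph)) {
    a <- gi[r] + 1L; b <- gj[r] + 1L
    if (ph[r] == 1L) cases[a, b] <- cases[a, b] + 1L
    else controls[a, b] <- controls[a, b] + 1L
  }
  n_cases <- sum(cases); n_controls <- sum(controls)
  if (n_controls == 0L)
    stop("degenerate pair: no controls remain after pairwise deletion")
  if (n_cases == 0L)
    stop("degenerate pair: no cases remain after pairwise deletion")
  structure(list(cases = cases, controls = controls, n_cases = n_cases,
                 n_controls = n_controls,
                 threshold = n_cases / n_controls, snp_i = i, snp_j = j),
            class = "pair_table")
}

#' Pool genotype cells into HIGH/LOW risk classes
#'
#' A cell is HIGH risk when its case:control ratio reaches the
#' sample-wide ratio T = n_cases / n_controls; the comparison is done by
#' exact integer cross-multiplication so ties are unambiguous. With the
#' default `tie_rule = "high"` a cell exactly at T is HIGH (the classical
#' MDR convention). Cells with cases but no controls are HIGH; empty
#' cells are LOW.
#'
#' @param table a [build_pair_table()] result.
#' @param tie_rule `"high"` (default) or `"low"`: label for cells whose
#'   ratio equals T exactly.
#' @return 3x3 character matrix of `"HIGH"` / `"LOW"`.
#' @export
label_cells <- function(table, tie_rule = c("high", "low")) {
  stopifnot(inherits(table, "pair_table"))
  tie_rule <- match.arg(tie_rule)
  ca <- table$cases; co <- table$controls
  lhs <- ca * table$n_controls
  rhs <- co * table$n_cases
  high <- if (tie_rule == "high") lhs >= rhs else lhs > rhs
  high[ca == 0 & co == 0] <- FALSE
  lab <- matrix(ifelse(high, "HIGH", "LOW"), 3, 3,
                dimnames = dimnames(ca))
  lab
}

#' Classification accuracy of a pooled risk model
#'
#' Accuracy of the one-dimensional HIGH/LOW attribute as a classifier of
#' case-control status: cases in HIGH cells and controls in LOW cells are
#' classified correctly. `"balanced_accuracy"` averages sensitivity and
#' specificity instead, which is insensitive to class imbalance.
#'
#' @param table a [build_pair_table()] result.
#' @param labels 3x3 `"HIGH"`/`"LOW"` matrix from [label_cells()].
#' @param statistic `"accuracy"` (default) or `"balanced_accuracy"`.
#' @return accuracy in `[0, 1]`.
#' @export
pair_accuracy <- function(table, labels,
                          statistic = c("accuracy", "balanced_accuracy")) {
  stopifnot(inherits(table, "pair_table"))
  statistic <- match.arg(statistic)
  if (!all(dim(labels) == c(3, 3)) || !all(labels %in% c("HIGH", "LOW")))
    stop("labels must be a 3x3 HIGH/LOW matrix")
  n <- table$n_cases + table$n_controls
  if (n == 0) stop("empty table")
  high <- labels == "HIGH"
  tp <- sum(table$cases[high])
  tn <- sum(table$controls[!high])
  if (statistic == "balanced_accuracy")
    0.5 * (tp / table$n_cases + tn / table$n_controls)
  else
    (tp + tn) / n
}

#' Number of unordered SNP pairs
#'
#' `C(n, 2)` computed exactly in double precision (exact up to n ~ 1e8,
#' far beyond array sizes: 550,000 SNPs give 151,249,725,000 pairs).
#'
#' @param n_snps number of SNPs.
#' @return number of distinct unordered pairs.
#' @export
pair_count <- function(n_snps) {
  n <- as.numeric(n_snps)
  n * (n - 1) / 2
}

#' Exhaustive pairwise MDR scan
#'
#' Evaluates every unordered SNP pair exactly once: builds the
#' pairwise-complete 3x3 table, pools cells into HIGH/LOW risk classes
#' against the sample case:control ratio, and scores the pooled
#' attribute by classification accuracy. Pairs where one class vanishes
#' after pairwise deletion are recorded with accuracy 0 and flagged
#' degenerate. The loop runs in compiled code.
#'
#' @param study a [genotype_study()].
#' @param statistic `"accuracy"` (default) or `"balanced_accuracy"`.
#' @param tie_rule `"high"` (default) or `"low"`.
#' @return An `mdr_scan` object: list with `accuracy` (length
#'   `choose(n_snps, 2)`, pair (i, j) with i < j in row-major order),
#'   `degenerate`, `best_per_snp` (named), `has_valid_pair`,
#'   `max_accuracy`, `n_pairs`, `snp_ids` and the settings used.
#' @export
scan_all_pairs <- function(study,
                           statistic = c("accuracy", "balanced_accuracy"),
                           tie_rule = c("high", "low")) {
  stopifnot(inherits(study, "genotype_study"))
  statistic <- match.arg(statistic)
  tie_rule <- match.arg(tie_rule)
  if (ncol(study$genotypes) < 2) stop("at least 2 SNPs required")
  res <- scan_pairs_cpp(study$genotypes, study$phenotype,
                        statistic == "balanced_accuracy",
                        tie_rule == "high")
  names(res$best_per_snp) <- study$snp_ids
  structure(list(accuracy = res$accuracy, degenerate = res$degenerate,
                 best_per_snp = res$best_per_snp,
                 has_valid_pair = res$has_valid_pair,
                 max_accuracy = res$max_accuracy,
                 n_pairs = length(res$accuracy),
                 snp_ids = study$snp_ids, statistic = statistic,
                 tie_rule = tie_rule),
            class = "mdr_scan")
}

#' @export
print.mdr_scan <- function(x, ...) {
  cat("mdr_scan:", length(x$snp_ids), "SNPs,", x$n_pairs,
      "pairs, max", x$statistic, "=", format(x$max_accuracy, digits = 4),
      "\n")
  if (any(x$degenerate))
    cat("  degenerate pairs:", sum(x$degenerate), "\n")
  invisible(x)
}

#' Indices of the SNPs forming pair slot `p` of a scan
#'
#' Inverse of the row-major pair ordering used by [scan_all_pairs()].
#'
#' @param p pair slot (1-based).
#' @param n_snps number of SNPs in the scan.
#' @return integer vector `c(i, j)` with `i < j`.
#' @export
pair_index <- function(p, n_snps) {
  stopifnot(p >= 1, p <= pair_count(n_snps))
  p0 <- p - 1
  i <- 0
  left <- n_snps - 1
  while (p0 >= left) {
    p0 <- p0 - left
    i <- i + 1
    left <- left - 1
  }
  c(i + 1L, i + 1L + p0 + 1L)
}
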