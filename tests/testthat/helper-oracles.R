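# Independent reference implementations used to check the package's
# vectorized/compiled paths. Deliberately written as direct per-cell /
# per-draw counting, not shared with any package code.

# accuracy of one SNP pair by direct iteration over the 9 genotype cells
naive_pair_stats <- function(geno, pheno, i, j, statistic = "accuracy",
                             tie = "high") {
  gi <- geno[, i]; gj <- geno[, j]
  keep <- !is.na(gi) & !is.na(gj)
  gi <- gi[keep]; gj <- gj[keep]; ph <- pheno[keep]
  ncase <- sum(ph == 1); nctrl <- sum(ph == 0)
  if (ncase == 0 || nctrl == 0)
    return(list(acc = 0, degenerate = TRUE))
  tp <- 0; tn <- 0
  for (a in 0:2) {
    for (b in 0:2) {
      ca <- sum(gi == a & gj == b & ph == 1)
      co <- sum(gi == a & gj == b & ph == 0)
      high <- if (ca == 0 && co == 0) {
        FALSE
      } else if (tie == "high") {
        ca * nctrl >= co * ncase
      } else {
        ca * nctrl > co * ncase
      }
      if (high) tp <- tp + ca else tn <- tn + co
    }
  }
  acc <- if (statistic == "balanced_accuracy")
    0.5 * (tp / ncase + tn / nctrl)
  else
    (tp + tn) / (ncase + nctrl)
  list(acc = acc, degenerate = FALSE)
}

# triple-loop exhaustive scan
naive_scan <- function(study, statistic = "accuracy", tie = "high") {
  g <- study$genotypes; ph <- study$phenotype
  n <- ncol(g)
  acc <- numeric(0); degen <- logical(0)
  best <- rep(0, n); has <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- naive_pair_stats(g, ph, i, j, statistic, tie)
      acc <- c(acc, s$acc); degen <- c(degen, s$degenerate)
      if (!s$degenerate) {
        for (x in c(i, j)) {
          if (!has[x] || s$acc > best[x]) {
            best[x] <- s$acc; has[x] <- TRUE
          }
        }
      }
    }
  }
  list(accuracy = acc, degenerate = degen, best_per_snp = best,
       has_valid_pair = has,
       max_accuracy = if (any(!degen)) max(acc[!degen]) else 0)
}

# hypergeometric upper tail by exhaustive enumeration of all C(M, n)
# draws from a universe whose first K items are successes
enum_hypergeom <- function(M, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(M, n)
  hits <- colSums(draws <= K)
  sum(hits >= k) / ncol(draws)
}

# naive all-pairs interval check for the SNP-to-gene window
naive_window_map <- function(snp_map, genes, W) {
  out <- NULL
  for (s in seq_len(nrow(snp_map))) {
    for (g in seq_len(nrow(genes))) {
      if (snp_map$chromosome[s] == genes$chromosome[g] &&
          snp_map$position[s] >= genes$start[g] - W &&
          snp_map$position[s] <= genes$end[g] + W) {
        out <- rbind(out, data.frame(snp_id = snp_map$snp_id[s],
                                     gene_id = genes$gene_id[g],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(snp_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  out
}

# random small study, optionally with missing calls
random_study <- function(n_ind, n_snp, miss = 0, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, n_ind * n_snp, replace = TRUE), n_ind, n_snp)
  if (miss > 0)
    g[matrix(runif(n_ind * n_snp) < miss, n_ind, n_snp)] <- NA
  ph <- integer(n_ind)
  ph[sample(n_ind, max(1, floor(n_ind / 2)))] <- 1L
  if (all(ph == 1L)) ph[1] <- 0L
  genotype_study(g, paste0("s", seq_len(n_snp)), ph)
}
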