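#' Permute case-control labels
#'
#' Uniform random rearrangement of the phenotype vector, preserving the
#' case and control totals. Deterministic given `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param phenotype binary 0/1 label vector with at least one of each.
#' @param seed integer seed.
#' @return permuted label vector of the same length.
#' @export
permute_labels <- function(phenotype, seed) {
  if (!any(phenotype == 1) || !any(phenotype == 0))
    stop("need at least one case and one control")
  with_seed(seed, sample(phenotype))
}

# run `expr` under `seed` and restore the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# tolerance for >= comparisons between accuracies (doubles built from
# small-integer ratios; 1e-12 is far below any attainable spacing)
ACC_TOL <- 1e-12

#' Genome-wide null distribution of the maximum pair accuracy
#'
#' Randomizes the case-control labels `n_permutations` times, rescans
#' all SNP pairs in each null dataset, and records the best accuracy per
#' permutation. Because each permutation takes the maximum over the same
#' number of models as the observed scan, quantiles of this distribution
#' give genome-wide (family-wise) significance thresholds. Permutation k
#' uses seed `seed + k`, so the null is reproducible and each permutation
#' independent of the observed labels.
#'
#' @param study a [genotype_study()].
#' @param n_permutations number of label permutations (default 1000).
#' @param seed base integer seed.
#' @param alpha significance level attached to the null (default 0.05).
#' @param statistic,tie_rule passed to the scan; see [scan_all_pairs()].
#' @return A `null_max_dist` object: list with `maxima` (length
#'   `n_permutations`), `n_permutations`, `seed`, `alpha` and the scan
#'   settings.
#' @export
build_null <- function(study, n_permutations = 1000, seed = 1,
                       alpha = 0.05,
                       statistic = c("accuracy", "balanced_accuracy"),
                       tie_rule = c("high", "low")) {
  stopifnot(inherits(study, "genotype_study"))
  statistic <- match.arg(statistic)
  tie_rule <- match.arg(tie_rule)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (ncol(study$genotypes) < 2) stop("at least 2 SNPs required")
  perms <- vapply(seq_len(n_permutations),
                  function(k) permute_labels(study$phenotype, seed + k),
                  integer(length(study$phenotype)))
  maxima <- null_maxima_cpp(study$genotypes, perms,
                            statistic == "balanced_accuracy",
                            tie_rule == "high")
  structure(list(maxima = as.numeric(maxima),
                 n_permutations = n_permutations, seed = seed,
                 alpha = alpha, statistic = statistic,
                 tie_rule = tie_rule),
            class = "null_max_dist")
}

#' @export
print.null_max_dist <- function(x, ...) {
  cat("null_max_dist:", x$n_permutations, "permutation maxima,",
      "median", format(stats::median(x$maxima), digits = 4),
      " critical value (alpha =", x$alpha, "):",
      format(critical_value(x), digits = 4), "\n")
  invisible(x)
}

#' Critical accuracy at a given significance level
#'
#' The smallest observed null maximum `v` whose upper-tail fraction
#' `#\{maxima >= v\} / N` does not exceed `alpha`: any observed accuracy
#' at or above `c` is genome-wide significant at that level. When no
#' observed maximum qualifies (e.g. all maxima are identical), a
#' sentinel just above the largest maximum is returned with attribute
#' `attained = FALSE`.
#'
#' @param null a [build_null()] result.
#' @param alpha significance level in (0, 1); defaults to the level
#'   stored in `null`.
#' @return critical accuracy, with attribute `attained`.
#' @export
critical_value <- function(null, alpha = null$alpha) {
  stopifnot(inherits(null, "null_max_dist"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  mx <- null$maxima
  if (!length(mx)) stop("empty null distribution")
  n <- length(mx)
  vals <- sort(unique(mx))
  for (v in vals) {
    if (sum(mx >= v - ACC_TOL) / n <= alpha)
      return(structure(v, attained = TRUE))
  }
  structure(max(mx) + 1e-6, attained = FALSE)
}

#' Permutation p-value of an observed accuracy
#'
#' Monte-Carlo p-value against the null distribution of scan maxima,
#' with the add-one convention `p = (1 + #\{maxima >= A\}) / (N + 1)` so
#' p is never exactly zero. Vectorized over `accuracy`.
#'
#' @param null a [build_null()] result.
#' @param accuracy observed accuracy value(s) in `[0, 1]`.
#' @return p-value(s) in `(0, 1]`.
#' @export
model_p_value <- function(null, accuracy) {
  stopifnot(inherits(null, "null_max_dist"))
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracy must be in [0, 1]")
  n <- null$n_permutations
  vapply(accuracy,
         function(a) (1 + sum(null$maxima >= a - ACC_TOL)) / (n + 1),
         numeric(1))
}
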