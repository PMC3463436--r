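test_that("hypergeometric upper tail matches closed-form small cases", {
  # all 3 draws from the 3 successes among 10: 1 of C(10,3) draws
  expect_equal(hypergeom_upper_tail(10, 3, 3, 3), 1 / 120,
               tolerance = 1e-12)
  # k = 0 covers the whole distribution
  expect_equal(hypergeom_upper_tail(50, 7, 12, 0), 1.0)
  # explicit binomial-coefficient sum
  expect_equal(hypergeom_upper_tail(100, 10, 5, 3),
               (choose(10, 3) * choose(90, 2) +
                  choose(10, 4) * choose(90, 1) +
                  choose(10, 5)) / choose(100, 5),
               tolerance = 1e-12)
})

test_that("hypergeometric tail equals exhaustive draw enumeration", {
  set.seed(1)
  for (rep in 1:40) {
    M <- sample(2:9, 1)
    K <- sample(0:M, 1)
    n <- sample(1:M, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper_tail(M, K, n, k),
                 enum_hypergeom(M, K, n, k), tolerance = 1e-12)
  }
})

test_that("inconsistent hypergeometric counts are rejected", {
  expect_error(hypergeom_upper_tail(10, 11, 3, 1), "K")
  expect_error(hypergeom_upper_tail(10, 3, 11, 1), "n")
  expect_error(hypergeom_upper_tail(10, 3, 3, 4), "k")
})

test_that("the tail probability is non-increasing in k", {
  p <- vapply(0:5, function(k) hypergeom_upper_tail(40, 12, 5, k),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

fake_mapping <- function(assignments) {
  structure(list(assignments = assignments, window = 5e5,
                 unassigned = character(0)),
            class = "gene_mapping")
}

fake_scores <- function(snp_id, p_value, alpha = 0.05) {
  data.frame(snp_id = snp_id, best_accuracy = 0.6, p_value = p_value,
             significant = p_value <= alpha, no_valid_pair = FALSE,
             stringsAsFactors = FALSE)
}

test_that("gene enrichment counts mapped SNPs against the mapped universe", {
  # universe: 10 mapped SNPs, 3 significant, all three in GENE_A
  snps <- sprintf("s%02d", 1:10)
  asg <- data.frame(
    snp_id = snps,
    gene_id = c(rep("GENE_A", 3), rep("GENE_B", 7)),
    stringsAsFactors = FALSE)
  scores <- fake_scores(snps, c(rep(0.01, 3), rep(0.5, 7)))
  tab <- gene_enrichment(fake_mapping(asg), scores, alpha = 0.05)
  expect_equal(tab$p_value[tab$entity_id == "GENE_A"], 1 / 120,
               tolerance = 1e-12)
  # gene with no significant SNPs scores p = 1
  expect_equal(tab$p_value[tab$entity_id == "GENE_B"], 1.0)
  expect_true(tab$significant[tab$entity_id == "GENE_A"])

  # unscored mapped SNP is an error
  expect_error(gene_enrichment(fake_mapping(asg), scores[-1, ]),
               "without scores")
})

test_that("gene enrichment equals the one-sided Fisher test", {
  set.seed(3)
  for (rep in 1:10) {
    n_snp <- sample(10:25, 1)
    snps <- sprintf("s%02d", seq_len(n_snp))
    asg <- data.frame(
      snp_id = snps,
      gene_id = sample(c("GA", "GB", "GC"), n_snp, replace = TRUE),
      stringsAsFactors = FALSE)
    pv <- ifelse(runif(n_snp) < 0.3, 0.01, 0.5)
    tab <- gene_enrichment(fake_mapping(asg), fake_scores(snps, pv))
    M <- n_snp
    K <- sum(pv <= 0.05)
    for (r in seq_len(nrow(tab))) {
      n <- tab$n_members[r]; k <- tab$n_significant[r]
      ft <- fisher.test(matrix(c(k, n - k, K - k, M - K - (n - k)),
                               2, 2), alternative = "greater")
      expect_equal(tab$p_value[r], ft$p.value, tolerance = 1e-9)
    }
  }
})

fake_gene_rows <- function(ids, p) {
  data.frame(entity_id = ids, n_members = 5, n_significant = 1,
             p_value = p, significant = p <= 0.05,
             stringsAsFactors = FALSE)
}

make_sets <- function(sets) {
  structure(list(sets = sets,
                 branch = stats::setNames(
                   rep("unspecified", length(sets)), names(sets))),
            class = "gene_set_collection")
}

test_that("pathway enrichment tests sets against the observed gene universe", {
  genes <- sprintf("G%02d", 1:10)
  rows <- fake_gene_rows(genes, c(rep(0.01, 3), rep(0.8, 7)))
  sets <- make_sets(list(HIT = genes[1:3], MISS = genes[4:6],
                         GHOST = c("X1", "X2")))
  tab <- pathway_enrichment(rows, sets, alpha = 0.05)
  expect_equal(tab$p_value[tab$entity_id == "HIT"], 1 / 120,
               tolerance = 1e-12)
  expect_equal(tab$p_value[tab$entity_id == "MISS"], 1.0)
  # set disjoint from the universe is untestable, not an error
  expect_true(tab$untestable[tab$entity_id == "GHOST"])
  expect_equal(tab$p_value[tab$entity_id == "GHOST"], 1.0)
})

test_that("set membership is matched case-insensitively", {
  rows <- fake_gene_rows(c("BrCa1", "tp53", "EGFR"), c(0.01, 0.01, 0.9))
  tab <- pathway_enrichment(rows, make_sets(list(S = c("BRCA1", "TP53"))))
  expect_equal(tab$n_members[tab$entity_id == "S"], 2L)
  expect_equal(tab$n_significant[tab$entity_id == "S"], 2L)
})

test_that("a superset with the same significant members is never more enriched", {
  genes <- sprintf("G%02d", 1:12)
  rows <- fake_gene_rows(genes, c(rep(0.01, 2), rep(0.9, 10)))
  sets <- make_sets(list(S1 = genes[1:4], S2 = genes[1:8]))
  tab <- pathway_enrichment(rows, sets)
  expect_lte(tab$p_value[tab$entity_id == "S1"],
             tab$p_value[tab$entity_id == "S2"])
})
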