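make_study <- function(g1, g2, ph) {
  genotype_study(cbind(g1, g2), c("a", "b"), ph)
}

test_that("pair tables use pairwise-complete individuals", {
  st <- make_study(c(0, 0, 1, 1, 0, 0, 1, 1),
                   c(0, 1, 0, 1, 0, 1, 0, 1),
                   c(1, 1, 1, 1, 0, 0, 0, 0))
  tab <- build_pair_table(st, 1, 2)
  expect_equal(tab$n_cases + tab$n_controls, 8)
  expect_equal(sum(tab$cases > 0 | tab$controls > 0), 4)

  # one missing call at SNP 1 drops that individual from this pair only
  st2 <- make_study(c(NA, 0, 1, 1, 0, 0, 1, 1),
                    c(0, 1, 0, 1, 0, 1, 0, 1),
                    c(1, 1, 1, 1, 0, 0, 0, 0))
  tab2 <- build_pair_table(st2, 1, 2)
  expect_equal(tab2$n_cases + tab2$n_controls, 7)

  expect_error(build_pair_table(st, 1, 1), "differ")
})

test_that("pair table counts match direct iteration on random studies", {
  for (seed in 1:5) {
    st <- random_study(50, 2, miss = 0.1, seed = seed)
    tab <- build_pair_table(st, 1, 2)
    keep <- !is.na(st$genotypes[, 1]) & !is.na(st$genotypes[, 2])
    expect_equal(tab$n_cases, sum(st$phenotype[keep] == 1))
    expect_equal(tab$n_controls, sum(st$phenotype[keep] == 0))
    for (a in 0:2) for (b in 0:2) {
      in_cell <- keep & st$genotypes[, 1] == a & st$genotypes[, 2] == b
      in_cell[is.na(in_cell)] <- FALSE
      expect_equal(tab$cases[a + 1, b + 1],
                   sum(st$phenotype == 1 & in_cell))
      expect_equal(tab$controls[a + 1, b + 1],
                   sum(st$phenotype == 0 & in_cell))
    }
  }
})

test_that("cells pool HIGH when the ratio reaches T, ties HIGH, empty LOW", {
  # 3 cases vs 1 control in cell (0,0); 1 vs 3 in (1,1); T = 1
  st <- make_study(c(0, 0, 0, 1, 0, 1, 1, 1),
                   c(0, 0, 0, 1, 0, 1, 1, 1),
                   c(1, 1, 1, 1, 0, 0, 0, 0))
  tab <- build_pair_table(st, 1, 2)
  lab <- label_cells(tab)
  expect_equal(lab[1, 1], "HIGH")   # 3:1 >= 1
  expect_equal(lab[2, 2], "LOW")    # 1:3 <  1
  expect_equal(lab[3, 3], "LOW")    # empty cell
  expect_equal(pair_accuracy(tab, lab), 0.75)  # (3 + 3) / 8

  # tie: 4 cases and 4 controls in one cell at T = 1 goes HIGH...
  st_tie <- make_study(rep(0, 8), rep(0, 8), c(1, 1, 1, 1, 0, 0, 0, 0))
  tab_tie <- build_pair_table(st_tie, 1, 2)
  expect_equal(label_cells(tab_tie)[1, 1], "HIGH")
  # ...and the single-cell model carries no information: A = 0.5
  expect_equal(pair_accuracy(tab_tie, label_cells(tab_tie)), 0.5)
  # under tie_rule = "low" the tied cell flips
  expect_equal(label_cells(tab_tie, tie_rule = "low")[1, 1], "LOW")
})

test_that("a perfectly separating XOR layout scores accuracy 1", {
  st <- make_study(c(0, 0, 1, 1, 0, 0, 1, 1),
                   c(1, 1, 0, 0, 0, 0, 1, 1),
                   c(1, 1, 1, 1, 0, 0, 0, 0))
  tab <- build_pair_table(st, 1, 2)
  lab <- label_cells(tab)
  expect_equal(lab[1, 2], "HIGH")
  expect_equal(lab[2, 1], "HIGH")
  expect_equal(lab[1, 1], "LOW")
  expect_equal(lab[2, 2], "LOW")
  expect_equal(pair_accuracy(tab, lab), 1.0)
})

test_that("scan enumerates C(n,2) pairs and matches the brute-force scan", {
  st3 <- random_study(20, 3, seed = 1)
  expect_equal(scan_all_pairs(st3)$n_pairs, 3L)
  expect_error(scan_all_pairs(random_study(10, 1, seed = 1)), "2 SNPs")

  for (seed in 1:4) {
    st <- random_study(30, 10, miss = 0.05, seed = seed)
    for (statistic in c("accuracy", "balanced_accuracy")) {
      got <- scan_all_pairs(st, statistic = statistic)
      ref <- naive_scan(st, statistic = statistic)
      expect_equal(got$accuracy, ref$accuracy, tolerance = 1e-12)
      expect_equal(unname(got$best_per_snp), ref$best_per_snp,
                   tolerance = 1e-12)
      expect_equal(got$max_accuracy, ref$max_accuracy,
                   tolerance = 1e-12)
      expect_equal(got$degenerate, ref$degenerate)
    }
  }
})

test_that("relabeling SNP order permutes the multiset of accuracies only", {
  st <- random_study(40, 8, miss = 0.05, seed = 7)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  st2 <- genotype_study(st$genotypes[, perm], st$snp_ids[perm],
                        st$phenotype)
  s1 <- scan_all_pairs(st)
  s2 <- scan_all_pairs(st2)
  expect_equal(sort(s1$accuracy), sort(s2$accuracy), tolerance = 1e-12)
  expect_equal(s1$max_accuracy, s2$max_accuracy, tolerance = 1e-12)
  expect_equal(s1$best_per_snp[st$snp_ids],
               s2$best_per_snp[st$snp_ids], tolerance = 1e-12)
})

test_that("duplicating every individual leaves every accuracy unchanged", {
  st <- random_study(25, 6, seed = 3)
  dup <- genotype_study(rbind(st$genotypes, st$genotypes), st$snp_ids,
                        c(st$phenotype, st$phenotype))
  expect_equal(scan_all_pairs(dup)$accuracy, scan_all_pairs(st)$accuracy,
               tolerance = 1e-12)
})

test_that("degenerate pairs are flagged with accuracy 0", {
  g <- cbind(c(NA, NA, NA, NA), c(0, 1, 2, 0), c(1, 1, 0, 2))
  st <- genotype_study(g, c("a", "b", "c"), c(1, 1, 0, 0))
  expect_error(build_pair_table(st, 1, 2), "missing")
  sc <- scan_all_pairs(st)
  expect_true(sc$degenerate[1])   # pair (a, b)
  expect_true(sc$degenerate[2])   # pair (a, c)
  expect_false(sc$degenerate[3])  # pair (b, c)
  expect_equal(sc$accuracy[1], 0)
  expect_false(sc$has_valid_pair[1])
})

test_that("pair counting and pair indexing are mutually consistent", {
  expect_equal(pair_count(3), 3)
  expect_equal(pair_count(10), choose(10, 2))
  p <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    p <- p + 1
    expect_equal(pair_index(p, 5), c(i, j))
  }
})
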