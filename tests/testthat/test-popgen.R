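two_group_design <- function(samples, split) {
  tibble::tibble(sample = samples,
                 population = rep(c("pop1", "pop2"),
                                  c(split, length(samples) - split)))
}

test_that("group allele frequencies count alleles correctly", {
  samples <- c("a", "b", "c", "d", "e", "f")
  calls <- make_calls(list(c("homref", "het", "homalt",
                             "missing", "missing", "missing")), samples)
  des <- two_group_design(samples, 3)
  fr <- group_allele_freqs(calls, des, "population")
  g1 <- fr[fr$group == "pop1", ]
  expect_equal(g1$alt_count, 3L)          # het + 2*homalt
  expect_equal(g1$total_alleles, 6L)
  expect_equal(g1$freq, 0.5)
  # group with nothing called is flagged undefined, not zero
  g2 <- fr[fr$group == "pop2", ]
  expect_false(g2$defined)
  expect_true(is.na(g2$freq))
})

test_that("group frequencies track simulated truth within binomial error", {
  cfg <- popgen_sim_config(n_per_pop = 60, n_loci = 200, error_rate = 0,
                           mean_depth = 40, seed = 21)
  pg <- simulate_genotypes(cfg)
  ac <- simulate_allele_counts(pg$genotypes, cfg)
  geno <- genotype_pipeline(ac)
  fr <- group_allele_freqs(geno, pg$design, "population")
  j <- dplyr::inner_join(fr[fr$group == "pop1", ], pg$truth,
                         by = c("contig", "pos"))
  se <- sqrt(pmax(j$freq_pop1 * (1 - j$freq_pop1), 1e-4) / j$total_alleles)
  expect_gt(mean(abs(j$freq - j$freq_pop1) <= 3 * se + 1e-9), 0.95)
})

test_that("heterogeneity chi-square matches the textbook oracle", {
  expect_equal(chi2_heterogeneity(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi2_heterogeneity(matrix(10, 2, 2))$p_value, 1)
  ht <- chi2_heterogeneity(matrix(c(50, 28, 8, 22), 2, byrow = TRUE))
  expect_equal(ht$statistic, 12.21288, tolerance = 1e-6)
  expect_equal(ht$p_value, 4.746e-4, tolerance = 1e-3)
  hy <- chi2_heterogeneity(matrix(c(32, 119, 10, 14), 2, byrow = TRUE),
                           yates = TRUE)
  expect_equal(hy$statistic,
               oracle_yates_closed(matrix(c(32, 119, 10, 14), 2, byrow = TRUE)),
               tolerance = 1e-8)
  expect_error(chi2_heterogeneity(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "degenerate")
})

test_that("dissimilarity follows the allele-sharing definition", {
  samples <- c("x", "y")
  # identical at one locus, homref vs het at the other -> mean(0, 0.5) = 0.25
  calls <- make_calls(list(c("homref", "homref"), c("homref", "het")),
                      samples)
  d <- pairwise_dissimilarity(calls, min_genotyped_fraction = 0)
  expect_equal(d["x", "y"], 0.25)
  # identical individuals -> 0; opposite homozygotes everywhere -> 1
  same <- make_calls(list(c("het", "het"), c("homalt", "homalt")), samples)
  expect_equal(pairwise_dissimilarity(same, 0)["x", "y"], 0)
  opp <- make_calls(list(c("homref", "homalt"), c("homalt", "homref")),
                    samples)
  expect_equal(pairwise_dissimilarity(opp, 0)["x", "y"], 1)
  # symmetry, zero diagonal, [0,1]
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(diag(unclass(d)) == 0))
  expect_true(all(unclass(d) >= 0 & unclass(d) <= 1))
})

test_that("pairs with no comparable locus are an error", {
  calls <- make_calls(list(c("homref", "missing"), c("missing", "het")),
                      c("x", "y"))
  expect_error(pairwise_dissimilarity(calls, 0), "no comparable loci")
})

test_that("neighbour joining is exact on additive matrices", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  d <- ape::cophenetic.phylo(tr)
  out <- nj_tree(d)
  expect_equal(phangorn::RF.dist(out, tr), 0)
  dd <- ape::cophenetic.phylo(out)
  expect_lt(max(abs(dd[rownames(d), colnames(d)] - d)), 1e-9)
  # three taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  lens <- setNames(t3$edge.length[match(seq_len(3), t3$edge[, 2])],
                   t3$tip.label)
  expect_equal(lens[["A"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["B"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["C"]], (4 + 5 - 3) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), ">= 3")
})

test_that("NJ is invariant to label permutation", {
  set.seed(5)
  tr <- ape::unroot(ape::rtree(7))
  d <- ape::cophenetic.phylo(tr)
  perm <- sample(nrow(d))
  out1 <- nj_tree(d)
  out2 <- nj_tree(d[perm, perm])
  expect_equal(phangorn::RF.dist(out1, out2), 0)
  c1 <- ape::cophenetic.phylo(out1)
  c2 <- ape::cophenetic.phylo(out2)
  expect_lt(max(abs(c1 - c2[rownames(c1), colnames(c1)])), 1e-9)
})

test_that("non-symmetric distance input errors", {
  d <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "symmetric")
})

test_that("locus subsampling is seeded and screens on genotyped fraction", {
  cfg <- popgen_sim_config(n_per_pop = 10, n_loci = 100, mean_depth = 12,
                           seed = 4)
  pg <- simulate_genotypes(cfg)
  ac <- simulate_allele_counts(pg$genotypes, cfg)
  calls <- call_genotypes(ac)
  s1 <- subsample_loci(calls, n_loci = 40, seed = 9)
  s2 <- subsample_loci(calls, n_loci = 40, seed = 9)
  expect_identical(s1, s2)
  sm <- locus_summary(s1)
  expect_true(all(sm$n_called > 0.6 * 20))
})

test_that("population structure shows up in dissimilarity and the NJ tree", {
  cfg <- popgen_sim_config(n_per_pop = 25, n_loci = 250, baseline_fst = 0.1,
                           mean_depth = 30, seed = 17)
  pg <- simulate_genotypes(cfg)
  ac <- simulate_allele_counts(pg$genotypes, cfg)
  geno <- genotype_pipeline(ac, min_individuals = 40)
  d <- pairwise_dissimilarity(geno)
  summ <- dissimilarity_summary(d, pg$design, "population")
  within_means <- summ$mean[startsWith(summ$comparison, "within")]
  between_mean <- summ$mean[summ$comparison == "between"]
  expect_true(all(within_means < between_mean))
  tree <- nj_tree(d)
  pop1 <- pg$design$sample[pg$design$population == "pop1"]
  expect_true(has_bipartition(tree, pop1))
})
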