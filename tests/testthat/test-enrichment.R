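test_that("category enrichment handles the flat and extreme cases", {
  background <- sprintf("g%03d", 1:200)
  map <- tibble::tibble(gene_id = background,
                        category = rep(c("half", "other"), each = 100))
  # equal proportions in DE set and background: chi2 floored at 0, p 0.5
  de_equal <- c(background[1:10], background[101:110])
  r <- enrich(de_equal, background, map)
  expect_equal(r$chi2, c(0, 0))
  expect_equal(r$one_tailed_p, c(0.5, 0.5))
  # a DE set entirely inside a category covering half the background
  de_all_in <- background[1:20]
  r2 <- enrich(de_all_in, background, map)
  half <- r2[r2$category == "half", ]
  expect_equal(half$direction, "enriched")
  expect_lt(half$one_tailed_p, 0.01)
  expect_equal(half$n_de_in_category, 20L)
  # empty DE set refuses to test
  expect_error(enrich(character(), background, map), "empty DE set")
})

test_that("enrichment one-tailed p matches the Yates oracle", {
  set.seed(7)
  background <- sprintf("g%04d", 1:500)
  map <- tibble::tibble(gene_id = background,
                        category = sample(c("c1", "c2", "c3"), 500,
                                          replace = TRUE))
  de <- sample(background, 60)
  r <- enrich(de, background, map)
  for (i in seq_len(nrow(r))) {
    a <- r$n_de_in_category[i]
    tab <- matrix(c(a, r$n_de_total[i] - a,
                    r$n_background_in_category[i] - a,
                    (500 - r$n_de_total[i]) -
                      (r$n_background_in_category[i] - a)), 2, byrow = TRUE)
    want <- oracle_chi2(tab, yates = TRUE)
    expect_equal(r$chi2[i], unname(want["stat"]), tolerance = 1e-8)
    p1 <- if (r$direction[i] == "enriched") want["p"] / 2 else 1 - want["p"] / 2
    expect_equal(r$one_tailed_p[i], unname(p1), tolerance = 1e-8)
  }
})

test_that("permuted annotation gives null-distributed, never liberal p-values", {
  set.seed(13)
  background <- sprintf("g%04d", 1:2000)
  de <- background[1:200]
  ps <- replicate(2000, {
    members <- sample(background, 500)
    map <- tibble::tibble(gene_id = members, category = "c")
    enrich(de, background, map)$one_tailed_p
  })
  # oracle: the 2x2 table under label permutation is hypergeometric; the
  # one-tailed Yates p computed from those draws must have the same
  # distribution as what enrich() reports
  oracle_ps <- replicate(2000, {
    a <- rhyper(1, 200, 1800, 500)
    tab <- matrix(c(a, 200 - a, 500 - a, 1500 - (200 - a)), 2, byrow = TRUE)
    w <- oracle_chi2(tab, yates = TRUE)
    if (a / 200 >= 500 / 2000) unname(w["p"]) / 2 else 1 - unname(w["p"]) / 2
  })
  # the distributions are discrete with heavy ties, so compare empirical
  # CDFs directly (atoms rounded so equal atoms coincide) rather than
  # relying on a two-sample KS p-value
  ps_r <- round(ps, 9)
  or_r <- round(oracle_ps, 9)
  grid <- sort(unique(c(ps_r, or_r)))
  expect_lt(max(abs(ecdf(ps_r)(grid) - ecdf(or_r)(grid))), 0.05)
  # the continuity correction may make p conservative but never liberal
  for (t in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(ps < t), t + 2 * sqrt(t * (1 - t) / 2000))
  }
})

fake_de <- function(gene_id, M, padj = rep(0.01, length(M))) {
  out <- tibble::tibble(
    gene_id = gene_id, M_shrunk = M, p_adj = padj,
    signed_fold = signed_fold(M),
    significant = padj < 0.05 & abs(M) > 1)
  class(out) <- c("de_results", class(out))
  out
}

test_that("category summaries count directions and average signed folds", {
  map <- tibble::tibble(gene_id = c("a", "b", "c"),
                        category = c("k", "k", "m"))
  de <- fake_de(c("a", "b", "c"), c(1.5, -1.5, -1.208))
  s <- category_summary(de, map)
  k <- s[s$category == "k", ]
  expect_equal(k$n_down, 1L)
  expect_equal(k$n_up, 1L)
  expect_equal(k$mean_fold, 0)    # folds 2^1.5 and -2^1.5 cancel
  m <- s[s$category == "m", ]
  expect_equal(m$mean_fold, -2.31, tolerance = 1e-3)
  # counts sum to the number of significant annotated genes
  expect_equal(sum(s$n_down + s$n_up), 3L)
  # nothing significant, nothing reported
  none <- fake_de("a", 2, padj = 0.9)
  expect_equal(nrow(category_summary(none, map)), 0)
})

test_that("SNP-to-gene proximity is strict at the window boundary", {
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", start = 100000L,
                          end = 120000L, strand = "+", feature_type = "gene")
  near <- snps_near_genes(tibble::tibble(contig = "c1", pos = 150000L),
                          genes)
  expect_equal(near$distance, 30000L)
  inside <- snps_near_genes(tibble::tibble(contig = "c1", pos = 110000L),
                            genes)
  expect_equal(inside$distance, 0L)
  # 100,000 bases away exactly is excluded (strict <); 99,999 is kept
  at <- snps_near_genes(tibble::tibble(contig = "c1", pos = 220000L), genes)
  expect_equal(nrow(at), 0)
  just <- snps_near_genes(tibble::tibble(contig = "c1", pos = 219999L), genes)
  expect_equal(just$distance, 99999L)
})

test_that("proximity mapping equals the brute-force all-pairs scan", {
  set.seed(23)
  for (i in 1:100) {
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:15),
      contig = sample(c("c1", "c2"), 15, replace = TRUE),
      start = sample.int(4e5, 15),
      strand = "+", feature_type = "gene")
    genes$end <- genes$start + sample.int(5e4, 15)
    sites <- tibble::tibble(contig = sample(c("c1", "c2"), 8, replace = TRUE),
                            pos = sample.int(5e5, 8))
    got <- snps_near_genes(sites, genes)
    want <- oracle_near_genes(sites, genes, 1e5)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("frequency-difference intersections match hand enumeration", {
  # 10 loci on one contig; loci 1..4 diverge by > 0.5, locus 5 exactly 0.5
  freqs <- dplyr::bind_rows(
    tibble::tibble(group = "pop1", contig = "c1", pos = 1000L * (1:10),
                   alt_count = 0L, total_alleles = 100L,
                   freq = c(0.9, 0.95, 0.8, 0.7, 0.75, 0.5, 0.5, 0.4, NA, 0.6),
                   defined = !is.na(freq)),
    tibble::tibble(group = "pop2", contig = "c1", pos = 1000L * (1:10),
                   alt_count = 0L, total_alleles = 100L,
                   freq = c(0.3, 0.1, 0.25, 0.1, 0.25, 0.45, 0.6, 0.5, 0.5, 0.2),
                   defined = TRUE))
  # genes: g1 near loci 1-2, g2 near loci 3-4, g3 far away
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), contig = "c1",
    start = c(500L, 3500L, 300000L), end = c(1500L, 4500L, 301000L),
    strand = "+", feature_type = "gene")
  de <- list(main = fake_de(c("g1", "g2", "g3"), c(2, 0.1, 3)))
  out <- freq_diff_intersections(freqs, de, genes, window = 2000)
  # loci 1-4 selected (diffs .6,.85,.55,.6); locus 5 diff exactly .5 excluded
  expect_equal(out$selected_loci$pos, 1000L * (1:4))
  expect_equal(out$n_skipped_undefined, 1L)
  expect_setequal(out$genes, c("g1", "g2"))
  # of those genes only g1 is differentially expressed: 1 of 2
  expect_equal(out$summary$n_genes, 2L)
  expect_equal(out$summary$n_de, 1L)
  expect_equal(out$summary$fraction_de, 0.5)
})
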