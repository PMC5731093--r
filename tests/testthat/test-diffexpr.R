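test_that("size factors follow median-of-ratios with geometric mean one", {
  m <- matrix(rpois(300, 50), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), c("a", "b", "c")))
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1], m[, 1]))),
               rep(1, 3))
  # an exactly doubled sample doubles its size factor
  m2 <- cbind(a = m[, 1], b = 2 * m[, 1])
  s <- size_factors(m2)
  expect_equal(unname(s[2] / s[1]), 2)
  expect_equal(exp(mean(log(s))), 1)
  # single gene, counts (4, 9): ratios to the geometric mean 6 are 2/3, 3/2
  s1 <- size_factors(matrix(c(4, 9), 1, dimnames = list("g", c("a", "b"))))
  expect_equal(unname(s1), c(sqrt(4 / 9), sqrt(9 / 4)))
  expect_error(size_factors(matrix(c(0, 3, 5, 0), 2)), "non-zero")
})

test_that("M and A come straight from the printed formulas", {
  ma <- ma_values(4, 16)
  expect_equal(ma$M, 2)
  expect_equal(ma$A, 3)
  expect_equal(ma_values(7, 7)$M, 0)
  expect_equal(ma_values(16, 4)$M, -2)          # antisymmetry
  both0 <- ma_values(0, 0)
  expect_true(is.na(both0$M) && is.na(both0$A))
  expect_equal(ma_values(0, 2)$M, 2)            # pseudocount 0.5 on the zero
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(99)
  for (i in 1:250) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dispersion shrinkage contracts the gene-wise spread", {
  des <- sample_design(simulate_design(1)[c(1:6, 11:16), ])
  cfg <- expr_sim_config(n_genes = 400, design = des,
                         dispersion_trend = c(0.1, 0), baseline_sdlog = 0.5,
                         seed = 14)
  ex <- simulate_expression(cfg)
  disp <- fit_dispersion(ex$counts, ex$design)
  ok <- !is.na(disp$genewise)
  expect_lt(sd(log(disp$map[ok])), sd(log(disp$genewise[ok])))
  # MAP lies between the gene-wise estimate and the trend on the log scale
  lo <- pmin(log(disp$genewise[ok]), log(disp$trend[ok]))
  hi <- pmax(log(disp$genewise[ok]), log(disp$trend[ok]))
  expect_true(all(log(disp$map[ok]) >= lo - 1e-9 &
                    log(disp$map[ok]) <= hi + 1e-9))
  # a gene-wise estimate sitting on the trend stays there
  on_trend <- ok & abs(log(disp$genewise) - log(disp$trend)) < 0.02
  if (any(on_trend)) {
    expect_lt(max(abs(log(disp$map[on_trend]) - log(disp$trend[on_trend]))),
              0.02)
  }
})

test_that("level order swap negates every fold change", {
  des <- sample_design(simulate_design(1)[c(1:6, 11:16), ])
  cfg <- expr_sim_config(n_genes = 120, design = des, seed = 15,
                         de_genes = data.frame(gene = 1:10, factor = "source",
                                               log2fc = 1.5))
  ex <- simulate_expression(cfg)
  disp <- fit_dispersion(ex$counts, ex$design)
  fwd <- wald_contrast(ex$counts, ex$design, "source",
                       levels = c("wild", "domesticated"), dispersion = disp)
  rev <- wald_contrast(ex$counts, ex$design, "source",
                       levels = c("domesticated", "wild"), dispersion = disp)
  expect_equal(fwd$M_raw, -rev$M_raw, tolerance = 1e-6)
  expect_equal(fwd$M_shrunk, -rev$M_shrunk, tolerance = 1e-6)
  expect_equal(fwd$p, rev$p, tolerance = 1e-6)
})

test_that("unshrunken estimates are unbiased at large n", {
  des <- simulate_design(6)  # 96 samples
  # modest DE fraction with balanced directions, so median-of-ratios
  # normalisation is not distorted by composition
  cfg <- expr_sim_config(n_genes = 600, design = des, seed = 16,
                         de_genes = data.frame(gene = 1:30, factor = "exercise",
                                               log2fc = rep(c(1.5, -1.5), 15)))
  ex <- simulate_expression(cfg)
  de <- wald_contrast(ex$counts, ex$design, "exercise", shrink_lfc = FALSE)
  hit <- match(ex$truth$gene_id, de$gene_id)
  expect_lt(abs(mean(de$M_raw[hit[ex$truth$log2fc > 0]]) - 1.5), 0.1)
  expect_lt(abs(mean(de$M_raw[hit[ex$truth$log2fc < 0]]) + 1.5), 0.1)
  # and the joint flag obeys its definition, monotone in the M threshold
  n_sig <- sapply(c(0.5, 1, 1.5), function(thr) {
    sum(de$p_adj < 0.05 & abs(de$M_shrunk) > thr, na.rm = TRUE)
  })
  expect_true(all(diff(n_sig) <= 0))
})

test_that("confounded designs are rejected with the aliased columns named", {
  des <- sample_design(tibble::tibble(
    sample = sprintf("s%d", 1:8),
    source = rep(c("wild", "domesticated"), each = 4),
    exercise = rep(c("control", "trained"), each = 4)))
  cfg <- expr_sim_config(n_genes = 30, design = des, seed = 17)
  ex <- simulate_expression(cfg)
  expect_error(wald_contrast(ex$counts, ex$design, "source"),
               "aliased|confounded")
})

test_that("subset contrasts drop the filtered factor and still fit", {
  des <- simulate_design(2)
  cfg <- expr_sim_config(n_genes = 80, design = des, seed = 18)
  ex <- simulate_expression(cfg)
  de <- wald_contrast(ex$counts, ex$design, "exercise",
                      subset = list(source = "wild"))
  expect_equal(attr(de, "n_samples"), 16L)
  expect_true(any(!is.na(de$p)))
})

test_that("PCA separates constructed groups and canonicalises signs", {
  set.seed(20)
  base <- rpois(300, 60)
  shift <- c(rep(0, 150), rep(2, 150))
  mk <- function(fac) matrix(rpois(300 * 5, base * 2^(shift * fac)), 300, 5)
  counts <- cbind(mk(0), mk(1))
  rownames(counts) <- sprintf("g%03d", 1:300)
  colnames(counts) <- sprintf("s%02d", 1:10)
  pc <- pca_transform(counts, n_top = 200)
  expect_gt(pc$var_explained[["PC1"]], 0.9)
  grp <- rep(c(1, 2), each = 5)
  expect_true(all(sign(pc$scores$PC1[grp == 1]) !=
                    sign(pc$scores$PC1[grp == 2])))
  # permuting samples permutes scores identically
  perm <- c(3, 1, 2, 8, 10, 4, 5, 9, 7, 6)
  pc2 <- pca_transform(counts[, perm], n_top = 200)
  expect_equal(pc2$scores$PC1, pc$scores$PC1[perm], tolerance = 1e-8)
  # identical columns are flagged degenerate
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  expect_warning(pcd <- pca_transform(same), "degenerate")
  expect_true(pcd$degenerate)
  expect_error(pca_transform(counts[, 1:2]), "3 samples")
})

test_that("size factors agree with an established implementation", {
  des <- sample_design(simulate_design(1)[c(1:4, 13:16), ])
  cfg <- expr_sim_config(n_genes = 500, design = des,
                         library_size_factors = c(1, 1.5, 0.7, 2),
                         seed = 19)
  ex <- simulate_expression(cfg)
  ours <- size_factors(ex$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(ex$counts)
  # both use median-of-ratios; ours is rescaled to geometric mean 1
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})
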