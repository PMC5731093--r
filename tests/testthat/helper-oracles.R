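# Independent oracles and fixture builders used across tests. These are
# deliberately written from first principles, separate from the package's
# implementation paths.

# genotype-calling rule table, coded cell by cell
oracle_call <- function(ref, alt, min_depth = 10, frac = 0.20) {
  total <- ref + alt
  if (total < min_depth) return("missing")
  if (ref == 0 && alt == 0) return("missing")
  if (ref > 0 && alt > 0) {
    minor <- min(ref, alt) / total
    if (minor >= frac) return("het")
    return("missing")
  }
  if (alt == 0) "homref" else "homalt"
}

# Pearson chi-square on a 2x2 table from the textbook formula
oracle_chi2 <- function(tab, yates = FALSE) {
  stopifnot(all(dim(tab) == c(2, 2)))
  N <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / N
  dev <- abs(tab - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  c(stat = stat, p = 1 - pchisq(stat, df = 1))
}

# Yates statistic closed form |ad - bc| - N/2
oracle_yates_closed <- function(tab) {
  N <- sum(tab)
  num <- N * (max(abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) - N / 2,
                  0))^2
  num / prod(rowSums(tab), colSums(tab))
}

# beta-binomial pmf by direct product (Polya urn), no gamma functions
oracle_bb_logpmf <- function(k, n, a, b) {
  lp <- lchoose(n, k)
  if (k > 0) lp <- lp + sum(log(a + 0:(k - 1)))
  if (n - k > 0) lp <- lp + sum(log(b + 0:(n - k - 1)))
  lp - sum(log(a + b + 0:(n - 1)))
}

# Benjamini-Hochberg by its brute-force step-up definition:
# p_adj(i) = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j), capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Weir-Cockerham multi-locus FST estimator for two equal-sized populations,
# ratio of averages, from genotype dosage matrices (loci x individuals)
oracle_wc_fst <- function(dos1, dos2) {
  r <- 2
  n <- ncol(dos1)
  nbar <- n
  a_sum <- 0
  abc_sum <- 0
  for (i in seq_len(nrow(dos1))) {
    p1 <- mean(dos1[i, ]) / 2
    p2 <- mean(dos2[i, ]) / 2
    h1 <- mean(dos1[i, ] == 1)
    h2 <- mean(dos2[i, ] == 1)
    pbar <- (p1 + p2) / 2
    s2 <- sum((c(p1, p2) - pbar)^2) / (r - 1)
    hbar <- (h1 + h2) / 2
    nc <- n   # equal sample sizes
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  a_sum / abc_sum
}

# build a long genotype_calls tibble from a per-locus list of genotype
# vectors over a fixed sample panel
make_calls <- function(geno_by_locus, samples) {
  rows <- lapply(seq_along(geno_by_locus), function(i) {
    tibble::tibble(contig = "chr1", pos = i * 100L, ref = "A", alt = "G",
                   sample = samples, genotype = geno_by_locus[[i]])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("genotype_calls", class(out))
  out
}

# brute-force all-pairs SNP-to-gene distance scan
oracle_near_genes <- function(sites, genes, window) {
  hits <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(genes))) {
      if (sites$contig[i] != genes$contig[j]) next
      d <- max(genes$start[j] - sites$pos[i], sites$pos[i] - genes$end[j], 0)
      if (d < window) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          contig = sites$contig[i], pos = sites$pos[i],
          gene_id = genes$gene_id[j], distance = as.integer(d))
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          gene_id = character(), distance = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(hits), contig, pos, distance, gene_id)
}

# does an unrooted tree contain the bipartition splitting `tips1` from the
# rest? checks every clade tip set against tips1 and its complement
has_bipartition <- function(tree, tips1) {
  all_tips <- tree$tip.label
  tips1 <- sort(intersect(tips1, all_tips))
  comp <- sort(setdiff(all_tips, tips1))
  parts <- ape::prop.part(tree)
  for (cl in parts) {
    tips <- sort(all_tips[cl])
    if (identical(tips, tips1) || identical(tips, comp)) return(TRUE)
  }
  FALSE
}

# 20-locus fixture with hand-enumerated outcomes under the default rules
# (>= 45 fully genotyped individuals, not all-het, >= 3 alt occurrences),
# over a 50-individual panel.
fixture_loci <- function() {
  samples <- sprintf("i%02d", 1:50)
  mk <- function(n_called, n_het, n_homalt, all_het = FALSE) {
    if (all_het) {
      g <- c(rep("het", n_called), rep("missing", 50 - n_called))
    } else {
      g <- c(rep("het", n_het), rep("homalt", n_homalt),
             rep("homref", n_called - n_het - n_homalt),
             rep("missing", 50 - n_called))
    }
    g
  }
  spec <- list(
    # retained: plenty called, mixed genotypes, >= 3 alt occurrences
    keep1 = mk(50, 5, 2),   keep2 = mk(45, 3, 0),   keep3 = mk(48, 1, 1),
    keep4 = mk(50, 0, 2),   keep5 = mk(46, 10, 10), keep6 = mk(45, 2, 3),
    keep7 = mk(50, 3, 0),   keep8 = mk(49, 25, 5),
    # removed: fewer than 45 called
    drop_cov1 = mk(44, 5, 2), drop_cov2 = mk(10, 5, 2),
    drop_cov3 = mk(0, 0, 0),  drop_cov4 = mk(44, 44, 0, all_het = TRUE),
    # removed: every called individual heterozygous
    drop_het1 = mk(50, 50, 0, all_het = TRUE),
    drop_het2 = mk(45, 45, 0, all_het = TRUE),
    # removed: fewer than 3 alternative-allele occurrences
    drop_alt1 = mk(50, 0, 1),  # 2 occurrences (one homalt)
    drop_alt2 = mk(50, 2, 0),  # 2 occurrences (two hets)
    drop_alt3 = mk(50, 0, 0),  # monomorphic reference
    drop_alt4 = mk(45, 1, 0),  # 1 occurrence
    # boundary kept: exactly 3 occurrences (one homalt + one het)
    keep9 = mk(50, 1, 1),
    # boundary kept: exactly 45 called
    keep10 = mk(45, 4, 1))
  calls <- make_calls(spec, samples)
  expected_keep <- (seq_along(spec))[startsWith(names(spec), "keep")]
  list(calls = calls, expected_pos = expected_keep * 100L,
       n_cov = 4L, n_allhet = 2L, n_alt = 4L)
}
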