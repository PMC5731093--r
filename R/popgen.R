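# Group allele frequencies, heterogeneity tests, pairwise dissimilarity and
# neighbour-joining relatedness trees.

#' Per-group alternative-allele frequencies
#'
#' For each level of a design factor and each locus: alternative-allele
#' count (het + 2 homalt over called individuals), total called alleles
#' (2 x called individuals) and frequency. Loci with zero called
#' individuals in a group get `defined = FALSE` and `freq = NA`, never 0.
#'
#' @param calls a `genotype_calls` tibble.
#' @param design a [sample_design()] (or any tibble with `sample` plus the
#'   grouping column).
#' @param group name of the design column to group by (>= 2 levels present).
#' @return tibble of class `group_freqs`: group, contig, pos, alt_count,
#'   total_alleles, freq, defined.
#' @export
group_allele_freqs <- function(calls, design, group) {
  assert_that(group %in% names(design),
              paste0("design has no column '", group, "'"))
  design <- as_tibble(design)
  x <- inner_join(as_tibble(calls), design[c("sample", group)], by = "sample")
  assert_that(length(unique(x[[group]])) >= 2,
              paste0("grouping '", group, "' needs >= 2 levels present"))
  out <- x %>%
    rename(group = all_of(group)) %>%
    group_by(.data$group, .data$contig, .data$pos) %>%
    summarise(
      alt_count = sum((.data$genotype == "het") +
                        2L * (.data$genotype == "homalt")),
      total_alleles = 2L * sum(.data$genotype != "missing"),
      .groups = "drop") %>%
    mutate(defined = .data$total_alleles > 0L,
           freq = ifelse(.data$defined,
                         .data$alt_count / .data$total_alleles, NA_real_)) %>%
    select("group", "contig", "pos", "alt_count", "total_alleles",
           "freq", "defined") %>%
    arrange(.data$group, .data$contig, .data$pos)
  class(out) <- c("group_freqs", class(out))
  out
}

#' Chi-square test for heterogeneity of allele frequencies
#'
#' Pearson chi-square on a 2x2 allele-count table (groups x alleles),
#' df = 1, upper-tail p-value; Yates' continuity correction optional
#' (default off).
#'
#' @param counts 2x2 numeric matrix of allele counts (rows = groups,
#'   columns = alleles).
#' @param yates apply Yates' continuity correction.
#' @return one-row tibble: statistic, df, p_value, yates.
#' @export
chi2_heterogeneity <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  assert_that(all(dim(counts) == c(2, 2)), "counts must be a 2x2 table")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(all(rowSums(counts) > 0) && all(colSums(counts) > 0),
              "degenerate table: a zero margin")
  ht <- suppressWarnings(chisq.test(counts, correct = yates))
  tibble(statistic = unname(ht$statistic), df = 1L,
         p_value = unname(ht$p.value), yates = yates)
}

#' Subsample loci for relatedness analysis
#'
#' Draws a seeded random subset of loci, then keeps those genotyped in more
#' than `min_genotyped_fraction` of individuals — the screen applied before
#' computing dissimilarity indices.
#'
#' @param calls a `genotype_calls` tibble.
#' @param n_loci number of loci to draw at random (all if fewer available).
#' @param min_genotyped_fraction retain drawn loci genotyped in strictly
#'   more than this fraction of individuals (default 0.60).
#' @param seed integer seed for the draw.
#' @return `genotype_calls` tibble restricted to the selected loci.
#' @export
subsample_loci <- function(calls, n_loci = 1000, min_genotyped_fraction = 0.60,
                           seed = 1L) {
  keys <- unique(locus_key(calls$contig, calls$pos))
  set.seed(seed)
  drawn <- sample(keys, min(n_loci, length(keys)))
  x <- calls[locus_key(calls$contig, calls$pos) %in% drawn, ]
  n_ind <- length(unique(calls$sample))
  sm <- locus_summary(x)
  keep <- sm$n_called > min_genotyped_fraction * n_ind
  out <- x[locus_key(x$contig, x$pos) %in%
             locus_key(sm$contig[keep], sm$pos[keep]), ]
  class(out) <- unique(c("genotype_calls", class(out)))
  out
}

#' Pairwise simple-matching dissimilarity between individuals
#'
#' Allele-sharing dissimilarity on codominant diploid calls: per locus where
#' both individuals are called, identical genotypes score 0, het versus
#' either homozygote 0.5, opposite homozygotes 1; the pair's dissimilarity
#' is the mean over comparable loci (pairwise-complete denominator). A pair
#' with no comparable locus is an error.
#'
#' @param calls a `genotype_calls` tibble, typically pre-screened with
#'   [subsample_loci()] so every locus is genotyped in more than
#'   `min_genotyped_fraction` of individuals.
#' @param min_genotyped_fraction screening threshold re-applied defensively.
#' @return symmetric matrix of class `dissim_matrix`, values in \[0, 1\],
#'   zero diagonal.
#' @export
pairwise_dissimilarity <- function(calls, min_genotyped_fraction = 0.60) {
  samples <- sort(unique(calls$sample))
  n_ind <- length(samples)
  assert_that(n_ind >= 2, "need >= 2 individuals")
  sm <- locus_summary(calls)
  keep <- sm$n_called > min_genotyped_fraction * n_ind
  calls <- calls[locus_key(calls$contig, calls$pos) %in%
                   locus_key(sm$contig[keep], sm$pos[keep]), ]
  assert_that(nrow(calls) > 0, "no loci pass the genotyped-fraction screen")
  # dosage matrix loci x individuals with NA for missing
  keys <- sort(unique(locus_key(calls$contig, calls$pos)))
  dos <- matrix(NA_real_, length(keys), n_ind,
                dimnames = list(keys, samples))
  dos[cbind(match(locus_key(calls$contig, calls$pos), keys),
            match(calls$sample, samples))] <-
    c(homref = 0, het = 1, homalt = 2, missing = NA)[calls$genotype]
  d <- matrix(0, n_ind, n_ind, dimnames = list(samples, samples))
  for (i in seq_len(n_ind - 1)) {
    for (j in (i + 1):n_ind) {
      ok <- !is.na(dos[, i]) & !is.na(dos[, j])
      if (!any(ok)) {
        rlang::abort(paste0("no comparable loci for pair ", samples[i],
                            " / ", samples[j]))
      }
      d[i, j] <- d[j, i] <- mean(abs(dos[ok, i] - dos[ok, j])) / 2
    }
  }
  class(d) <- c("dissim_matrix", class(d))
  d
}

#' Neighbour-joining tree from a dissimilarity matrix
#'
#' Saitou-Nei neighbour joining (exact on additive distances) with labels
#' ordered deterministically and negative branch lengths clamped to zero
#' with a warning.
#'
#' @param d symmetric dissimilarity/distance matrix with >= 3 labelled rows.
#' @return unrooted ape `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- unclass(d)
  assert_that(is.matrix(d) && nrow(d) == ncol(d), "d must be a square matrix")
  assert_that(nrow(d) >= 3, "neighbour joining needs >= 3 labels")
  assert_that(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
              "d must be symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    rlang::warn(paste0("clamped ", sum(tree$edge.length < 0),
                       " negative branch length(s) to 0"))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Summarise dissimilarity within and between groups
#'
#' @param d a `dissim_matrix`.
#' @param design tibble with `sample` and the grouping column.
#' @param group grouping column name.
#' @return tibble: comparison (within:<level> / between), mean, sd, n_pairs.
#' @export
dissimilarity_summary <- function(d, design, group) {
  d <- unclass(d)
  samples <- rownames(d)
  grp <- design[[group]][match(samples, design$sample)]
  assert_that(!anyNA(grp), "every sample in d must appear in the design")
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  comparison <- ifelse(grp[pairs[, 1]] == grp[pairs[, 2]],
                       paste0("within:", grp[pairs[, 1]]), "between")
  tibble(comparison = comparison, value = d[pairs]) %>%
    group_by(.data$comparison) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n_pairs = dplyr::n(), .groups = "drop") %>%
    arrange(.data$comparison)
}
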