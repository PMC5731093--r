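# Synthetic-data generators with known ground truth.
#
# The population-genetic generator follows the Balding-Nichols model: locus i
# in population j drifts around its ancestral frequency p_i with a
# locus-by-population differentiation F_ij = logistic(alpha_i + beta_j),
# the generative counterpart of the logistic FST decomposition fitted by the
# outlier scan, so parameter recovery closes the loop.

#' Configuration for the two-population genotype simulator
#'
#' Defaults emulate the study design this package targets: two populations
#' (one wild, one domesticated strain) of 60 individuals each, ~1000
#' biallelic loci, a modest baseline differentiation, and a minority of loci
#' under diversifying selection (positive locus effect alpha on the logit
#' FST scale).
#'
#' @param n_per_pop individuals per population.
#' @param n_loci number of biallelic loci.
#' @param ancestral_beta shape parameters of the Beta distribution of
#'   ancestral allele frequencies.
#' @param baseline_fst neutral locus-population FST in (0,1); mapped to the
#'   shared population effect beta on the logit scale.
#' @param selected_loci two-column data frame (`locus`, `alpha`) of loci with
#'   non-zero selection effects, or `NULL`.
#' @param mean_depth,depth_dispersion negative-binomial read-depth model for
#'   [simulate_allele_counts()] (dispersion 0 gives Poisson depths).
#' @param error_rate per-read sequencing error rate in \[0, 0.5).
#' @param seed integer seed fixing all randomness.
#' @return a `popgen_sim_config` list.
#' @export
popgen_sim_config <- function(n_per_pop = 60, n_loci = 1000,
                              ancestral_beta = c(0.8, 0.8),
                              baseline_fst = 0.05,
                              selected_loci = NULL,
                              mean_depth = 30, depth_dispersion = 0.3,
                              error_rate = 0.005, seed = 1L) {
  assert_that(baseline_fst > 0 && baseline_fst < 1,
              "baseline_fst must be in (0,1)")
  assert_that(error_rate >= 0 && error_rate < 0.5,
              "error_rate must be in [0, 0.5)")
  assert_that(n_per_pop >= 1 && n_loci >= 1, "need >= 1 individual and locus")
  if (!is.null(selected_loci)) {
    selected_loci <- as_tibble(selected_loci)
    assert_that(all(c("locus", "alpha") %in% names(selected_loci)),
                "selected_loci needs columns locus, alpha")
    assert_that(all(selected_loci$locus >= 1 & selected_loci$locus <= n_loci),
                "selected locus index out of range")
  }
  structure(list(n_pops = 2L, n_per_pop = n_per_pop, n_loci = n_loci,
                 ancestral_beta = ancestral_beta, baseline_fst = baseline_fst,
                 selected_loci = selected_loci, mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "popgen_sim_config")
}

#' Simulate two-population genotypes under the Balding-Nichols model
#'
#' Ancestral frequencies are drawn from the configured Beta distribution;
#' per-population frequencies from Beta(p(1-F)/F, (1-p)(1-F)/F) with
#' F = logistic(alpha_i + beta_j), beta_j = logit(baseline FST); genotypes
#' are Hardy-Weinberg draws within population.
#'
#' @param cfg a [popgen_sim_config()].
#' @return list with `genotypes` (long tibble: contig, pos, ref, alt, sample,
#'   genotype in homref/het/homalt), `design` (sample, population),
#'   and `truth` (locus, contig, pos, p_ancestral, alpha, freq_pop1,
#'   freq_pop2).
#' @export
simulate_genotypes <- function(cfg) {
  assert_that(inherits(cfg, "popgen_sim_config"), "cfg must be a popgen_sim_config")
  set.seed(cfg$seed)
  L <- cfg$n_loci
  alpha <- numeric(L)
  if (!is.null(cfg$selected_loci)) {
    alpha[cfg$selected_loci$locus] <- cfg$selected_loci$alpha
  }
  beta <- qlogis(cfg$baseline_fst)
  p_anc <- rbeta(L, cfg$ancestral_beta[1], cfg$ancestral_beta[2])
  p_anc <- pmin(pmax(p_anc, 0.01), 0.99)   # keep loci informative
  fst <- plogis(outer(alpha, c(beta, beta), "+"))
  fst <- pmin(pmax(fst, 1e-6), 1 - 1e-6)
  freq <- matrix(NA_real_, L, 2)
  for (j in 1:2) {
    th <- (1 - fst[, j]) / fst[, j]
    freq[, j] <- rbeta(L, th * p_anc, th * (1 - p_anc))
  }
  freq <- pmin(pmax(freq, 1e-9), 1 - 1e-9)
  # synthetic site records: one contig per 50 loci, positions spaced 1 kb
  contig <- paste0("ctg", sprintf("%04d", (seq_len(L) - 1L) %/% 50L + 1L))
  pos <- as.integer(((seq_len(L) - 1L) %% 50L + 1L) * 1000L)
  refalt <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2,
                   byrow = TRUE)[(seq_len(L) - 1L) %% 4L + 1L, , drop = FALSE]
  samples <- c(sprintf("wild_%03d", seq_len(cfg$n_per_pop)),
               sprintf("dom_%03d", seq_len(cfg$n_per_pop)))
  population <- rep(c("pop1", "pop2"), each = cfg$n_per_pop)
  n_ind <- length(samples)
  # genotype = number of alt alleles, HW within population
  dosage <- matrix(0L, L, n_ind)
  for (j in 1:2) {
    idx <- which(population == c("pop1", "pop2")[j])
    dosage[, idx] <- matrix(
      rbinom(L * length(idx), 2L, rep(freq[, j], length(idx))),
      nrow = L)
  }
  geno_levels <- c("homref", "het", "homalt")
  genotypes <- tibble(
    contig = rep(contig, n_ind), pos = rep(pos, n_ind),
    ref = rep(refalt[, 1], n_ind), alt = rep(refalt[, 2], n_ind),
    sample = rep(samples, each = L),
    genotype = geno_levels[as.vector(dosage) + 1L])
  genotypes <- arrange(genotypes, .data$contig, .data$pos, .data$sample)
  list(
    genotypes = genotypes,
    design = tibble(sample = samples, population = population),
    truth = tibble(locus = seq_len(L), contig = contig, pos = pos,
                   p_ancestral = p_anc, alpha = alpha,
                   freq_pop1 = freq[, 1], freq_pop2 = freq[, 2]))
}

#' Simulate allele read counts from genotypes
#'
#' Per (individual, site): total depth ~ NB(mean_depth, depth_dispersion);
#' alt reads ~ Binomial(depth, e) for homref, Binomial(depth, 1/2) for het,
#' Binomial(depth, 1 - e) for homalt, with e the sequencing error rate.
#'
#' @param genotypes long genotype tibble from [simulate_genotypes()].
#' @param cfg the same [popgen_sim_config()] (depth and error fields used).
#' @param seed optional seed override (defaults to `cfg$seed + 1`).
#' @return an [allele_counts()] tibble.
#' @export
simulate_allele_counts <- function(genotypes, cfg, seed = NULL) {
  assert_that(inherits(cfg, "popgen_sim_config"), "cfg must be a popgen_sim_config")
  set.seed(seed %||% (cfg$seed + 1L))
  n <- nrow(genotypes)
  if (cfg$mean_depth <= 0) {
    depth <- integer(n)
  } else if (cfg$depth_dispersion > 0) {
    depth <- rnbinom(n, mu = cfg$mean_depth, size = 1 / cfg$depth_dispersion)
  } else {
    depth <- rpois(n, cfg$mean_depth)
  }
  p_alt <- c(homref = cfg$error_rate, het = 0.5, homalt = 1 - cfg$error_rate)
  alt_depth <- rbinom(n, depth, p_alt[genotypes$genotype])
  allele_counts(tibble(
    contig = genotypes$contig, pos = genotypes$pos,
    ref = genotypes$ref, alt = genotypes$alt, sample = genotypes$sample,
    ref_depth = depth - alt_depth, alt_depth = alt_depth))
}

#' Configuration for the expression-count simulator
#'
#' Counts are negative-binomial with mean `s_j * q_gj` and gene-wise
#' dispersion following the trend `a0 + a1 / q_g` in baseline mean
#' expression; `q_gj` carries additive log2 effects for designated
#' differentially expressed genes. Defaults mirror bulk heart RNA-seq at
#' desk scale: log-normal baseline means and a dispersion trend with
#' asymptote 0.05.
#'
#' @param n_genes number of genes.
#' @param design a [sample_design()] tibble (sex, source, exercise,
#'   performance per sample); defaults to a balanced design from
#'   [simulate_design()].
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   mean expression.
#' @param dispersion_trend numeric `c(a0, a1)`, both >= 0.
#' @param de_genes data frame (`gene`, `factor`, `log2fc`) of true effects;
#'   `gene` indexes rows, `factor` one of the design factors, or `NULL`.
#' @param library_size_factors per-sample scaling (> 0), recycled.
#' @param seed integer seed.
#' @return an `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_genes = 2000, design = simulate_design(),
                            baseline_meanlog = log(100), baseline_sdlog = 1,
                            dispersion_trend = c(0.05, 5),
                            de_genes = NULL, library_size_factors = 1,
                            seed = 1L) {
  assert_that(all(dispersion_trend >= 0), "dispersion trend a0, a1 must be >= 0")
  assert_that(all(library_size_factors > 0), "library size factors must be > 0")
  design <- sample_design(design)
  if (!is.null(de_genes)) {
    de_genes <- as_tibble(de_genes)
    assert_that(all(c("gene", "factor", "log2fc") %in% names(de_genes)),
                "de_genes needs columns gene, factor, log2fc")
    assert_that(!any(duplicated(de_genes[c("gene", "factor")])),
                "duplicate (gene, factor) effect in de_genes")
    assert_that(all(de_genes$gene >= 1 & de_genes$gene <= n_genes),
                "de_genes gene index out of range")
    assert_that(all(de_genes$factor %in% DESIGN_FACTORS),
                paste0("de_genes factor must be one of: ",
                       paste(DESIGN_FACTORS, collapse = ", ")))
  }
  structure(list(n_genes = n_genes, design = design,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion_trend = dispersion_trend, de_genes = de_genes,
                 library_size_factors = library_size_factors,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate a gene-by-sample count matrix with known effects
#'
#' @param cfg an [expr_sim_config()].
#' @return list with `counts` (integer matrix, genes x samples), `design`,
#'   `truth` (gene_id, factor, log2fc), `true_dispersion`, `size_factors`.
#' @export
simulate_expression <- function(cfg) {
  assert_that(inherits(cfg, "expr_sim_config"), "cfg must be an expr_sim_config")
  set.seed(cfg$seed)
  G <- cfg$n_genes
  design <- cfg$design
  n <- nrow(design)
  gene_ids <- sprintf("gene%05d", seq_len(G))
  base_mean <- rlnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog)
  disp <- cfg$dispersion_trend[1] + cfg$dispersion_trend[2] / base_mean
  s <- rep_len(cfg$library_size_factors, n)
  log2q <- matrix(log2(base_mean), G, n)
  truth <- tibble(gene_id = character(), factor = character(),
                  log2fc = numeric())
  if (!is.null(cfg$de_genes)) {
    for (k in seq_len(nrow(cfg$de_genes))) {
      g <- cfg$de_genes$gene[k]
      fac <- cfg$de_genes$factor[k]
      lfc <- cfg$de_genes$log2fc[k]
      in_state2 <- design[[fac]] == DESIGN_LEVELS[[fac]][2]
      log2q[g, in_state2] <- log2q[g, in_state2] + lfc
    }
    truth <- tibble(gene_id = gene_ids[cfg$de_genes$gene],
                    factor = cfg$de_genes$factor,
                    log2fc = cfg$de_genes$log2fc)
  }
  mu <- sweep(2^log2q, 2, s, "*")
  counts <- matrix(rnbinom(G * n, mu = mu, size = rep(1 / disp, n)),
                   G, n, dimnames = list(gene_ids, design$sample))
  list(counts = counts, design = design, truth = truth,
       true_dispersion = setNames(disp, gene_ids),
       size_factors = setNames(s, design$sample))
}

#' Generate a balanced four-factor sample design
#'
#' Crosses sex, source, exercise regime and swimming performance with
#' `n_per_cell` samples per cell of the 2^4 design.
#'
#' @param n_per_cell samples per factor combination.
#' @return a [sample_design()] tibble.
#' @export
simulate_design <- function(n_per_cell = 2) {
  grid <- expand.grid(sex = DESIGN_LEVELS$sex, source = DESIGN_LEVELS$source,
                      exercise = DESIGN_LEVELS$exercise,
                      performance = DESIGN_LEVELS$performance,
                      rep = seq_len(n_per_cell),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sample_design(tibble(
    sample = sprintf("s%03d", seq_len(nrow(grid))),
    sex = grid$sex, source = grid$source, exercise = grid$exercise,
    performance = grid$performance))
}

DESIGN_FACTORS <- c("sex", "source", "exercise", "performance")
DESIGN_LEVELS <- list(sex = c("male", "female"),
                      source = c("wild", "domesticated"),
                      exercise = c("control", "trained"),
                      performance = c("inferior", "superior"))

#' Validate a sample-design table
#'
#' A design table has one row per sample with a `sample` id column and the
#' four experimental factors `sex` (male/female), `source`
#' (wild/domesticated), `exercise` (control/trained) and `performance`
#' (inferior/superior). Extra factor columns are allowed and kept.
#'
#' @param x data frame.
#' @return validated tibble of class `sample_design`.
#' @export
sample_design <- function(x) {
  x <- as_tibble(x)
  assert_that("sample" %in% names(x), "design needs a 'sample' column")
  assert_that(!any(duplicated(x$sample)), "duplicate sample ids in design")
  for (fac in intersect(DESIGN_FACTORS, names(x))) {
    bad <- setdiff(unique(x[[fac]]), DESIGN_LEVELS[[fac]])
    assert_that(length(bad) == 0,
                paste0("design factor '", fac, "' has invalid level(s): ",
                       paste(bad, collapse = ", ")))
  }
  class(x) <- unique(c("sample_design", class(x)))
  x
}
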