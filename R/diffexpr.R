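# Negative-binomial differential expression, described-model implementation:
# median-of-ratios normalisation, Cox-Reid adjusted gene-wise dispersion with
# an a0 + a1/mean trend and empirical-Bayes (log-normal) shrinkage to a MAP
# value, NB GLM fits by IRLS with the dispersion fixed at the MAP, shrunken
# log2 fold changes via a zero-centred normal prior on the contrast
# coefficient, Wald z tests, and Benjamini-Hochberg adjustment.

#' Coerce counts to a gene-by-sample integer matrix
#'
#' Accepts a matrix with rownames or a data frame whose first column (or a
#' column named `gene`/`gene_id`) holds gene ids.
#'
#' @param x matrix or data frame.
#' @return integer matrix with gene rownames.
#' @export
as_count_matrix <- function(x) {
  if (is.data.frame(x)) {
    gene_col <- intersect(c("gene", "gene_id"), names(x))
    gene_col <- if (length(gene_col) > 0) gene_col[1] else names(x)[1]
    genes <- as.character(x[[gene_col]])
    x <- as.matrix(x[setdiff(names(x), gene_col)])
    rownames(x) <- genes
  }
  assert_that(is.numeric(x), "counts must be numeric")
  assert_that(all(x >= 0), "counts must be non-negative")
  assert_that(max(abs(x - round(x))) < 1e-8, "counts must be integers")
  storage.mode(x) <- "double"
  x
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (with non-zero counts in every
#' sample) of the ratio of its count to the gene's geometric mean;
#' rescaled to geometric mean 1.
#'
#' @param counts gene-by-sample count matrix (see [as_count_matrix()]).
#' @return named numeric vector of size factors (> 0).
#' @export
size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  use <- rowSums(counts == 0) == 0
  assert_that(any(use),
              paste0("no gene has non-zero counts in all samples; ",
                     "filter samples or use a pseudo-reference"))
  lc <- log(counts[use, , drop = FALSE])
  lgm <- rowMeans(lc)
  s <- exp(apply(lc - lgm, 2, median))
  s <- s / exp(mean(log(s)))
  setNames(s, colnames(counts))
}

#' M (log2 fold change) and A (average log2 expression) values
#'
#' M = log2(cd2) - log2(cd1); A = (log2(cd2) + log2(cd1)) / 2, where cd1 and
#' cd2 are average normalised coverage depths in the two contrasted states.
#' A zero depth gets pseudocount 0.5; genes with both depths zero are
#' flagged `NA` (excluded from testing).
#'
#' @param cd1,cd2 non-negative average coverage depths (vectorised).
#' @return tibble with columns `M`, `A`.
#' @export
ma_values <- function(cd1, cd2) {
  assert_that(all(cd1 >= 0) && all(cd2 >= 0), "coverage depths must be >= 0")
  both_zero <- cd1 == 0 & cd2 == 0
  c1 <- ifelse(cd1 == 0, 0.5, cd1)
  c2 <- ifelse(cd2 == 0, 0.5, cd2)
  out <- tibble(M = log2(c2) - log2(c1), A = 0.5 * (log2(c2) + log2(c1)))
  out$M[both_zero] <- NA_real_
  out$A[both_zero] <- NA_real_
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values (monotone step-up procedure).
#' @export
bh_adjust <- function(p) {
  assert_that(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# NB GLM by IRLS with natural-log link, fixed dispersion, optional ridge
# penalty (prior precision per coefficient; 0 = flat). Returns coefficients,
# standard errors and fitted means.
nb_irls <- function(y, X, offset, dispersion, ridge = NULL,
                    tol = 1e-8, max_iter = 100) {
  p <- ncol(X)
  if (is.null(ridge)) ridge <- rep(0, p)
  Lambda <- diag(ridge, p)
  beta <- qr.solve(qr(X), log((y + 0.5) / exp(offset)))
  mu <- pmax(exp(drop(X %*% beta) + offset), 1e-10)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + dispersion * mu)
    z <- drop(X %*% beta) + (y - mu) / mu
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X + Lambda, XtW %*% z),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    mu <- pmax(exp(drop(X %*% beta) + offset), 1e-10)
    dev <- -2 * sum(dnbinom(y, mu = mu, size = 1 / dispersion, log = TRUE)) +
      sum(ridge * beta^2)
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  w <- mu / (1 + dispersion * mu)
  info0 <- t(X * w) %*% X
  info <- info0 + Lambda
  # standard error of the (possibly ridge-shrunken) estimator: sandwich form
  # (I + L)^-1 I (I + L)^-1, which reduces to I^-1 without a penalty
  cov <- tryCatch({
    ii <- solve(info)
    ii %*% info0 %*% ii
  }, error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, se = sqrt(pmax(diag(cov), 0)), mu = mu,
       info = info, converged = converged)
}

# Cox-Reid adjusted NB profile log-likelihood in the dispersion, fitted
# means held fixed.
nb_cr_loglik <- function(dispersion, y, mu, X) {
  ll <- sum(dnbinom(y, mu = mu, size = 1 / dispersion, log = TRUE))
  w <- mu / (1 + dispersion * mu)
  ll - 0.5 * determinant(t(X * w) %*% X, logarithm = TRUE)$modulus[1]
}

DISP_RANGE <- log(c(1e-8, 20))

#' Fit gene-wise, trended and MAP (shrunken) dispersions
#'
#' Gene-wise dispersions are Cox-Reid adjusted maximum-likelihood estimates
#' given the design; the expected-dispersion trend a0 + a1/mean is fitted by
#' iteratively reweighted gamma regression on the gene-wise estimates with
#' outlier exclusion; gene-wise estimates are then shrunk towards the trend
#' by maximising the CR likelihood plus a log-normal prior centred on the
#' trend, whose variance is estimated from the residual spread of
#' log gene-wise estimates (method of moments, floored at 0.25).
#'
#' @param counts gene-by-sample count matrix.
#' @param design a [sample_design()] covering the samples.
#' @param factors design columns to include in the model (default: all
#'   standard factors present with >= 2 levels).
#' @param sf optional pre-computed size factors.
#' @return tibble of class `dispersion_fit`: gene_id, mean_norm, genewise,
#'   trend, map; attributes `trend_coef` (a0, a1), `prior_var`, `sf`,
#'   `model_factors`.
#' @export
fit_dispersion <- function(counts, design, factors = NULL, sf = NULL) {
  counts <- as_count_matrix(counts)
  dm <- build_design_matrix(counts, design, factors)
  X <- dm$X
  counts <- dm$counts
  sf <- sf %||% size_factors(counts)
  offset <- log(sf)
  G <- nrow(counts)
  norm <- sweep(counts, 2, sf, "/")
  mean_norm <- rowMeans(norm)
  genewise <- rep(NA_real_, G)
  mu_list <- vector("list", G)
  for (g in seq_len(G)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    d0 <- max((var(norm[g, ]) - mean_norm[g]) / mean_norm[g]^2, 1e-4)
    fit <- nb_irls(y, X, offset, d0)
    opt <- optimize(function(ld) nb_cr_loglik(exp(ld), y, fit$mu, X),
                    DISP_RANGE, maximum = TRUE)
    fit <- nb_irls(y, X, offset, exp(opt$maximum))
    opt <- optimize(function(ld) nb_cr_loglik(exp(ld), y, fit$mu, X),
                    DISP_RANGE, maximum = TRUE)
    genewise[g] <- exp(opt$maximum)
    mu_list[[g]] <- fit$mu
  }
  trend <- fit_dispersion_trend(genewise, mean_norm)
  a <- trend$coef
  trend_val <- pmax(a[1] + a[2] / pmax(mean_norm, 1e-8), 1e-8)
  # prior variance: spread of log residuals minus expected sampling variance
  lr <- log(genewise) - log(trend_val)
  samp_var <- trigamma(max((ncol(counts) - ncol(X)) / 2, 0.5))
  prior_var <- max(mad(lr[trend$used], na.rm = TRUE)^2 - samp_var, 0.25)
  map <- trend_val
  for (g in seq_len(G)) {
    if (is.na(genewise[g])) next
    y <- counts[g, ]
    mu <- mu_list[[g]]
    obj <- function(ld) nb_cr_loglik(exp(ld), y, mu, X) -
      (ld - log(trend_val[g]))^2 / (2 * prior_var)
    opt <- optimize(obj, DISP_RANGE, maximum = TRUE)
    lo <- min(log(genewise[g]), log(trend_val[g]))
    hi <- max(log(genewise[g]), log(trend_val[g]))
    map[g] <- exp(min(max(opt$maximum, lo), hi))
  }
  out <- tibble(gene_id = rownames(counts), mean_norm = mean_norm,
                genewise = genewise, trend = trend_val, map = map)
  class(out) <- c("dispersion_fit", class(out))
  attr(out, "trend_coef") <- setNames(a, c("a0", "a1"))
  attr(out, "prior_var") <- prior_var
  attr(out, "sf") <- sf
  attr(out, "model_factors") <- dm$factors
  out
}

# Iteratively reweighted gamma regression of gene-wise dispersion on
# 1/mean, with outlier exclusion between iterations.
fit_dispersion_trend <- function(genewise, mean_norm) {
  use <- !is.na(genewise) & genewise > 1e-7 & mean_norm > 0
  if (sum(use) < 10) {
    rlang::warn("fewer than 10 usable genes: dispersion trend not fitted, gene-wise estimates used")
    return(list(coef = c(0, 0), used = use))
  }
  x <- 1 / mean_norm
  coef <- c(max(median(genewise[use], na.rm = TRUE), 1e-4), 1)
  for (it in 1:10) {
    fit <- tryCatch(
      glm(genewise ~ x, family = stats::Gamma(link = "identity"),
          subset = use, start = coef),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      fit <- stats::lm(genewise ~ x, subset = use)
    }
    coef_new <- pmax(stats::coef(fit), c(1e-8, 0))
    pred <- pmax(coef_new[1] + coef_new[2] * x, 1e-8)
    ratio <- genewise / pred
    use_new <- !is.na(genewise) & genewise > 1e-7 & mean_norm > 0 &
      ratio > 1e-4 & ratio < 15
    if (identical(use_new, use) ||
        max(abs(coef_new - coef) / pmax(coef, 1e-8)) < 1e-6) {
      coef <- coef_new
      use <- use_new
      break
    }
    coef <- coef_new
    use <- use_new
  }
  list(coef = unname(coef), used = use)
}

build_design_matrix <- function(counts, design, factors = NULL,
                                contrast_factor = NULL, contrast_levels = NULL) {
  design <- as_tibble(design)
  assert_that(all(colnames(counts) %in% design$sample),
              "every count column must appear in the design")
  design <- design[match(colnames(counts), design$sample), ]
  if (is.null(factors)) {
    factors <- setdiff(intersect(c(DESIGN_FACTORS, names(design)),
                                 names(design)), "sample")
    factors <- factors[vapply(factors,
                              function(f) length(unique(design[[f]])) >= 2,
                              logical(1))]
  }
  assert_that(length(factors) >= 1, "no usable design factors")
  df <- design[factors]
  for (f in factors) {
    lev <- if (!is.null(contrast_factor) && f == contrast_factor) {
      contrast_levels
    } else if (f %in% names(DESIGN_LEVELS)) {
      intersect(DESIGN_LEVELS[[f]], unique(df[[f]]))
    } else {
      sort(unique(df[[f]]))
    }
    df[[f]] <- factor(df[[f]], levels = lev)
  }
  X <- model.matrix(~ ., data = as.data.frame(df))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    rlang::abort(paste0("confounded design: aliased column(s) ",
                        paste(aliased, collapse = ", ")))
  }
  list(X = X, counts = counts, design = design, factors = factors)
}

#' Wald-test contrast with shrunken log2 fold changes
#'
#' Fits per gene an additive NB GLM in the design factors (dispersion fixed
#' at the MAP value from [fit_dispersion()]); the contrast's log2 fold
#' change is shrunk by a zero-centred normal prior whose variance is fitted
#' from the spread of maximum-likelihood fold changes (method of moments,
#' floored at 0.25); the Wald statistic is the shrunken estimate divided by
#' its standard error, compared to a standard normal; p-values are
#' Benjamini-Hochberg adjusted. A gene is flagged significant when
#' p_adj < 0.05 and |M_shrunk| > 1.
#'
#' @param counts gene-by-sample count matrix.
#' @param design a [sample_design()].
#' @param factor design factor to contrast.
#' @param levels `c(level1, level2)`; the fold change is level2 vs level1.
#'   Defaults to the factor's standard state order.
#' @param shrink_lfc shrink the fold change (default TRUE).
#' @param subset optional named list of factor = level filters applied to
#'   samples before fitting (e.g. `list(source = "wild")`).
#' @param drop_covariates drop the other design factors from the model
#'   within a subset (default keeps all non-aliased covariates).
#' @param dispersion optional pre-computed `dispersion_fit` for these
#'   counts/design.
#' @return tibble of class `de_results`: gene_id, base_mean, A, M_raw,
#'   M_shrunk, SE, wald_z, p, p_adj, signed_fold, significant. Attributes:
#'   `contrast`, `prior_var_lfc`, `sf`, `n_samples`.
#' @export
wald_contrast <- function(counts, design, factor, levels = NULL,
                          shrink_lfc = TRUE, subset = NULL,
                          drop_covariates = FALSE, dispersion = NULL) {
  counts <- as_count_matrix(counts)
  design <- as_tibble(design)
  levels <- levels %||% DESIGN_LEVELS[[factor]]
  assert_that(!is.null(levels) && length(levels) == 2,
              "levels must give c(level1, level2)")
  if (!is.null(subset)) {
    keep <- rep(TRUE, nrow(design))
    for (f in names(subset)) keep <- keep & design[[f]] %in% subset[[f]]
    design <- design[keep, ]
    counts <- counts[, design$sample, drop = FALSE]
  }
  assert_that(all(levels %in% design[[factor]]),
              paste0("both contrast levels must be present in '", factor, "'"))
  factors <- if (drop_covariates) factor else NULL
  dm <- build_design_matrix(counts, design, factors = factors,
                            contrast_factor = factor,
                            contrast_levels = levels)
  X <- dm$X
  design <- dm$design
  coef_name <- paste0(factor, levels[2])
  assert_that(coef_name %in% colnames(X), "contrast coefficient not in model")
  ci <- match(coef_name, colnames(X))
  if (is.null(dispersion)) {
    dispersion <- fit_dispersion(counts, design, factors = dm$factors)
  }
  sf <- attr(dispersion, "sf")
  offset <- log(sf)
  norm <- sweep(counts, 2, sf, "/")
  in2 <- design[[factor]] == levels[2]
  cd1 <- rowMeans(norm[, !in2, drop = FALSE])
  cd2 <- rowMeans(norm[, in2, drop = FALSE])
  ma <- ma_values(cd1, cd2)
  G <- nrow(counts)
  M_raw <- SE_raw <- rep(NA_real_, G)
  testable <- rowSums(counts) > 0 &
    !(rowSums(counts[, in2, drop = FALSE]) == 0 |
        rowSums(counts[, !in2, drop = FALSE]) == 0)
  disp <- dispersion$map[match(rownames(counts), dispersion$gene_id)]
  disp[is.na(disp)] <- 0.1
  for (g in which(testable)) {
    fit <- nb_irls(counts[g, ], X, offset, disp[g])
    M_raw[g] <- fit$beta[ci] / log(2)
    SE_raw[g] <- fit$se[ci] / log(2)
  }
  if (shrink_lfc) {
    okg <- testable & is.finite(M_raw) & is.finite(SE_raw)
    prior_var <- if (sum(okg) >= 2) {
      max(var(M_raw[okg]) - mean(SE_raw[okg]^2), 0.25, na.rm = TRUE)
    } else 0.25
    ridge <- rep(0, ncol(X))
    ridge[ci] <- 1 / (prior_var * log(2)^2)
    M_shrunk <- SE <- rep(NA_real_, G)
    for (g in which(testable)) {
      fit <- nb_irls(counts[g, ], X, offset, disp[g], ridge = ridge)
      M_shrunk[g] <- fit$beta[ci] / log(2)
      SE[g] <- fit$se[ci] / log(2)
    }
  } else {
    prior_var <- Inf
    M_shrunk <- M_raw
    SE <- SE_raw
  }
  z <- M_shrunk / SE
  p <- 2 * pnorm(-abs(z))
  out <- tibble(
    gene_id = rownames(counts),
    base_mean = rowMeans(norm),
    A = ma$A, M_raw = M_raw, M_shrunk = M_shrunk, SE = SE,
    wald_z = z, p = p, p_adj = bh_adjust(p),
    signed_fold = signed_fold(M_shrunk))
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05 &
    abs(out$M_shrunk) > 1
  class(out) <- c("de_results", class(out))
  attr(out, "contrast") <- c(factor = factor, level1 = levels[1],
                             level2 = levels[2])
  attr(out, "prior_var_lfc") <- prior_var
  attr(out, "sf") <- sf
  attr(out, "n_samples") <- ncol(counts)
  out
}

#' Signed fold change from a log2 fold change
#'
#' `2^M` for M >= 0 and `-2^(-M)` for M < 0, the reporting convention for
#' fold-change tables (e.g. M = -1.208 prints as -2.31).
#'
#' @param M log2 fold changes.
#' @return signed folds.
#' @export
signed_fold <- function(M) ifelse(M >= 0, 2^M, -(2^(-M)))

#' PCA of normalised, log-transformed counts
#'
#' Transforms counts as log2(K/s + 1) (a regularising log transform of the
#' normalised abundances), keeps the `n_top` most variable genes, centres
#' genes and computes sample scores by SVD. Rotation signs are fixed by
#' making each component's largest-magnitude loading positive so results do
#' not depend on sample order.
#'
#' @param counts gene-by-sample count matrix.
#' @param n_top number of most-variable genes to keep (default 500).
#' @param sf optional pre-computed size factors.
#' @return list of class `expr_pca`: `scores` (tibble sample, PC1..),
#'   `var_explained` (per-PC fraction), `degenerate` flag.
#' @export
pca_transform <- function(counts, n_top = 500, sf = NULL) {
  counts <- as_count_matrix(counts)
  assert_that(ncol(counts) >= 3, "PCA needs at least 3 samples")
  sf <- sf %||% size_factors(counts)
  y <- log2(sweep(counts, 2, sf, "/") + 1)
  rv <- apply(y, 1, var)
  keep <- head(order(rv, decreasing = TRUE), min(n_top, nrow(y)))
  y <- y[keep, , drop = FALSE]
  yc <- y - rowMeans(y)
  total_var <- sum(apply(yc, 1, var))
  if (total_var == 0) {
    rlang::warn("all samples identical: PCA degenerate")
    k <- min(ncol(y) - 1, nrow(y))
    scores <- matrix(0, ncol(y), k,
                     dimnames = list(colnames(y), paste0("PC", seq_len(k))))
    return(structure(list(
      scores = bind_cols(tibble(sample = colnames(y)), as_tibble(scores)),
      var_explained = setNames(rep(NA_real_, k), colnames(scores)),
      degenerate = TRUE), class = "expr_pca"))
  }
  pc <- prcomp(t(yc), center = FALSE)
  # canonical sign: largest-magnitude loading positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = bind_cols(tibble(sample = colnames(y)),
                       as_tibble(pc$x)),
    var_explained = setNames(ve, colnames(pc$x)),
    degenerate = FALSE), class = "expr_pca")
}
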