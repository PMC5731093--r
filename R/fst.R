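# FST-decomposition outlier scan.
#
# Locus-population differentiation is decomposed on the logistic scale into
# a locus effect alpha_i (shared by populations; non-zero only under the
# selection model, indicator delta_i) and a population effect beta_j (shared
# by loci): FST_ij = 1 / (1 + exp(-(alpha_i * delta_i + beta_j))). Observed
# allele counts follow a beta-binomial (2-allele Dirichlet-multinomial)
# around the ancestral frequency p_i with concentration (1 - FST) / FST.
# Posterior inclusion probabilities for delta_i come from a reversible-jump
# MCMC; outliers are called on Bayesian q-values.

FST_EPS <- 1e-12

#' MCMC settings for the outlier scan
#'
#' Defaults are the full-scale settings (5000 output iterations, thinning
#' 10, 20 pilot runs of length 5000, burn-in 5000, prior odds 500 for the
#' neutral model); [mcmc_settings_reduced()] gives desk-scale settings for
#' simulations and examples.
#'
#' @param n_output_iterations retained posterior samples.
#' @param thinning sweeps between retained samples.
#' @param n_pilot_runs,pilot_length proposal-adaptation runs before burn-in.
#' @param burn_in discarded sweeps after adaptation.
#' @param prior_odds_neutral prior odds of the neutral over the selection
#'   model per locus; prior inclusion probability is 1/(1 + odds).
#' @param seed integer seed fixing the chain.
#' @return an `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_output_iterations = 5000, thinning = 10,
                          n_pilot_runs = 20, pilot_length = 5000,
                          burn_in = 5000, prior_odds_neutral = 500,
                          seed = 1L) {
  vals <- c(n_output_iterations, thinning, n_pilot_runs, pilot_length,
            burn_in, prior_odds_neutral)
  assert_that(all(vals > 0), "all MCMC settings must be positive")
  structure(list(n_output_iterations = n_output_iterations,
                 thinning = thinning, n_pilot_runs = n_pilot_runs,
                 pilot_length = pilot_length, burn_in = burn_in,
                 prior_odds_neutral = prior_odds_neutral,
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @param ... overrides passed to [mcmc_settings()].
#' @export
mcmc_settings_reduced <- function(..., seed = 1L) {
  defaults <- list(n_output_iterations = 1000, thinning = 10,
                   n_pilot_runs = 5, pilot_length = 1000, burn_in = 1000,
                   prior_odds_neutral = 500, seed = seed)
  do.call(mcmc_settings, utils::modifyList(defaults, list(...)))
}

# Beta-binomial log-likelihood kernel without the count-combinatorial
# constant (which cancels in every MH ratio). a, n: loci x pops alt
# counts/totals; p: length-L ancestral frequencies; fst: same shape as a,
# in (0,1). Cells with n == 0 contribute 0.
bb_kernel <- function(a, n, p, fst) {
  fst <- pmin(pmax(fst, FST_EPS), 1 - FST_EPS)
  th <- (1 - fst) / fst
  tp <- th * p
  tq <- th * (1 - p)
  ll <- lbeta(a + tp, n - a + tq) - lbeta(tp, tq)
  ll[n == 0] <- 0
  ll
}

# Full beta-binomial log-likelihood matrix (proper log pmf).
bb_loglik_mat <- function(a, n, p, fst) {
  ll <- lchoose(n, a) + bb_kernel(a, n, p, fst)
  ll[n == 0] <- 0
  ll
}

#' Dirichlet-multinomial (beta-binomial) log-likelihood at one locus
#'
#' Log-likelihood of per-population biallelic allele counts given the
#' ancestral frequency and per-population FST, with concentration
#' (1 - FST)/FST; populations with zero total count contribute 0. In the
#' FST -> 0 limit this approaches the binomial log-likelihood.
#'
#' @param counts matrix with one row per population and two columns
#'   (allele-1 count, allele-2 count).
#' @param p ancestral frequency of allele 1, in (0,1).
#' @param fst per-population FST values in (0,1), recycled.
#' @return scalar log-likelihood.
#' @export
dm_loglik <- function(counts, p, fst) {
  counts <- matrix(as.numeric(counts), ncol = 2)
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(p > 0 && p < 1, "p must be in (0,1)")
  assert_that(all(fst > 0 & fst < 1), "fst must be in (0,1)")
  fst <- rep_len(fst, nrow(counts))
  a <- matrix(counts[, 1], nrow = 1)
  n <- matrix(counts[, 1] + counts[, 2], nrow = 1)
  sum(bb_loglik_mat(a, n, p, matrix(fst, nrow = 1)))
}

# priors (documented defaults of the reference Bayesian FST scan)
ALPHA_PRIOR_SD <- 3
BETA_PRIOR_MEAN <- -1
BETA_PRIOR_SD <- 1.8

#' Reversible-jump MCMC scan for FST outlier loci
#'
#' Fits the logistic alpha + beta FST decomposition to per-group allele
#' counts by Metropolis-Hastings within Gibbs: random-walk updates for the
#' ancestral frequencies (logit scale), locus effects alpha (when included)
#' and population effects beta, plus a reversible-jump move toggling each
#' locus's selection indicator with the configured prior odds (the jump
#' proposal draws alpha from its prior, so the move ratio reduces to the
#' likelihood ratio times the prior inclusion odds). Pilot runs adapt all
#' proposal scales towards acceptance rates in 0.25-0.45.
#'
#' @param freqs a `group_freqs` tibble (from [group_allele_freqs()]) with
#'   >= 2 groups; every locus must have positive total count in >= 2
#'   groups (others are excluded with a message).
#' @param settings an [mcmc_settings()] object.
#' @return tibble of class `fst_scan`, one row per locus: contig, pos,
#'   post_prob (posterior inclusion probability), alpha_mean (posterior
#'   mean of alpha x delta), qvalue, selection ("diversifying",
#'   "balancing" or "none"), fst_mean (posterior mean locus FST averaged
#'   over populations). Attributes: `beta_mean`, `fst_baseline`
#'   (logistic of mean beta per population), `acceptance`, `ess_beta`,
#'   `settings`, `n_excluded`.
#' @export
rjmcmc_scan <- function(freqs, settings = mcmc_settings_reduced()) {
  assert_that(inherits(settings, "mcmc_settings"),
              "settings must be mcmc_settings()")
  groups <- sort(unique(freqs$group))
  J <- length(groups)
  assert_that(J >= 2, "need >= 2 populations")
  keys <- sort(unique(locus_key(freqs$contig, freqs$pos)))
  L0 <- length(keys)
  a <- n <- matrix(0, L0, J, dimnames = list(keys, groups))
  idx <- cbind(match(locus_key(freqs$contig, freqs$pos), keys),
               match(freqs$group, groups))
  a[idx] <- freqs$alt_count
  n[idx] <- freqs$total_alleles
  ok <- rowSums(n > 0) >= 2
  if (any(!ok)) {
    rlang::inform(paste0("excluding ", sum(!ok),
                         " locus/loci with data in < 2 populations"))
  }
  a <- a[ok, , drop = FALSE]
  n <- n[ok, , drop = FALSE]
  keys <- keys[ok]
  L <- nrow(a)
  assert_that(L >= 1, "no usable loci")

  set.seed(settings$seed)
  prior_odds <- settings$prior_odds_neutral

  # state
  p <- pmin(pmax(rowSums(a) / pmax(rowSums(n), 1), 0.02), 0.98)
  alpha <- numeric(L)
  delta <- integer(L)
  beta <- rep(BETA_PRIOR_MEAN, J)

  # proposal scales, adapted in pilots
  sd_p <- rep(0.4, L)
  sd_alpha <- rep(0.8, L)
  sd_beta <- rep(0.15, J)

  ones_J <- rep(1, J)
  beta_mat <- matrix(beta, L, J, byrow = TRUE)
  Fmat <- plogis(outer(alpha * delta, ones_J) + beta_mat)
  ll_mat <- bb_kernel(a, n, p, Fmat)
  ll_rows <- rowSums(ll_mat)

  acc <- list(p = 0, alpha = 0, beta = 0, rj = 0)
  try_ <- list(p = 0, alpha = 0, beta = 0, rj = 0)

  sweep_once <- function() {
    # 1. ancestral frequencies (logit random walk, uniform prior => Jacobian)
    p_new <- plogis(qlogis(p) + rnorm(L, 0, sd_p))
    p_new <- pmin(pmax(p_new, 1e-9), 1 - 1e-9)
    ll_new_mat <- bb_kernel(a, n, p_new, Fmat)
    ll_new <- rowSums(ll_new_mat)
    log_r <- ll_new - ll_rows +
      log(p_new * (1 - p_new)) - log(p * (1 - p))
    take <- log(runif(L)) < log_r
    if (any(take)) {
      p[take] <<- p_new[take]
      ll_mat[take, ] <<- ll_new_mat[take, ]
      ll_rows[take] <<- ll_new[take]
    }
    acc$p <<- acc$p + sum(take); try_$p <<- try_$p + L

    # 2. alpha for included loci (random walk, normal prior)
    inc <- which(delta == 1L)
    if (length(inc) > 0) {
      alpha_new <- alpha[inc] + rnorm(length(inc), 0, sd_alpha[inc])
      f_new <- plogis(outer(alpha_new, ones_J) + beta_mat[inc, , drop = FALSE])
      ll_new_mat <- bb_kernel(a[inc, , drop = FALSE], n[inc, , drop = FALSE],
                              p[inc], f_new)
      ll_new <- rowSums(ll_new_mat)
      log_r <- ll_new - ll_rows[inc] +
        (alpha[inc]^2 - alpha_new^2) / (2 * ALPHA_PRIOR_SD^2)
      take <- log(runif(length(inc))) < log_r
      if (any(take)) {
        ti <- inc[take]
        alpha[ti] <<- alpha_new[take]
        Fmat[ti, ] <<- f_new[take, ]
        ll_mat[ti, ] <<- ll_new_mat[take, ]
        ll_rows[ti] <<- ll_new[take]
      }
      acc$alpha <<- acc$alpha + sum(take); try_$alpha <<- try_$alpha + length(inc)
    }

    # 3. reversible-jump toggle of delta (alpha proposed from its prior, so
    # the move ratio is the likelihood ratio times the prior inclusion odds)
    alpha_star <- ifelse(delta == 1L, alpha, rnorm(L, 0, ALPHA_PRIOR_SD))
    delta_new <- 1L - delta
    f_new <- plogis(outer(alpha_star * delta_new, ones_J) + beta_mat)
    ll_new_mat <- bb_kernel(a, n, p, f_new)
    ll_new <- rowSums(ll_new_mat)
    log_r <- ll_new - ll_rows +
      ifelse(delta == 0L, -log(prior_odds), log(prior_odds))
    take <- log(runif(L)) < log_r
    if (any(take)) {
      delta[take] <<- delta_new[take]
      alpha[take] <<- alpha_star[take]
      Fmat[take, ] <<- f_new[take, ]
      ll_mat[take, ] <<- ll_new_mat[take, ]
      ll_rows[take] <<- ll_new[take]
    }
    acc$rj <<- acc$rj + sum(take); try_$rj <<- try_$rj + L

    # 4. population effects beta (random walk, normal prior)
    for (j in seq_len(J)) {
      b_new <- beta[j] + rnorm(1, 0, sd_beta[j])
      f_col <- plogis(alpha * delta + b_new)
      ll_col <- bb_kernel(a[, j], n[, j], p, f_col)
      log_r <- sum(ll_col) - sum(ll_mat[, j]) +
        ((beta[j] - BETA_PRIOR_MEAN)^2 -
           (b_new - BETA_PRIOR_MEAN)^2) / (2 * BETA_PRIOR_SD^2)
      if (log(runif(1)) < log_r) {
        ll_rows <<- ll_rows - ll_mat[, j] + ll_col
        ll_mat[, j] <<- ll_col
        Fmat[, j] <<- f_col
        beta_mat[, j] <<- b_new
        beta[j] <<- b_new
        acc$beta <<- acc$beta + 1
      }
      try_$beta <<- try_$beta + 1
    }
  }

  # pilot runs: adapt proposal scales towards acceptance in [0.25, 0.45]
  for (pilot in seq_len(settings$n_pilot_runs)) {
    acc <- list(p = 0, alpha = 0, beta = 0, rj = 0)
    try_ <- list(p = 0, alpha = 0, beta = 0, rj = 0)
    for (s in seq_len(settings$pilot_length)) sweep_once()
    rate_p <- acc$p / max(try_$p, 1)
    rate_a <- acc$alpha / max(try_$alpha, 1)
    rate_b <- acc$beta / max(try_$beta, 1)
    adj <- function(sd, rate) {
      if (rate < 0.25) pmax(sd * 0.7, 1e-3)
      else if (rate > 0.45) pmin(sd * 1.4, 10)
      else sd
    }
    sd_p <- adj(sd_p, rate_p)
    if (try_$alpha > 0) sd_alpha <- adj(sd_alpha, rate_a)
    sd_beta <- adj(sd_beta, rate_b)
  }
  final_rates <- c(p = acc$p / max(try_$p, 1),
                   alpha = if (try_$alpha > 0) acc$alpha / try_$alpha else NA,
                   beta = acc$beta / max(try_$beta, 1),
                   rj = acc$rj / max(try_$rj, 1))
  off <- which(!is.na(final_rates[c("p", "beta")]) &
                 (final_rates[c("p", "beta")] < 0.15 |
                    final_rates[c("p", "beta")] > 0.6))
  if (length(off) > 0) {
    rlang::warn(paste0("pilot adaptation did not converge; acceptance rates: ",
                       paste(names(final_rates), round(final_rates, 3),
                             sep = "=", collapse = ", ")))
  }

  for (s in seq_len(settings$burn_in)) sweep_once()

  n_out <- settings$n_output_iterations
  sum_delta <- numeric(L)
  sum_alpha <- numeric(L)
  sum_fst <- numeric(L)
  sum_beta <- numeric(J)
  beta_chain <- matrix(NA_real_, n_out, J)
  acc <- list(p = 0, alpha = 0, beta = 0, rj = 0)
  try_ <- list(p = 0, alpha = 0, beta = 0, rj = 0)
  for (it in seq_len(n_out)) {
    for (s in seq_len(settings$thinning)) sweep_once()
    sum_delta <- sum_delta + delta
    sum_alpha <- sum_alpha + alpha * delta
    sum_fst <- sum_fst + rowMeans(Fmat)
    sum_beta <- sum_beta + beta
    beta_chain[it, ] <- beta
  }
  post_prob <- sum_delta / n_out
  alpha_mean <- sum_alpha / n_out
  final_rates <- c(p = acc$p / max(try_$p, 1),
                   alpha = if (try_$alpha > 0) acc$alpha / try_$alpha else NA,
                   beta = acc$beta / max(try_$beta, 1),
                   rj = acc$rj / max(try_$rj, 1))

  out <- tibble(
    contig = sub(":[^:]*$", "", keys),
    pos = as.integer(sub("^.*:", "", keys)),
    post_prob = post_prob, alpha_mean = alpha_mean,
    qvalue = bayes_qvalue(post_prob),
    fst_mean = sum_fst / n_out)
  out$selection <- ifelse(out$post_prob == 0, "none",
                          ifelse(out$alpha_mean > 0, "diversifying",
                                 ifelse(out$alpha_mean < 0, "balancing",
                                        "none")))
  out <- arrange(out, .data$qvalue, desc(.data$post_prob), .data$contig,
                 .data$pos)
  class(out) <- c("fst_scan", class(out))
  attr(out, "beta_mean") <- setNames(sum_beta / n_out, groups)
  attr(out, "fst_baseline") <- setNames(plogis(sum_beta / n_out), groups)
  attr(out, "acceptance") <- final_rates
  attr(out, "ess_beta") <- apply(beta_chain, 2, ess_acf)
  attr(out, "settings") <- settings
  attr(out, "n_excluded") <- sum(!ok)
  out
}

# Bayesian q-value: for each locus, the mean posterior error probability
# (1 - post_prob) over all loci with posterior probability >= its own.
# Tied loci share the q of the last rank of their tie group.
bayes_qvalue <- function(post_prob) {
  ord <- order(post_prob, decreasing = TRUE)
  pp <- post_prob[ord]
  cm <- cumsum(1 - pp) / seq_along(pp)
  runs <- rle(pp)$lengths
  last_idx <- rep(cumsum(runs), runs)
  q <- numeric(length(pp))
  q[ord] <- pmin(cm[last_idx], 1)
  q
}

# crude effective sample size from the autocorrelation function
ess_acf <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  k <- if (length(pos) > 0) pos[1] - 1 else length(rho)
  n / (1 + 2 * sum(rho[seq_len(k)]))
}

#' Annotate outlier SNPs with overlapping gene features
#'
#' Labels each SNP with the feature type(s) of overlapping CDS / 5' UTR /
#' 3' UTR records, or "intergenic"; multiple overlapping types are joined
#' in the fixed order CDS, five_prime_UTR, three_prime_UTR.
#'
#' @param result an `fst_scan` tibble (or any tibble with contig, pos).
#' @param features gene-feature tibble from [read_gff()].
#' @return `result` with an added `feature` column.
#' @export
annotate_outliers <- function(result, features) {
  feat <- features[features$feature_type %in%
                     c("CDS", "five_prime_UTR", "three_prime_UTR"), ]
  type_order <- c("CDS", "five_prime_UTR", "three_prime_UTR")
  lab <- vapply(seq_len(nrow(result)), function(i) {
    hit <- feat$contig == result$contig[i] &
      feat$start <= result$pos[i] & feat$end >= result$pos[i]
    if (!any(hit)) return("intergenic")
    types <- unique(feat$feature_type[hit])
    paste(type_order[type_order %in% types], collapse = ",")
  }, "")
  mutate(result, feature = lab)
}
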