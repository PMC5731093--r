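---
title: "Models and methods in traitpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in traitpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

traitpop implements an analysis chain for experiments that profile a tissue
by RNA-seq in fish from two populations (a wild and a domesticated Atlantic
salmon strain is the motivating design), exercise-train them, and grade their
swimming performance. The same sequencing reads serve two purposes: the
aligned coverage yields a gene-by-sample count matrix for differential
expression, and the per-site allele depths yield SNP genotypes for
population-genetic analysis. This vignette explains each model, its
assumptions and tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Genotype calling from allele read depths

RNA-seq genotypes are called from per-site reference/alternative read depths
with deterministic rules rather than genotype likelihoods:

* a cell with total depth below `min_depth` (default 10 reads) is `missing`;
* if both alleles are observed and the minor-allele read fraction is at
  least `min_het_fraction` (default 0.20) the call is `het`; below that the
  putative heterozygote is *discarded* (set `missing`), not coerced to a
  homozygote — at RNA-seq error rates a low minor fraction is ambiguous
  between sequencing error and allele-specific expression, so discarding is
  the conservative reading. The boundary is kept: a minor fraction of
  exactly 0.20 is a heterozygote;
* otherwise the call is the homozygote of the observed allele.

Loci are then screened across the cohort: at least `min_individuals`
(default 45) fully genotyped individuals (i.e. at least 90 called alleles),
not every called individual heterozygous (a signature of paralogous
misalignment), and at least `min_alt_occurrences` (default 3, "more than
two") occurrences of the alternative allele, counted as alleles
(het = 1, homalt = 2). Whether "occurrences" means alleles or carrier
individuals is ambiguous; allele counting is the default and
`count_carriers = TRUE` switches to carriers. The filter report attributes
each removed locus to the first failing rule in the order above; retention
itself is the order-free conjunction of the three rules.

## Relatedness: dissimilarity and neighbour joining

Pairwise relatedness uses a simple-matching allele-sharing dissimilarity on
codominant diploid calls: per locus scored in both individuals, identical
genotypes contribute 0, a heterozygote against either homozygote 0.5, and
opposite homozygotes 1; the pair's value is the mean over comparable loci
(pairwise-complete denominators). This is the standard default index for
codominant data in distance-based relatedness software; the index actually
used by the original study's toolchain is not stated, so the default was
chosen and documented here. Loci are pre-screened to those genotyped in
more than 60% of individuals, after an optional seeded random subsample
(`subsample_loci()`), mirroring a typical locus-thinning step.

Trees come from Saitou–Nei neighbour joining (via ape), which is exact on
additive distance matrices. Labels are ordered deterministically before
agglomeration so output is invariant to input order, and negative branch
lengths — a known NJ artefact on noisy distances — are clamped to zero with
a warning.

Allele-frequency heterogeneity between two groups is a Pearson chi-square
on the 2x2 allele-count table (df = 1). The default is uncorrected;
Yates' continuity correction is available by flag. Groups with no called
individuals at a locus get an undefined (not zero) frequency.

## FST-decomposition outlier scan

Locus-by-population differentiation is modelled on the logistic scale as

    FST_ij = logistic(alpha_i * delta_i + beta_j)

with `beta_j` a population effect shared by loci, `alpha_i` a locus effect
shared by populations, and `delta_i` a model indicator: a locus departs from
neutrality only when its alpha is included. Positive alpha means
diversifying selection, negative balancing selection. Observed allele
counts in each population follow a beta-binomial (two-allele
Dirichlet-multinomial) around an ancestral frequency `p_i` with
concentration `(1 - FST_ij)/FST_ij`.

The posterior is explored by Metropolis–Hastings within Gibbs: logit-scale
random walks for `p_i` (uniform prior, with the Jacobian term), random
walks for included `alpha_i` and for `beta_j`, and a reversible-jump move
toggling each `delta_i`. The jump proposes alpha from its prior, so the
acceptance ratio reduces to the likelihood ratio times the prior inclusion
odds (1 : `prior_odds_neutral`, default 500). Priors are
alpha ~ N(0, 3^2), beta ~ N(-1, 1.8^2), p ~ Uniform(0,1) — the published
defaults of the reference Bayesian FST scan, since the study reports the
run settings but not priors. Pilot runs adapt every proposal scale towards
acceptance rates of 0.25–0.45 (scale multiplied by 0.7 or 1.4 per pilot);
final acceptance rates and a crude autocorrelation-based effective sample
size for beta are attached to the result, and no automatic re-run is
attempted on poor adaptation, only a warning.

Outliers are ranked by the Bayesian q-value: the mean posterior error
probability (1 − inclusion probability) over all loci at or above a locus's
posterior. Ties share the q of their group's last rank; q is monotone in
the posterior by construction. Default run-length settings follow the
reported full-scale analysis (5000 output iterations, thinning 10, 20
pilot runs of 5000, burn-in 5000); `mcmc_settings_reduced()` (1000 output
iterations, 5 pilot runs of 1000, burn-in 1000) is the desk-scale default
used by the demo and simulations, chosen so a ~300-locus scan completes in
well under a minute while posterior means of beta remain stable to ±0.03
on the FST scale across seeds.

A note on attainable power: with only two populations, one locus
contributes a single frequency contrast, so even a moderately strong locus
effect yields bounded evidence. Integrating the likelihood over the alpha
prior shows that a locus must display near-fixed frequency differences
before its Bayes factor clears prior odds of 500; diversifying effects
around alpha = +2 over a baseline FST of 0.05 (locus FST 0.28) almost never
do. The scan therefore flags only strongly divergent loci at stringent
q-values in two-population designs — the tests exercise detection at
effect sizes where the Bayes factors do clear the prior odds, and the
model's calibration (no outliers on neutral data, baseline FST recovered
through beta) rather than unattainable recall.

## Differential expression

The expression model is the described shrinkage estimator chain for
negative-binomial counts, implemented directly rather than by calling an
existing package (whose independent filtering, outlier replacement and
exact rlog are deliberately out of scope):

1. **Normalisation.** Median-of-ratios size factors: per sample, the median
   over all-nonzero genes of the ratio to the gene's geometric mean,
   rescaled to geometric mean one.
2. **Dispersion.** Per-gene Cox–Reid adjusted maximum-likelihood dispersion
   given the fitted design means; a trend `a0 + a1/mean` fitted by
   iteratively reweighted gamma regression with outlier exclusion
   (gene-wise/trend ratios outside [1e-4, 15] are dropped and the fit
   repeated); and empirical-Bayes shrinkage of each gene-wise estimate to
   the maximum of CR likelihood plus a log-normal prior centred on the
   trend. The prior variance is the residual spread of log gene-wise
   estimates (MAD-based) minus the expected sampling variance
   `trigamma((m - p)/2)`, floored at 0.25. The MAP value is clamped to lie
   between the gene-wise and trend values on the log scale, which the
   posterior mode satisfies anyway except for numerical edge cases.
3. **Fold changes and tests.** Per gene, an additive NB GLM (log link) in
   the design factors — sex, source, exercise regime, swimming performance
   — is fitted by IRLS with the dispersion fixed at its MAP value
   (tolerance 1e-8, at most 100 iterations). The contrast's log2 fold
   change M is shrunk by a zero-centred normal prior whose variance is the
   method-of-moments excess of the MLE spread over its average squared
   standard error, floored at 0.25 (log2 scale); computationally the prior
   is a ridge term on that coefficient inside IRLS. The Wald statistic is
   the shrunken M over its standard error, where the standard error is the
   sampling standard deviation of the shrunken estimator (the sandwich form
   `(I+L)^-1 I (I+L)^-1`), which keeps the null distribution standard
   normal; p-values are two-sided and Benjamini–Hochberg adjusted.
   A gene is flagged when `p_adj < 0.05` and `|M| > 1`.
4. **Reporting.** `A = (log2 cd2 + log2 cd1)/2` and raw M follow the MA
   definitions on mean normalised coverage depths, with pseudocount 0.5 for
   zero depths; genes with zero counts throughout one contrast level are
   excluded from testing. Signed folds are `2^M` (M >= 0) or `-2^(-M)`,
   the convention that prints M = -1.208 as -2.31.

Within subset analyses (e.g. only wild, control fish) all remaining
non-constant covariates stay in the model by default (`drop_covariates`
removes them); a factor aliased with the subset raises an error naming the
aliased columns rather than silently dropping information.

The PCA uses `log2(count/size_factor + 1)` — a regularising log transform
chosen in place of the full generalised-least-squares rlog, a documented
deviation — on the 500 most variable genes, gene-centred, with component
signs fixed by making each component's largest-magnitude loading positive
so scores are invariant to sample order.

## Enrichment and integration

Category enrichment compares, per category, differentially expressed
against non-differentially-expressed genes (in-category vs not) with a
Yates-corrected chi-square. The reported p is one-tailed for enrichment:
half the two-sided p when the DE proportion exceeds the background
proportion, else one minus that half — a documented convention, since the
chi-square statistic is one-sided but not directional. The background is
the set of genes expressed (testable) in all states of the contrast. Rows
with any expected cell below 1 are flagged, not dropped. Category
summaries report down/up counts and the arithmetic mean of signed folds
("average fold" is not defined in the source material; a geometric option
exists).

SNP-to-gene integration assigns a gene to a SNP when the distance from the
SNP to the gene's range is strictly less than 100,000 bases (inside a gene
is distance 0); the boundary is strict. Loci whose alternative-allele
frequencies differ by strictly more than 0.50 between populations are
intersected with differential-expression tables through those gene
assignments. Outlier SNPs are separately labelled with overlapping
CDS/5'UTR/3'UTR feature types ("intergenic" otherwise); `gene` records are
kept from GFF3 input solely to drive proximity, while `exon` and `mRNA`
records are dropped as uninformative for site labelling.

## Synthetic data: what it emulates, and what it does not

`simulate_genotypes()` draws ancestral frequencies from Beta(0.8, 0.8)
(a drift-like U-shaped spectrum; segregating but often extreme), then
population frequencies from the Balding–Nichols Beta with
`FST_ij = logistic(alpha_i + beta_j)` — the generative counterpart of the
outlier model, so the scan can be checked by parameter recovery — and
Hardy–Weinberg genotypes within population. Defaults: two populations of
60, 1000 loci, baseline FST 0.05. `simulate_allele_counts()` layers
negative-binomial sequencing depth (mean 30, dispersion 0.3) and a single
global error rate (0.005): alternative reads are Binomial(depth, e),
Binomial(depth, 1/2) or Binomial(depth, 1-e) by genotype, enough to
exercise the 20% heterozygote rule. `simulate_expression()` draws
log-normal baseline means (meanlog log 100, sdlog 1), gene dispersions on
the trend `a0 + a1/mean` (defaults 0.05, 5), additive log2 effects for
designated genes over the four-factor design, and NB counts scaled by
library size factors.

Not emulated: linkage disequilibrium between loci, site-specific error
rates, allele-specific expression, GC or length biases, batch effects, and
count outliers. Passing tests therefore demonstrate correctness of the
algorithms under their own model assumptions, not robustness to every
artefact of real RNA-seq data.

## Problem sizes and reproducibility

The demo pipeline (`run_demo()`) simulates 500 loci (8 under diversifying
selection) across two populations of 60 and a 1500-gene, 32-sample
expression matrix, runs every stage with reduced MCMC settings, and writes
all tables plus a manifest; it is byte-reproducible from its seed, with
per-stage seeds derived from the global one so stages can be re-run
independently. Simulation-based tests use 150–4000 genes and 60–400 loci —
sizes at which the statistical checks (calibration, parameter recovery,
power) are already tight while a full run stays interactive.

## Known limitations

* The outlier scan supports biallelic, codominant loci in two or more
  populations; dominant-marker mode (and its Fis prior and recessive-band
  threshold settings) is not implemented, as those settings do not apply to
  codominant SNP data.
* Differential expression omits independent filtering, Cook's-distance
  outlier handling and the exact rlog transform.
* The q-value is the Bayesian posterior-error version, not a permutation
  FDR; with few loci it is coarse.
* NJ trees carry no bootstrap support values.
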