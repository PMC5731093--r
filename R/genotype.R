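# Genotype calling and locus filtering from allele read depths.
#
# Calling rules, applied per (individual, site):
#   * total depth < min_depth            -> missing (insufficient coverage)
#   * both alleles seen, minor fraction >= min_het_fraction -> het
#   * both alleles seen, minor fraction <  min_het_fraction -> missing
#     (a putative heterozygote the rule discards, not a homozygote)
#   * otherwise homozygote for the observed allele
# The boundary is kept: a minor fraction of exactly min_het_fraction is het.

#' Call genotypes from reference/alternative read depths
#'
#' Vectorised over its first two arguments.
#'
#' @param ref_depth,alt_depth non-negative integer read depths.
#' @param min_depth minimum total coverage to call a genotype (default 10).
#' @param min_het_fraction minimum minor-allele read fraction for a
#'   heterozygote call (default 0.20); putative heterozygotes below it are
#'   discarded as missing.
#' @return character vector in `homref`, `het`, `homalt`, `missing`.
#' @export
call_genotype <- function(ref_depth, alt_depth, min_depth = 10,
                          min_het_fraction = 0.20) {
  assert_that(all(ref_depth >= 0) && all(alt_depth >= 0),
              "read depths must be non-negative")
  total <- ref_depth + alt_depth
  minor <- pmin(ref_depth, alt_depth)
  out <- rep("missing", length(total))
  callable <- total >= min_depth
  both <- callable & ref_depth > 0 & alt_depth > 0
  out[both & minor / total >= min_het_fraction] <- "het"
  out[callable & alt_depth == 0] <- "homref"
  out[callable & ref_depth == 0] <- "homalt"
  out
}

#' Genotype an allele-count table
#'
#' Applies [call_genotype()] to every (individual, site) cell.
#'
#' @param counts an [allele_counts()] tibble.
#' @inheritParams call_genotype
#' @return long tibble of class `genotype_calls`: contig, pos, ref, alt,
#'   sample, genotype.
#' @export
call_genotypes <- function(counts, min_depth = 10, min_het_fraction = 0.20) {
  counts <- allele_counts(counts)
  out <- tibble(
    contig = counts$contig, pos = counts$pos, ref = counts$ref,
    alt = counts$alt, sample = counts$sample,
    genotype = call_genotype(counts$ref_depth, counts$alt_depth,
                             min_depth, min_het_fraction))
  class(out) <- c("genotype_calls", class(out))
  out
}

#' Per-locus genotype summary
#'
#' @param calls a long genotype tibble (contig, pos, sample, genotype).
#' @return tibble per locus: `n_called` individuals, `n_alt` occurrences of
#'   the alternative allele (het + 2 homalt), `all_het` flag over called
#'   individuals.
#' @export
locus_summary <- function(calls) {
  calls %>%
    group_by(.data$contig, .data$pos) %>%
    summarise(
      n_called = sum(.data$genotype != "missing"),
      n_alt = sum((.data$genotype == "het") + 2L * (.data$genotype == "homalt")),
      all_het = .data$n_called > 0 && all(.data$genotype[.data$genotype != "missing"] == "het"),
      .groups = "drop")
}

#' Filter loci across the population of genotyped individuals
#'
#' A locus is retained iff (1) at least `min_individuals` individuals are
#' fully genotyped (i.e. at least `2 * min_individuals` alleles detected),
#' (2) not every called individual is heterozygous, and (3) the alternative
#' allele occurs at least `min_alt_occurrences` times (counting alleles:
#' het = 1, homalt = 2; set `count_carriers = TRUE` to count individuals
#' carrying the alternative allele instead). Rules are itemised in a filter
#' report attached as attribute `"filter_report"` (see [filter_report()]);
#' removal is attributed to the first failing rule in the order above.
#'
#' @param calls a `genotype_calls` tibble.
#' @param min_individuals minimum fully genotyped individuals (default 45).
#' @param min_alt_occurrences minimum alternative-allele occurrences
#'   (default 3, i.e. "more than two occurrences").
#' @param count_carriers count carrier individuals instead of alleles.
#' @return filtered `genotype_calls` tibble with a `filter_report` attribute.
#' @export
filter_loci <- function(calls, min_individuals = 45, min_alt_occurrences = 3,
                        count_carriers = FALSE) {
  if (nrow(calls) == 0) {
    attr(calls, "filter_report") <- empty_filter_report(min_individuals,
                                                        min_alt_occurrences)
    return(calls)
  }
  sm <- locus_summary(calls)
  if (count_carriers) {
    carriers <- calls %>%
      group_by(.data$contig, .data$pos) %>%
      summarise(n_alt = sum(.data$genotype %in% c("het", "homalt")),
                .groups = "drop")
    sm$n_alt <- carriers$n_alt[match(locus_key(sm$contig, sm$pos),
                                     locus_key(carriers$contig, carriers$pos))]
  }
  fail_cov <- sm$n_called < min_individuals
  fail_het <- !fail_cov & sm$all_het
  fail_alt <- !fail_cov & !fail_het & sm$n_alt < min_alt_occurrences
  keep <- !(fail_cov | fail_het | fail_alt)
  report <- tibble(
    rule = c("min_individuals", "all_heterozygous", "min_alt_occurrences"),
    threshold = c(min_individuals, NA_real_, min_alt_occurrences),
    n_removed = c(sum(fail_cov), sum(fail_het), sum(fail_alt)))
  attr(report, "n_input_loci") <- nrow(sm)
  attr(report, "n_retained_loci") <- sum(keep)
  kept_keys <- locus_key(sm$contig[keep], sm$pos[keep])
  out <- calls[locus_key(calls$contig, calls$pos) %in% kept_keys, ]
  class(out) <- unique(c("genotype_calls", class(out)))
  attr(out, "filter_report") <- report
  out
}

empty_filter_report <- function(min_individuals, min_alt_occurrences) {
  report <- tibble(
    rule = c("min_individuals", "all_heterozygous", "min_alt_occurrences"),
    threshold = c(min_individuals, NA_real_, min_alt_occurrences),
    n_removed = c(0L, 0L, 0L))
  attr(report, "n_input_loci") <- 0L
  attr(report, "n_retained_loci") <- 0L
  report
}

#' Extract the filter report attached by [filter_loci()]
#'
#' @param x a filtered `genotype_calls` tibble.
#' @return tibble of per-rule removal counts with attributes
#'   `n_input_loci`, `n_retained_loci`.
#' @export
filter_report <- function(x) {
  rep <- attr(x, "filter_report")
  assert_that(!is.null(rep), "object carries no filter report")
  rep
}

#' Full genotyping pipeline: call genotypes, then filter loci
#'
#' @param counts an [allele_counts()] tibble.
#' @inheritParams call_genotype
#' @inheritParams filter_loci
#' @return filtered `genotype_calls` tibble with a `filter_report` attribute.
#' @export
genotype_pipeline <- function(counts, min_depth = 10, min_het_fraction = 0.20,
                              min_individuals = 45, min_alt_occurrences = 3,
                              count_carriers = FALSE) {
  calls <- call_genotypes(counts, min_depth, min_het_fraction)
  filter_loci(calls, min_individuals, min_alt_occurrences, count_carriers)
}
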