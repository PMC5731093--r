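# Functional-category enrichment and SNP-by-expression integration.

#' Read a gene-to-category map from TSV
#'
#' Two columns: `gene_id`, `category`; a gene may carry many categories.
#'
#' @param path TSV path with header.
#' @return tibble gene_id, category.
#' @export
read_category_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  assert_that(all(c("gene_id", "category") %in% names(x)),
              "category map needs columns gene_id, category")
  assert_that(all(nzchar(x$category)), "category labels must be non-empty")
  distinct(as_tibble(x[c("gene_id", "category")]))
}

#' Category enrichment of a differentially expressed gene set
#'
#' Per category, a 2x2 table (differentially expressed vs not, in category
#' vs not) is tested with a Yates-corrected chi-square; the reported
#' p-value is one-tailed for enrichment: half the two-sided p when the
#' observed proportion of category genes among the DE set exceeds the
#' background proportion, else one minus that half. Rows where any expected
#' cell count is below 1 are flagged `low_expected` but still reported.
#'
#' @param de_genes character vector of differentially expressed gene ids
#'   (must be a subset of `background`).
#' @param background character vector of all tested genes (the full set of
#'   genes expressed in all states).
#' @param map tibble gene_id, category (see [read_category_map()]).
#' @return tibble of class `enrichment`: category, n_de_in_category,
#'   n_de_total, n_background_in_category, n_background_total, chi2,
#'   one_tailed_p, direction, low_expected; sorted by p.
#' @export
enrich <- function(de_genes, background, map) {
  de_genes <- unique(de_genes)
  background <- unique(background)
  assert_that(length(de_genes) > 0, "nothing to test: empty DE set")
  assert_that(all(de_genes %in% background),
              "de_genes must be a subset of background")
  map <- map[map$gene_id %in% background, ]
  cats <- sort(unique(map$category))
  assert_that(length(cats) > 0, "no category covers the background")
  n_de <- length(de_genes)
  n_bg <- length(background)
  rows <- lapply(cats, function(cc) {
    in_cat <- unique(map$gene_id[map$category == cc])
    a <- sum(de_genes %in% in_cat)              # DE, in category
    b <- n_de - a                               # DE, not in category
    c_ <- length(in_cat) - a                    # non-DE, in category
    d <- (n_bg - n_de) - c_                     # non-DE, not in category
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    direction <- if (a / n_de >= length(in_cat) / n_bg) "enriched" else "depleted"
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      chi2 <- 0
      p2 <- 1
    } else {
      ht <- suppressWarnings(chisq.test(tab, correct = TRUE))
      chi2 <- unname(ht$statistic)
      p2 <- unname(ht$p.value)
    }
    p1 <- if (direction == "enriched") p2 / 2 else 1 - p2 / 2
    tibble(category = cc, n_de_in_category = a, n_de_total = n_de,
           n_background_in_category = length(in_cat),
           n_background_total = n_bg, chi2 = chi2, one_tailed_p = p1,
           direction = direction, low_expected = any(expected < 1))
  })
  out <- arrange(bind_rows(rows), .data$one_tailed_p, .data$category)
  class(out) <- c("enrichment", class(out))
  out
}

#' Per-category summary of significant genes
#'
#' Among genes flagged significant in a contrast, counts down- and
#' up-regulated genes per category and the arithmetic mean of their signed
#' folds (geometric mean of |fold| with majority sign via
#' `mean_fold = "geometric"`). Categories with no significant gene are
#' omitted.
#'
#' @param results a `de_results` tibble from [wald_contrast()].
#' @param map tibble gene_id, category.
#' @param mean_fold "arithmetic" (default) or "geometric".
#' @return tibble: category, n_down, n_up, mean_fold.
#' @export
category_summary <- function(results, map, mean_fold = c("arithmetic",
                                                         "geometric")) {
  mean_fold <- match.arg(mean_fold)
  sig <- results[!is.na(results$significant) & results$significant, ]
  if (nrow(sig) == 0) {
    return(tibble(category = character(), n_down = integer(),
                  n_up = integer(), mean_fold = numeric()))
  }
  x <- inner_join(sig, as_tibble(map), by = "gene_id")
  x %>%
    group_by(.data$category) %>%
    summarise(
      n_down = sum(.data$M_shrunk < 0),
      n_up = sum(.data$M_shrunk > 0),
      mean_fold = if (mean_fold == "arithmetic") {
        mean(.data$signed_fold)
      } else {
        sign(sum(sign(.data$signed_fold))) *
          exp(mean(log(abs(.data$signed_fold))))
      },
      .groups = "drop") %>%
    arrange(.data$category)
}

#' Genes within a window of each SNP
#'
#' Assigns a gene to a SNP when the minimum distance from the SNP position
#' to the gene's range is strictly less than `window` bases on the same
#' contig (a SNP inside the gene has distance 0). Gene ranges come from
#' `gene`-type features when present, otherwise from the union of the
#' gene's sub-features.
#'
#' @param sites tibble with contig, pos (one row per SNP).
#' @param features gene-feature tibble from [read_gff()].
#' @param window distance bound in bases (default 100000, strict `<`).
#' @return tibble: contig, pos, gene_id, distance; qualifying genes sorted
#'   by distance then gene id within each SNP.
#' @export
snps_near_genes <- function(sites, features, window = 100000) {
  sites <- distinct(as_tibble(sites), .data$contig, .data$pos)
  genes <- gene_ranges(features)
  out <- inner_join(sites, genes, by = "contig",
                    relationship = "many-to-many")
  if (nrow(out) == 0) {
    return(tibble(contig = character(), pos = integer(),
                  gene_id = character(), distance = integer()))
  }
  out <- out %>%
    mutate(distance = pmax(.data$start - .data$pos,
                           .data$pos - .data$end, 0L)) %>%
    filter(.data$distance < window) %>%
    select("contig", "pos", "gene_id", "distance") %>%
    arrange(.data$contig, .data$pos, .data$distance, .data$gene_id)
  out
}

# one range per gene: the gene-type record when present, else the span of
# the gene's sub-features
gene_ranges <- function(features) {
  assert_that(nrow(features) > 0, "no gene features")
  features %>%
    group_by(.data$gene_id, .data$contig) %>%
    summarise(
      start = if (any(.data$feature_type == "gene")) {
        min(.data$start[.data$feature_type == "gene"])
      } else min(.data$start),
      end = if (any(.data$feature_type == "gene")) {
        max(.data$end[.data$feature_type == "gene"])
      } else max(.data$end),
      .groups = "drop")
}

#' Intersect high-frequency-difference loci with differential expression
#'
#' Selects loci whose alternative-allele frequencies differ by strictly
#' more than `threshold` between two populations, maps them to nearby genes
#' with [snps_near_genes()], and reports per DE table how many of those
#' genes are differentially expressed.
#'
#' @param freqs a `group_freqs` tibble with exactly the two populations to
#'   compare.
#' @param de_tables named list of `de_results` tibbles.
#' @param features gene-feature tibble.
#' @param threshold frequency-difference bound (default 0.50, strict `>`).
#' @param window proximity window passed to [snps_near_genes()].
#' @return list: `selected_loci` (contig, pos, freq difference),
#'   `genes` (gene ids near selected loci), `summary` (tibble per DE table:
#'   n_genes, n_de, fraction_de), `n_skipped_undefined`.
#' @export
freq_diff_intersections <- function(freqs, de_tables, features,
                                    threshold = 0.50, window = 100000) {
  groups <- sort(unique(freqs$group))
  assert_that(length(groups) == 2, "freqs must cover exactly 2 populations")
  wide <- tidyr::pivot_wider(as_tibble(freqs)[c("group", "contig", "pos", "freq")],
                             names_from = "group", values_from = "freq")
  undefined <- !complete.cases(wide)
  wide <- wide[!undefined, ]
  sel <- wide[abs(wide[[groups[1]]] - wide[[groups[2]]]) > threshold, ]
  selected <- tibble(contig = sel$contig, pos = sel$pos,
                     freq_diff = abs(sel[[groups[1]]] - sel[[groups[2]]]))
  near <- snps_near_genes(selected, features, window)
  genes <- sort(unique(near$gene_id))
  summary <- bind_rows(lapply(names(de_tables), function(nm) {
    de <- de_tables[[nm]]
    de_ids <- de$gene_id[!is.na(de$significant) & de$significant]
    tibble(de_table = nm, n_genes = length(genes),
           n_de = sum(genes %in% de_ids),
           fraction_de = if (length(genes) > 0) {
             sum(genes %in% de_ids) / length(genes)
           } else NA_real_)
  }))
  list(selected_loci = selected, genes = genes, summary = summary,
       n_skipped_undefined = sum(undefined))
}
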