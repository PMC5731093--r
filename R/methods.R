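# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

tidy_dissim <- function(x) {
  m <- unclass(x)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  tibble(sample1 = rownames(m)[pairs[, 1]],
         sample2 = colnames(m)[pairs[, 2]],
         dissimilarity = m[pairs]) %>%
    arrange(.data$sample1, .data$sample2)
}

#' @export
tidy.dissim_matrix <- function(x, ...) tidy_dissim(x)

#' @export
glance.dissim_matrix <- function(x, ...) {
  v <- unclass(x)[upper.tri(x)]
  tibble(n_samples = nrow(x), n_pairs = length(v),
         mean = mean(v), sd = sd(v), min = min(v), max = max(v))
}

#' @export
tidy.de_results <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "de_results")
  out
}

#' @export
glance.de_results <- function(x, ...) {
  ct <- attr(x, "contrast")
  tibble(factor = unname(ct["factor"]),
         level1 = unname(ct["level1"]), level2 = unname(ct["level2"]),
         n_genes = nrow(x), n_tested = sum(!is.na(x$p)),
         n_significant = sum(x$significant, na.rm = TRUE),
         prior_var_lfc = attr(x, "prior_var_lfc"),
         n_samples = attr(x, "n_samples"))
}

#' @export
tidy.fst_scan <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "fst_scan")
  out
}

#' @export
glance.fst_scan <- function(x, ...) {
  fb <- attr(x, "fst_baseline")
  tibble(n_loci = nrow(x),
         n_outliers_q05 = sum(x$qvalue < 0.05),
         n_outliers_q001 = sum(x$qvalue < 0.001),
         fst_baseline_mean = mean(fb),
         n_excluded = attr(x, "n_excluded"))
}

#' MA plot of a differential-expression contrast
#'
#' @param object a `de_results` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.de_results <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[!is.na(d$A) & !is.na(d$M_shrunk), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$A, y = .data$M_shrunk,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red3")) +
    ggplot2::geom_hline(yintercept = c(-1, 0, 1), linetype = c(2, 1, 2),
                        linewidth = 0.3) +
    ggplot2::labs(x = "A (average log2 expression)",
                  y = "M (shrunken log2 fold change)",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Outlier plot of an FST scan
#'
#' Posterior mean locus effect against the q-value (log10 scale).
#'
#' @param object an `fst_scan` tibble.
#' @param q_threshold reference line (default 0.05).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fst_scan <- function(object, q_threshold = 0.05, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log10(pmax(.data$qvalue, 1e-4)),
                                  y = .data$alpha_mean,
                                  colour = .data$selection)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = log10(q_threshold), linetype = 2) +
    ggplot2::labs(x = "log10 q-value", y = "posterior mean alpha",
                  colour = "selection") +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param object an `expr_pca` object.
#' @param design optional design tibble to colour samples by a factor.
#' @param colour design column name for colouring.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.expr_pca <- function(object, design = NULL, colour = NULL, ...) {
  d <- object$scores
  if (!is.null(design) && !is.null(colour)) {
    d <- left_join(d, as_tibble(design), by = "sample")
  }
  ve <- round(100 * object$var_explained[1:2], 1)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = paste0("PC1 (", ve[1], "%)"),
                    y = paste0("PC2 (", ve[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Enrichment bar plot
#'
#' @param object an `enrichment` tibble.
#' @param max_categories categories shown, by increasing p (default 20).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.enrichment <- function(object, max_categories = 20, ...) {
  d <- head(as_tibble(object), max_categories)
  d$category <- factor(d$category, levels = rev(d$category))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(pmax(.data$one_tailed_p, 1e-16)),
                                  y = .data$category,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 one-tailed p", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a neighbour-joining relatedness tree
#'
#' @param tree an ape `phylo` tree from [nj_tree()].
#' @param design optional design tibble; tips are coloured by `colour`.
#' @param colour design column name.
#' @return invisibly, the tree (base-graphics plot via ape).
#' @export
plot_nj_tree <- function(tree, design = NULL, colour = NULL) {
  cols <- "black"
  if (!is.null(design) && !is.null(colour)) {
    grp <- design[[colour]][match(tree$tip.label, design$sample)]
    pal <- grDevices::hcl.colors(max(length(unique(grp)), 2), "Dark 2")
    cols <- pal[as.integer(factor(grp))]
  }
  ape::plot.phylo(tree, type = "unrooted", tip.color = cols, cex = 0.6)
  invisible(tree)
}
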