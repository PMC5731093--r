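# End-to-end pipeline: simulate (or load) inputs, genotype, relatedness,
# FST outlier scan, differential expression, enrichment, integration.
# Every stage writes its table under the configured output directory and is
# recorded in a machine-readable run manifest. Stage seeds are derived from
# the global seed so stages are independently reproducible.

#' Simulate gene features on the simulated contigs
#'
#' Places genes (with a CDS sub-feature) at random positions on the given
#' contigs, for exercising SNP-to-gene proximity and outlier annotation on
#' synthetic data.
#'
#' @param gene_ids character vector of gene ids to place.
#' @param contigs character vector of contig names to draw from.
#' @param contig_length assumed contig length in bases.
#' @param seed integer seed.
#' @return gene-feature tibble as from [read_gff()].
#' @export
simulate_gene_features <- function(gene_ids, contigs, contig_length = 50000,
                                   seed = 1L) {
  set.seed(seed)
  n <- length(gene_ids)
  start <- sample.int(max(contig_length - 6000, 1), n, replace = TRUE)
  len <- sample(1000:5000, n, replace = TRUE)
  gene <- tibble(gene_id = gene_ids,
                 contig = sample(contigs, n, replace = TRUE),
                 start = start, end = start + len,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 feature_type = "gene")
  cds <- mutate(gene, start = .data$start + 100L,
                end = pmax(.data$end - 100L, .data$start + 101L),
                feature_type = "CDS")
  arrange(bind_rows(gene, cds), .data$contig, .data$start, .data$gene_id)
}

#' Simulate a gene-to-category map
#'
#' Each gene draws 1-3 categories from a fixed vocabulary, uniformly.
#'
#' @param gene_ids character vector of gene ids.
#' @param n_categories number of category labels.
#' @param seed integer seed.
#' @return tibble gene_id, category.
#' @export
simulate_category_map <- function(gene_ids, n_categories = 10, seed = 1L) {
  set.seed(seed)
  cats <- sprintf("cat%02d", seq_len(n_categories))
  rows <- lapply(gene_ids, function(g) {
    tibble(gene_id = g, category = sample(cats, sample(1:3, 1)))
  })
  distinct(bind_rows(rows))
}

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Each block
#' overrides the defaults of the corresponding stage; unknown keys are
#' rejected.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @param popgen overrides for [popgen_sim_config()].
#' @param expr overrides for [expr_sim_config()] (the design is generated
#'   with [simulate_design()] unless supplied).
#' @param genotyping overrides for [genotype_pipeline()] thresholds.
#' @param mcmc overrides for [mcmc_settings_reduced()].
#' @param relatedness list with `n_loci` (random subsample size) and
#'   `min_genotyped_fraction`.
#' @param integration list with `threshold` and `window`.
#' @param contrasts character vector of design factors to contrast.
#' @param n_categories categories in the simulated annotation map.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, popgen = list(),
                            expr = list(), genotyping = list(),
                            mcmc = list(), relatedness = list(),
                            integration = list(),
                            contrasts = c("source", "exercise"),
                            n_categories = 10L) {
  check_keys <- function(block, allowed, name) {
    bad <- setdiff(names(block), allowed)
    assert_that(length(bad) == 0,
                paste0("unknown ", name, " config key(s): ",
                       paste(bad, collapse = ", ")))
  }
  check_keys(popgen, setdiff(names(formals(popgen_sim_config)), "seed"), "popgen")
  check_keys(expr, setdiff(names(formals(expr_sim_config)), "seed"), "expr")
  check_keys(genotyping, c("min_depth", "min_het_fraction", "min_individuals",
                           "min_alt_occurrences", "count_carriers"), "genotyping")
  check_keys(mcmc, setdiff(names(formals(mcmc_settings)), "seed"), "mcmc")
  check_keys(relatedness, c("n_loci", "min_genotyped_fraction"), "relatedness")
  check_keys(integration, c("threshold", "window"), "integration")
  assert_that(all(contrasts %in% DESIGN_FACTORS),
              "contrasts must be standard design factors")
  structure(list(out_dir = out_dir, seed = as.integer(seed), popgen = popgen,
                 expr = expr, genotyping = genotyping, mcmc = mcmc,
                 relatedness = relatedness, integration = integration,
                 contrasts = contrasts, n_categories = n_categories),
            class = "pipeline_config")
}

stage_seed <- function(seed, stage) (seed * 97L + stage * 1009L) %% 2000000000L

#' Run the full pipeline on simulated data
#'
#' Simulates two-population allele counts and a four-factor expression
#' matrix, then runs genotyping, group allele frequencies plus per-locus
#' heterogeneity tests, dissimilarity and a neighbour-joining tree, the
#' FST outlier scan, differential-expression contrasts, category
#' enrichment, and the frequency-difference-by-expression integration.
#' Every table is written as TSV (tree as newick) under `config$out_dir`
#' together with `manifest.json` recording seeds, parameters, outputs and
#' per-stage record counts. A stage failure stops the run with the partial
#' manifest (status "failed") on disk.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "traitpop",
                   version = as.character(utils::packageVersion("traitpop")),
                   seed = config$seed, stages = list())
  path <- function(f) file.path(config$out_dir, f)
  record <- function(name, outputs, n_records, seed, status = "ok") {
    manifest$stages[[name]] <<- list(status = status, outputs = outputs,
                                     n_records = n_records, seed = seed)
    jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  run_stage <- function(name, seed, fun) {
    tryCatch(fun(seed), error = function(e) {
      record(name, character(), 0L, seed, status = "failed")
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
  }

  # 1. simulate inputs
  s1 <- stage_seed(config$seed, 1L)
  sim <- run_stage("simulate", s1, function(seed) {
    pg_cfg <- do.call(popgen_sim_config, c(config$popgen, list(seed = seed)))
    if (is.null(pg_cfg$selected_loci) && is.null(config$popgen$selected_loci)) {
      pg_cfg <- do.call(popgen_sim_config,
                        c(config$popgen,
                          list(selected_loci = tibble(
                            locus = seq_len(min(8L, pg_cfg$n_loci)),
                            alpha = 2), seed = seed)))
    }
    pg <- simulate_genotypes(pg_cfg)
    counts_tab <- simulate_allele_counts(pg$genotypes, pg_cfg)
    ex_cfg <- do.call(expr_sim_config, c(config$expr, list(seed = seed + 1L)))
    if (is.null(config$expr$de_genes)) {
      n_de <- min(60L, ex_cfg$n_genes)
      ex_cfg <- do.call(expr_sim_config,
                        c(config$expr,
                          list(de_genes = tibble(
                            gene = seq_len(n_de),
                            factor = rep_len(c("source", "exercise"), n_de),
                            log2fc = rep_len(c(2, -2), n_de)),
                            seed = seed + 1L)))
    }
    ex <- simulate_expression(ex_cfg)
    write_allele_counts(counts_tab, path("allele_counts.tsv"))
    write_result_table(pg$truth, path("sim_popgen_truth.tsv"))
    write_result_table(ex$truth, path("sim_expr_truth.tsv"))
    write_result_table(ex$design, path("design.tsv"))
    cm <- bind_cols(tibble(gene_id = rownames(ex$counts)),
                    as_tibble(ex$counts))
    write_result_table(cm, path("expr_counts.tsv"))
    list(pg = pg, counts_tab = counts_tab, ex = ex, pg_cfg = pg_cfg)
  })
  record("simulate",
         c("allele_counts.tsv", "expr_counts.tsv", "design.tsv",
           "sim_popgen_truth.tsv", "sim_expr_truth.tsv"),
         c(nrow(sim$counts_tab), nrow(sim$ex$counts)), s1)

  # 2. genotyping
  s2 <- stage_seed(config$seed, 2L)
  geno <- run_stage("genotype", s2, function(seed) {
    do.call(genotype_pipeline, c(list(sim$counts_tab), config$genotyping))
  })
  write_result_table(geno, path("genotypes.tsv"))
  rep_ <- filter_report(geno)
  jsonlite::write_json(
    list(rules = rep_, n_input_loci = attr(rep_, "n_input_loci"),
         n_retained_loci = attr(rep_, "n_retained_loci")),
    path("filter_report.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  record("genotype", c("genotypes.tsv", "filter_report.json"),
         attr(rep_, "n_retained_loci"), s2)

  # 3. relatedness + allele-frequency analysis
  s3 <- stage_seed(config$seed, 3L)
  popg <- run_stage("popgen", s3, function(seed) {
    freqs <- group_allele_freqs(geno, rename(sim$pg$design,
                                             population = "population"),
                                "population")
    rel <- config$relatedness
    sub <- subsample_loci(geno, n_loci = rel$n_loci %||% 1000,
                          min_genotyped_fraction =
                            rel$min_genotyped_fraction %||% 0.60,
                          seed = seed)
    d <- pairwise_dissimilarity(sub)
    tree <- nj_tree(d)
    # per-locus heterogeneity tests between the two populations
    wide <- tidyr::pivot_wider(
      as_tibble(freqs)[c("group", "contig", "pos", "alt_count",
                         "total_alleles")],
      names_from = "group",
      values_from = c("alt_count", "total_alleles"))
    groups <- sort(unique(freqs$group))
    het <- bind_rows(lapply(seq_len(nrow(wide)), function(i) {
      tab <- matrix(c(wide[[paste0("alt_count_", groups[1])]][i],
                      wide[[paste0("total_alleles_", groups[1])]][i] -
                        wide[[paste0("alt_count_", groups[1])]][i],
                      wide[[paste0("alt_count_", groups[2])]][i],
                      wide[[paste0("total_alleles_", groups[2])]][i] -
                        wide[[paste0("alt_count_", groups[2])]][i]),
                    2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        return(tibble(contig = wide$contig[i], pos = wide$pos[i],
                      statistic = NA_real_, p_value = NA_real_))
      }
      ht <- chi2_heterogeneity(tab)
      tibble(contig = wide$contig[i], pos = wide$pos[i],
             statistic = ht$statistic, p_value = ht$p_value)
    }))
    list(freqs = freqs, d = d, tree = tree, het = het)
  })
  write_result_table(popg$freqs, path("group_freqs.tsv"))
  write_result_table(popg$het, path("heterogeneity_tests.tsv"))
  write_result_table(tidy_dissim(popg$d), path("dissimilarity.tsv"))
  write_newick(popg$tree, path("nj_tree.nwk"))
  record("popgen",
         c("group_freqs.tsv", "heterogeneity_tests.tsv",
           "dissimilarity.tsv", "nj_tree.nwk"),
         c(nrow(popg$freqs), nrow(popg$het)), s3)

  # 4. FST outlier scan
  s4 <- stage_seed(config$seed, 4L)
  scan <- run_stage("fst_scan", s4, function(seed) {
    settings <- do.call(mcmc_settings_reduced,
                        c(config$mcmc, list(seed = seed)))
    rjmcmc_scan(popg$freqs, settings)
  })
  features <- simulate_gene_features(
    rownames(sim$ex$counts)[seq_len(min(200L, nrow(sim$ex$counts)))],
    unique(sim$pg$truth$contig), seed = stage_seed(config$seed, 8L))
  scan_ann <- annotate_outliers(scan, features)
  write_result_table(scan_ann, path("fst_outliers.tsv"))
  record("fst_scan", "fst_outliers.tsv", nrow(scan_ann), s4)

  # 5. differential expression
  s5 <- stage_seed(config$seed, 5L)
  de_tables <- run_stage("diffexpr", s5, function(seed) {
    disp <- fit_dispersion(sim$ex$counts, sim$ex$design)
    out <- lapply(config$contrasts, function(f) {
      wald_contrast(sim$ex$counts, sim$ex$design, f, dispersion = disp)
    })
    names(out) <- config$contrasts
    out
  })
  for (f in names(de_tables)) {
    write_result_table(de_tables[[f]], path(paste0("de_", f, ".tsv")))
  }
  pca <- pca_transform(sim$ex$counts)
  write_result_table(pca$scores, path("pca_scores.tsv"))
  record("diffexpr",
         c(paste0("de_", names(de_tables), ".tsv"), "pca_scores.tsv"),
         vapply(de_tables, nrow, 1L), s5)

  # 6. enrichment
  s6 <- stage_seed(config$seed, 6L)
  enr <- run_stage("enrich", s6, function(seed) {
    map <- simulate_category_map(rownames(sim$ex$counts),
                                 config$n_categories, seed = seed)
    out <- list()
    for (f in names(de_tables)) {
      de <- de_tables[[f]]
      background <- de$gene_id[!is.na(de$p)]
      de_ids <- de$gene_id[!is.na(de$significant) & de$significant]
      out[[f]] <- if (length(de_ids) > 0) {
        enrich(de_ids, background, map)
      } else {
        tibble()
      }
    }
    list(map = map, tables = out)
  })
  write_result_table(enr$map, path("category_map.tsv"))
  for (f in names(enr$tables)) {
    write_result_table(enr$tables[[f]], path(paste0("enrichment_", f, ".tsv")))
  }
  record("enrich",
         c("category_map.tsv", paste0("enrichment_", names(enr$tables), ".tsv")),
         vapply(enr$tables, nrow, 1L), s6)

  # 7. integration
  s7 <- stage_seed(config$seed, 7L)
  integ <- run_stage("integrate", s7, function(seed) {
    thr <- config$integration$threshold %||% 0.50
    win <- config$integration$window %||% 100000
    freq_diff_intersections(popg$freqs, de_tables, features,
                            threshold = thr, window = win)
  })
  write_result_table(integ$summary, path("integration_summary.tsv"))
  write_result_table(integ$selected_loci, path("integration_loci.tsv"))
  record("integrate", c("integration_summary.tsv", "integration_loci.tsv"),
         nrow(integ$selected_loci), s7)

  invisible(manifest)
}

#' Run the demonstration pipeline
#'
#' [run_pipeline()] with desk-scale defaults: 500 loci with 8 under
#' diversifying selection across two populations of 60, a 1500-gene
#' expression matrix with 60 true effects over a balanced 32-sample
#' design, and reduced MCMC settings.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @return manifest list, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L) {
  cfg <- pipeline_config(
    out_dir, seed = seed,
    popgen = list(n_loci = 500, n_per_pop = 60),
    expr = list(n_genes = 1500),
    relatedness = list(n_loci = 200))
  run_pipeline(cfg)
}
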