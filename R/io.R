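# Readers/writers for the external formats the pipeline touches.
#
# The allele-count TSV dialect: header `contig  pos  ref  alt  <sample...>`,
# one row per biallelic site, per-sample cells "REF:ALT" read-depth pairs,
# "." meaning no data (stored as the 0:0 pair).

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a validated allele-count table
#'
#' An allele-count table is a long tibble with one row per (site, sample):
#' columns `contig`, `pos`, `ref`, `alt`, `sample`, `ref_depth`, `alt_depth`.
#' Sites are biallelic single-base substitutions; missing per-sample data is
#' encoded as the depth pair 0:0. Sites are stored sorted by (contig, pos).
#'
#' @param x data frame with the seven columns above.
#' @return tibble of class `allele_counts`.
#' @export
allele_counts <- function(x) {
  need <- c("contig", "pos", "ref", "alt", "sample", "ref_depth", "alt_depth")
  missing_cols <- setdiff(need, names(x))
  assert_that(length(missing_cols) == 0,
              paste0("allele_counts: missing columns: ",
                     paste(missing_cols, collapse = ", ")))
  x <- as_tibble(x)[need]
  x$pos <- as.integer(x$pos)
  x$ref_depth <- as.integer(x$ref_depth)
  x$alt_depth <- as.integer(x$alt_depth)
  assert_that(all(x$pos >= 1L), "allele_counts: positions must be >= 1 (1-based)")
  bad_depth <- which(x$ref_depth < 0L | x$alt_depth < 0L)
  assert_that(length(bad_depth) == 0,
              paste0("allele_counts: negative depth in row(s) ",
                     paste(head(bad_depth, 5), collapse = ", ")))
  assert_that(all(x$ref %in% VALID_BASES) && all(x$alt %in% VALID_BASES),
              "allele_counts: ref/alt must be single bases A/C/G/T")
  assert_that(all(x$ref != x$alt), "allele_counts: ref and alt must differ")
  # one alt allele per site; duplicated (contig, pos) rows are a caller error
  site <- distinct(x, .data$contig, .data$pos, .data$ref, .data$alt)
  dup <- duplicated(site[c("contig", "pos")])
  assert_that(!any(dup),
              paste0("allele_counts: duplicate site(s): ",
                     paste(head(locus_key(site$contig[dup], site$pos[dup]), 5),
                           collapse = ", ")))
  x <- arrange(x, .data$contig, .data$pos, .data$sample)
  class(x) <- c("allele_counts", class(x))
  x
}

#' Read an allele-count table from TSV or VCF
#'
#' TSV follows the package's allele-count dialect (see [allele_counts()]).
#' VCF must carry per-sample `AD` (allelic depth) fields; only biallelic
#' single-base SNV records are used and multi-allelic or non-SNV records are
#' skipped with a warning (count in attribute `n_skipped`).
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return an [allele_counts()] tibble.
#' @export
read_allele_counts <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (format == "tsv") read_allele_counts_tsv(path) else read_allele_counts_vcf(path)
}

read_allele_counts_tsv <- function(path) {
  lines <- readLines(path)
  assert_that(length(lines) >= 1, "empty allele-count file")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  assert_that(identical(header[1:4], c("contig", "pos", "ref", "alt")),
              "allele-count TSV header must start: contig pos ref alt")
  samples <- header[-(1:4)]
  assert_that(length(samples) >= 1, "allele-count TSV has no sample columns")
  n_skipped <- 0L
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      rlang::abort(paste0("malformed allele-count row at line ", i + 1L,
                          ": expected ", length(header), " fields, got ",
                          length(fields)))
    }
    ref <- fields[3]; alt <- fields[4]
    if (grepl(",", alt, fixed = TRUE) || nchar(ref) != 1L || nchar(alt) != 1L) {
      n_skipped <- n_skipped + 1L
      next
    }
    pairs <- fields[-(1:4)]
    pairs[pairs == "."] <- "0:0"
    mat <- matrix(suppressWarnings(as.integer(unlist(
      strsplit(pairs, ":", fixed = TRUE)))), nrow = 2L)
    if (anyNA(mat)) {
      rlang::abort(paste0("malformed depth pair at line ", i + 1L))
    }
    if (any(mat < 0L)) {
      rlang::abort(paste0("negative depth at line ", i + 1L))
    }
    rows[[i]] <- tibble(
      contig = fields[1], pos = as.integer(fields[2]), ref = ref, alt = alt,
      sample = samples, ref_depth = mat[1, ], alt_depth = mat[2, ])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (n_skipped > 0) {
    rlang::warn(paste0("skipped ", n_skipped, " non-biallelic site(s)"))
  }
  assert_that(length(rows) > 0, "no usable sites in allele-count file")
  out <- allele_counts(bind_rows(rows))
  attr(out, "n_skipped") <- n_skipped
  out
}

read_allele_counts_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% VALID_BASES & fix$ALT %in% VALID_BASES
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    rlang::warn(paste0("skipped ", n_skipped, " non-biallelic site(s)"))
  }
  assert_that(any(keep), "no biallelic SNV records with AD in VCF")
  ad <- vcfR::extract.gt(vcf, element = "AD")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  parse_ad <- function(x) {
    x[is.na(x) | x == "." | x == "./."] <- "0,0"
    m <- matrix(suppressWarnings(as.integer(unlist(
      strsplit(x, ",", fixed = TRUE)))), nrow = 2L)
    m[is.na(m)] <- 0L
    m
  }
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    m <- parse_ad(ad[i, ])
    tibble(contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
           ref = fix$REF[i], alt = fix$ALT[i],
           sample = colnames(ad), ref_depth = m[1, ], alt_depth = m[2, ])
  })
  out <- allele_counts(bind_rows(rows))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write an allele-count table in the package TSV dialect
#'
#' Inverse of [read_allele_counts()] for `format = "tsv"`; writing then
#' reading reproduces the table exactly.
#'
#' @param x an [allele_counts()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(x, path) {
  x <- allele_counts(x)
  wide <- tidyr::pivot_wider(
    mutate(x, cell = paste0(.data$ref_depth, ":", .data$alt_depth)),
    id_cols = c("contig", "pos", "ref", "alt"),
    names_from = "sample", values_from = "cell")
  wide <- arrange(wide, .data$contig, .data$pos)
  lines <- c(paste(names(wide), collapse = "\t"),
             apply(as.matrix(wide), 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Keeps `gene`, `CDS`, `five_prime_UTR` and `three_prime_UTR` records;
#' `exon` and `mRNA` records (and any other types) are dropped. `gene`
#' records are retained because gene ranges drive SNP-to-gene proximity,
#' while the UTR/CDS records label the feature context of individual SNPs.
#' Records with end < start are rejected with a warning.
#'
#' @param path GFF3 file path.
#' @return tibble with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `feature_type` (1-based inclusive coordinates).
#' @export
read_gff <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  # screen records rtracklayer would refuse wholesale: reject them
  # individually with a warning, then parse the remainder properly
  start <- suppressWarnings(as.integer(vapply(
    strsplit(lines[body], "\t", fixed = TRUE),
    function(f) if (length(f) == 9L) f[4] else NA_character_, "")))
  end <- suppressWarnings(as.integer(vapply(
    strsplit(lines[body], "\t", fixed = TRUE),
    function(f) if (length(f) == 9L) f[5] else NA_character_, "")))
  bad <- is.na(start) | is.na(end) | end < start
  if (any(bad)) {
    rlang::warn(paste0("rejected ", sum(bad), " GFF record(s) with end < start",
                       " or malformed coordinates"))
    keep_lines <- lines
    keep_lines[body][bad] <- NA
    path <- tempfile(fileext = ".gff3")
    writeLines(keep_lines[!is.na(keep_lines)], path)
    on.exit(unlink(path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(empty_gene_features())
  keep_types <- c("gene", "CDS", "five_prime_UTR", "three_prime_UTR")
  gr <- gr[as.character(gr$type) %in% keep_types]
  if (length(gr) == 0) return(empty_gene_features())
  type <- as.character(gr$type)
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else
    rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    vapply(gr$Parent, function(x) if (length(x)) x[[1]] else NA_character_, "")
  } else rep(NA_character_, length(gr))
  gene_id <- ifelse(type == "gene", id, ifelse(is.na(parent), id, parent))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  out <- tibble(
    gene_id = gene_id,
    contig = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = strand, feature_type = type)
  arrange(out, .data$contig, .data$start, .data$end, .data$gene_id)
}

empty_gene_features <- function() {
  tibble(gene_id = character(), contig = character(), start = integer(),
         end = integer(), strand = character(), feature_type = character())
}

#' Write / read trees in newick format
#'
#' Thin wrappers over ape; round-trip stable (topology and branch lengths).
#'
#' @param tree an ape `phylo` object.
#' @param path optional file path; if `NULL` the newick string is returned.
#' @return newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  assert_that(inherits(tree, "phylo"), "write_newick needs an ape phylo tree")
  s <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' @rdname write_newick
#' @param text newick string (used when `path` is `NULL`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}

#' Write a result table as TSV
#'
#' Column names form the documented header; an empty tibble yields a
#' header-only file.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "NA")
  invisible(path)
}
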