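#' Read a per-SNP p-value table
#'
#' Reads a tab-separated file with header columns `snp_id`, `chrom`,
#' `pos`, `p` (lines starting with `#` are metadata and skipped) into a
#' validated [pvalue_set()], preserving row order. Errors name the
#' offending data line.
#'
#' @param path file path.
#' @return A [pvalue_set()].
#' @export
read_pvalue_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1L || all(!nzchar(lines)))
    stop("empty p-value table: ", path)
  x <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "",
                         check.names = TRUE)
  required <- c("snp_id", "chrom", "pos", "p")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  p <- suppressWarnings(as.numeric(x$p))
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad) > 0)
    stop("invalid p-value '", x$p[bad[1]], "' on line ", bad[1] + 1L,
         " of ", path, " (must be a number in [0, 1])")
  pos <- suppressWarnings(as.numeric(x$pos))
  bad <- which(is.na(pos) | pos < 0)
  if (length(bad) > 0)
    stop("invalid position '", x$pos[bad[1]], "' on line ", bad[1] + 1L,
         " of ", path)
  if (anyDuplicated(x$snp_id)) {
    dup <- which(duplicated(x$snp_id))[1]
    stop("duplicate snp_id '", x$snp_id[dup], "' on line ", dup + 1L,
         " of ", path)
  }
  pvalue_set(x$snp_id, x$chrom, pos, p)
}

#' Read prioritized regions (BED or gene table)
#'
#' Two dialects are supported. `"bed"`: BED3+name, 0-based half-open,
#' converted on read to the package's 1-based inclusive convention
#' (start + 1). `"gene_tsv"`: tab-separated with header columns `gene`,
#' `chrom`, `start_bp`, `end_bp`, already 1-based inclusive (the layout
#' of a gene-location table).
#'
#' @param path file path.
#' @param dialect `"bed"` or `"gene_tsv"`.
#' @return A [region_set()] (possibly empty).
#' @export
read_regions <- function(path, dialect = c("bed", "gene_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                     !startsWith(lines, "track")]
    if (length(lines) == 0)
      return(region_set(character(0), numeric(0), numeric(0), character(0)))
    x <- utils::read.table(text = lines, sep = "\t", quote = "",
                           colClasses = "character")
    if (ncol(x) < 3) stop("BED file needs at least 3 columns: ", path)
    start <- as.numeric(x[[2]]) + 1   # 0-based half-open -> 1-based inclusive
    end <- as.numeric(x[[3]])
    src <- if (ncol(x) >= 4) x[[4]] else rep(NA_character_, nrow(x))
    region_set(x[[1]], start, end, src)
  } else {
    x <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character")
    required <- c("gene", "chrom", "start_bp", "end_bp")
    missing <- setdiff(required, names(x))
    if (length(missing) > 0)
      stop("missing column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
    if (nrow(x) == 0)
      return(region_set(character(0), numeric(0), numeric(0), character(0)))
    region_set(x$chrom, as.numeric(x$start_bp), as.numeric(x$end_bp), x$gene)
  }
}

#' Write an adjustment result (or any table) as annotated TSV
#'
#' Writes tab-separated output preceded by `#`-prefixed metadata lines
#' (method, level, seed, package version), so the file remains a valid
#' input for [read_pvalue_table()]-style readers. Writing an
#' `fdr_adjustment` together with its `pvalue_set` reproduces the input
#' columns plus `method`, `level`, `subset`, `weighted_p` and
#' `rejected` (0/1).
#'
#' @param x an `fdr_adjustment`, or a data frame.
#' @param path output path.
#' @param markers the [pvalue_set()] the adjustment was computed from
#'   (required when `x` is an `fdr_adjustment`).
#' @param seed optional seed to record in the metadata.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path, markers = NULL, seed = NULL) {
  meta <- c(paste0("# priorfdr ",
                   as.character(utils::packageVersion("priorfdr"))))
  if (inherits(x, "fdr_adjustment")) {
    if (is.null(markers))
      stop("writing an fdr_adjustment needs the 'markers' pvalue_set")
    if (nrow(markers) != x$m)
      stop("'markers' does not match the adjustment (different m)")
    meta <- c(meta, paste0("# method=", x$method), paste0("# level=", x$level))
    x <- data.frame(markers[, c("snp_id", "chrom", "pos", "p")],
                    method = x$method, level = x$level, subset = x$subset,
                    weighted_p = x$weighted_p,
                    rejected = as.integer(x$rejected),
                    stringsAsFactors = FALSE)
  }
  if (!is.null(seed)) meta <- c(meta, paste0("# seed=", seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate small seeded fixture files
#'
#' Writes self-contained synthetic datasets used in examples and
#' tests; everything is generated from the seed, nothing is downloaded.
#'
#' \describe{
#'   \item{`toy_pvalues`}{a 20-SNP p-value table with a known BH
#'     outcome at q = 0.05, plus a matching one-gene region BED.}
#'   \item{`null_panel`}{a p-value table from one all-null
#'     statistic-level replicate on a small marker map.}
#'   \item{`disease_model_panel`}{a genotype panel TSV (plus marker map
#'     and phenotype) simulated under the six-locus disease model at
#'     desk scale.}
#' }
#'
#' @param kind fixture kind (see Details).
#' @param seed integer seed; same seed, byte-identical files.
#' @param out_dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(kind = c("toy_pvalues", "null_panel",
                                   "disease_model_panel"),
                          seed = 1L, out_dir = ".") {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (kind == "toy_pvalues") {
    set.seed(derive_seed(seed, 1L))
    m <- 20L
    p <- round(stats::runif(m), 6)
    p[1:3] <- c(0.0004, 0.0011, 0.0052)  # three planted signals
    ps <- pvalue_set(sprintf("rs%03d", 1:m), rep("1", m),
                     seq_len(m) * 100000L, p)
    f <- file.path(out_dir, "toy_pvalues.tsv")
    write_results(as.data.frame(ps), f, seed = seed)
    bed <- file.path(out_dir, "toy_region.bed")
    writeLines("1\t99999\t300000\ttoy_gene", bed)
    files <- c(f, bed)
  } else if (kind == "null_panel") {
    cfg <- stat_panel_config(markers = marker_map(n_chrom = 2L,
                                                  snps_per_chrom = 500L),
                             cluster_chrom = character(0), mu = numeric(0))
    panel <- simulate_stat_panel(cfg, 1L, seed)
    f <- file.path(out_dir, "null_panel_pvalues.tsv")
    write_results(as.data.frame(as_pvalue_set(panel)), f, seed = seed)
    files <- f
  } else {
    set.seed(derive_seed(seed, 2L))
    model <- haplotype_model(maf = stats::runif(120, 0.05, 0.5),
                             chrom = rep(c("1", "2"), each = 60))
    disease <- disease_model(c(30L, 90L), grr = c(1.34, 1.57),
                             maf = model$maf[c(30L, 90L)], prevalence = 0.05)
    cc <- simulate_case_control(model, disease, 100L, 100L, seed = seed)
    f1 <- file.path(out_dir, "genotypes.tsv")
    utils::write.table(cc$genotypes, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    f2 <- file.path(out_dir, "phenotype.tsv")
    utils::write.table(data.frame(phenotype = cc$phenotype), f2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    f3 <- file.path(out_dir, "marker_map.tsv")
    utils::write.table(data.frame(snp_id = paste0("snp_", seq_len(model$n_snps)),
                                  chrom = model$chrom, pos = model$pos),
                       f3, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(f1, f2, f3)
  }
  invisible(files)
}
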