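#' Genotype counts for a single SNP
#'
#' Convenience container for the 2 x 3 genotype table of one SNP:
#' counts of the three genotypes (minor-allele count 2, 1, 0 written
#' `aa`, `Aa`, `AA`) in cases and controls.
#'
#' @param case,control length-3 integer vectors `c(AA, Aa, aa)` of
#'   genotype counts (major homozygote, heterozygote, minor
#'   homozygote).
#' @return A list of class `genotype_counts`.
#' @export
genotype_counts <- function(case, control) {
  if (length(case) != 3L || length(control) != 3L)
    stop("case and control must each give 3 genotype counts (AA, Aa, aa)")
  if (any(case < 0) || any(control < 0) ||
      any(case != floor(case)) || any(control != floor(control)))
    stop("genotype counts must be non-negative integers")
  if (sum(case) == 0 || sum(control) == 0)
    stop("each group must contain at least one individual")
  structure(list(case = as.numeric(case), control = as.numeric(control)),
            class = "genotype_counts")
}

# 2x2 Pearson chi-square without continuity correction, upper-tail p
chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(list(stat = NA_real_, p = 1))
  stat <- n * (a * d - b * c)^2 / den
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Allelic (1-df) chi-square association test
#'
#' Pearson chi-square on the 2 x 2 allele table: each individual
#' contributes two alleles (`2*hom + het` minor alleles per group).
#' No continuity correction. A monomorphic SNP (zero allele margin)
#' returns p = 1 with a warning.
#'
#' @param counts a [genotype_counts()].
#' @return The upper-tail p-value (with attribute `statistic`).
#' @examples
#' # case minor/major alleles 60/140 vs control 40/160
#' allelic_chisq(genotype_counts(c(45, 50, 5), c(62, 36, 2)))
#' @export
allelic_chisq <- function(counts) {
  a <- 2 * counts$case[3] + counts$case[2]      # case minor alleles
  b <- 2 * counts$case[1] + counts$case[2]      # case major alleles
  c <- 2 * counts$control[3] + counts$control[2]
  d <- 2 * counts$control[1] + counts$control[2]
  if (a + c == 0 || b + d == 0) {
    warning("monomorphic SNP: allele margin is zero; returning p = 1")
    return(structure(1, statistic = NA_real_))
  }
  res <- chisq_2x2(a, b, c, d)
  structure(res$p, statistic = res$stat)
}

#' Genotypic (2-df) chi-square association test
#'
#' Pearson chi-square on the 2 x 3 genotype table. Genotype columns
#' empty in both groups are collapsed out first, so the degrees of
#' freedom equal the number of non-empty columns minus one. Fewer than
#' two non-empty columns (no genotype variation) returns p = 1 with a
#' warning.
#'
#' @param counts a [genotype_counts()].
#' @return The upper-tail p-value (with attributes `statistic`, `df`).
#' @export
genotypic_chisq <- function(counts) {
  tab <- rbind(counts$case, counts$control)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2L) {
    warning("fewer than 2 non-empty genotype columns; returning p = 1")
    return(structure(1, statistic = NA_real_, df = NA_integer_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1L
  structure(stats::pchisq(stat, df = df, lower.tail = FALSE),
            statistic = stat, df = df)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg equilibrium for one SNP:
#' conditional on the observed allele counts, every compatible
#' heterozygote count `h` has probability proportional to
#' `2^h * n! / (n_AA! n_Aa! n_aa!)`; the p-value is the total
#' probability of configurations no more probable than the observed
#' one (standard, not mid-p). A monomorphic SNP returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major homozygote,
#'   heterozygote, minor homozygote).
#' @return Exact p-value.
#' @examples
#' hwe_exact(1, 0, 1)  # 1/3
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) ||
      any(c(n_AA, n_Aa, n_aa) != floor(c(n_AA, n_Aa, n_aa))))
    stop("genotype counts must be non-negative integers")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total count must be positive")
  n_minor <- 2 * n_aa + n_Aa
  n_major <- 2 * n_AA + n_Aa
  if (n_minor == 0 || n_major == 0) return(1)
  # heterozygote counts compatible with the allele margin
  h <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  aa <- (n_minor - h) / 2
  AA <- n - aa - h
  logp <- h * log(2) - lfactorial(AA) - lfactorial(h) - lfactorial(aa)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[h == n_Aa]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

#' Hardy-Weinberg QC filter
#'
#' Flags the SNPs of a case-control panel that pass the HWE exact test
#' in the control group: a SNP is retained iff its control-group
#' [hwe_exact()] p-value is at least `threshold`. The default 1e-4 is
#' the conventional GWAS genotyping-QC cutoff.
#'
#' @param panel a `case_control_data` (see [simulate_case_control()]),
#'   or a genotype matrix with a 0/1 `phenotype` vector.
#' @param threshold exclusion threshold in (0, 1).
#' @param phenotype needed only when `panel` is a bare matrix.
#' @return Logical vector, `TRUE` for retained SNPs.
#' @export
hwe_filter <- function(panel, threshold = 1e-4, phenotype = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  if (inherits(panel, "case_control_data")) {
    g <- panel$genotypes; phenotype <- panel$phenotype
  } else g <- panel
  ctl <- g[phenotype == 0L, , drop = FALSE]
  counts <- genotype_count_matrix(ctl)
  p <- vapply(seq_len(ncol(g)), function(j)
    hwe_exact(counts[1, j], counts[2, j], counts[3, j]), numeric(1))
  p >= threshold
}

# 3 x m matrix of genotype counts (rows: AA, Aa, aa) for a genotype
# matrix of minor-allele dosages
genotype_count_matrix <- function(g) {
  het <- colSums(g == 1L)
  hom <- colSums(g == 2L)
  rbind(AA = nrow(g) - het - hom, Aa = het, aa = hom)
}

# vectorized per-SNP association tests on a genotype matrix
panel_test_pvalues <- function(g, phenotype, test = c("allelic", "genotypic")) {
  test <- match.arg(test)
  case <- genotype_count_matrix(g[phenotype == 1L, , drop = FALSE])
  ctrl <- genotype_count_matrix(g[phenotype == 0L, , drop = FALSE])
  m <- ncol(g)
  if (test == "allelic") {
    a <- 2 * case[3, ] + case[2, ]; b <- 2 * case[1, ] + case[2, ]
    c <- 2 * ctrl[3, ] + ctrl[2, ]; d <- 2 * ctrl[1, ] + ctrl[2, ]
    n <- a + b + c + d
    den <- (a + b) * (c + d) * (a + c) * (b + d)
    stat <- ifelse(den == 0, NA_real_, n * (a * d - b * c)^2 / den)
    p <- ifelse(is.na(stat), 1,
                stats::pchisq(stat, df = 1, lower.tail = FALSE))
  } else {
    p <- vapply(seq_len(m), function(j)
      as.numeric(genotypic_chisq_quiet(case[, j], ctrl[, j])), numeric(1))
  }
  p
}

genotypic_chisq_quiet <- function(case, ctrl) {
  tab <- rbind(case, ctrl)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0)) return(1)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  stats::pchisq(stat, df = ncol(tab) - 1L, lower.tail = FALSE)
}

#' Association tests for every SNP of a case-control panel
#'
#' Runs the chosen per-SNP test across a whole panel and returns a
#' [pvalue_set()].
#'
#' @param panel a `case_control_data`.
#' @param test `"allelic"` (1-df allele-count chi-square) or
#'   `"genotypic"` (2-df genotype-table chi-square).
#' @param keep optional logical mask of SNPs to test (e.g. from
#'   [hwe_filter()]); excluded SNPs are dropped from the output.
#' @return A [pvalue_set()] with one row per retained SNP.
#' @export
association_scan <- function(panel, test = c("allelic", "genotypic"),
                             keep = NULL) {
  test <- match.arg(test)
  g <- panel$genotypes
  if (is.null(keep)) keep <- rep(TRUE, ncol(g))
  p <- panel_test_pvalues(g[, keep, drop = FALSE], panel$phenotype, test)
  mk <- panel$model
  pvalue_set(paste0("snp_", which(keep)), mk$chrom[keep], mk$pos[keep], p)
}

#' Permutation null p-values
#'
#' Permutes the phenotype labels `B` times and recomputes the chosen
#' association test for every SNP under each permutation, yielding the
#' empirical null used by the permutation-based FDR estimate
#' ([permutation_fdr_estimate()]). Each permutation is seeded
#' independently from the master seed, so individual permutations are
#' reproducible in isolation.
#'
#' @param panel a `case_control_data`.
#' @param test `"allelic"` or `"genotypic"`.
#' @param B number of permutations.
#' @param seed master integer seed.
#' @param permutations optional list of explicit index vectors
#'   (overrides random permutation; an identity permutation reproduces
#'   the observed p-values).
#' @param keep optional logical mask of SNPs to include.
#' @return A `B x m` matrix of null p-values.
#' @export
permutation_null_pvalues <- function(panel, test = c("allelic", "genotypic"),
                                     B = 100L, seed = 1L,
                                     permutations = NULL, keep = NULL) {
  test <- match.arg(test)
  if (B < 1) stop("B must be >= 1")
  g <- panel$genotypes
  if (!is.null(keep)) g <- g[, keep, drop = FALSE]
  n <- nrow(g)
  out <- matrix(NA_real_, B, ncol(g))
  for (b in seq_len(B)) {
    perm <- if (!is.null(permutations)) permutations[[b]] else {
      set.seed(derive_seed(seed, b))
      sample.int(n)
    }
    out[b, ] <- panel_test_pvalues(g, panel$phenotype[perm], test)
  }
  out
}
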