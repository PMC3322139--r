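#' Scaled synthetic marker map
#'
#' Builds the default desk-scale marker map used by the statistic-level
#' simulator: 22 pseudo-chromosomes of `snps_per_chrom` equally spaced
#' SNPs. The defaults (22 x 1428 = 31,416 SNPs at 8,900 bp spacing,
#' ~112 SNPs/Mb) are a one-tenth scale model of a 314k-SNP genome-wide
#' panel that keeps Mb-based windows meaningful: a 2 Mb prioritized
#' region holds ~225 SNPs and a 1 Mb power window ~112 SNPs on each
#' side.
#'
#' @param n_chrom number of pseudo-chromosomes.
#' @param snps_per_chrom SNPs per chromosome.
#' @param spacing_bp distance between adjacent SNPs in bp.
#' @return A data frame with `snp_id`, `chrom`, `pos`.
#' @export
marker_map <- function(n_chrom = 22L, snps_per_chrom = 1428L,
                       spacing_bp = 8900L) {
  chrom <- rep(as.character(seq_len(n_chrom)), each = snps_per_chrom)
  pos <- rep(seq_len(snps_per_chrom) * spacing_bp, n_chrom)
  data.frame(snp_id = paste0("snp_", chrom, "_", pos),
             chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Configuration for the statistic-level panel simulator
#'
#' The statistic-level simulator is the fast surrogate for the full
#' genotype pipeline, enabling Monte-Carlo FDR/power studies with
#' thousands of replicates: it draws per-SNP z-scores directly. Null
#' SNPs follow a latent AR(1) Gaussian within LD blocks of `block_size`
#' SNPs (parameter `rho`), mimicking clusters of correlated test
#' statistics. Each causal locus contributes one lead z-score drawn
#' from `Normal(mu, 1)` plus `cluster_size - 1` tag SNPs whose
#' correlation with the lead decays as `rho_tag^d` with the SNP offset
#' `d`, so a detected locus shows several (not dozens of) significant
#' SNPs, as in real LD around an association peak.
#'
#' The default six causal loci mirror the standard disease model:
#' three small-effect loci (lead noncentrality `mu = 5.2`) on
#' chromosomes 6, 10, 5 and three large-effect loci (`mu = 6`) on
#' chromosomes 3, 11, 4, each at the center of its chromosome.
#'
#' @param markers marker map data frame (`snp_id`, `chrom`, `pos`).
#' @param block_size SNPs per LD block.
#' @param rho within-block AR(1) correlation of null z-scores.
#' @param cluster_chrom chromosome of each causal locus.
#' @param mu per-locus lead noncentrality.
#' @param cluster_size SNPs per causal cluster (lead + tags).
#' @param rho_tag base of the tag-correlation decay.
#' @return An object of class `stat_panel_config` with the marker map,
#'   block layout and causal-cluster table (`clusters`: `locus`,
#'   `chrom`, `pos`, `mu`; lead positions double as the true causal
#'   positions).
#' @export
stat_panel_config <- function(markers = marker_map(), block_size = 50L,
                              rho = 0.8,
                              cluster_chrom = c("6", "10", "5", "3", "11", "4"),
                              mu = c(5.2, 5.2, 5.2, 6, 6, 6),
                              cluster_size = 10L, rho_tag = 0.8) {
  stopifnot(length(mu) == length(cluster_chrom), cluster_size >= 1L,
            rho >= 0, rho < 1, rho_tag >= 0, rho_tag < 1)
  m <- nrow(markers)
  within <- stats::ave(seq_len(m), markers$chrom, FUN = seq_along)
  block <- cumsum(within %% block_size == 1L |
                    c(TRUE, markers$chrom[-1] != markers$chrom[-m]))
  block_lens <- rle(block)$lengths
  maxB <- max(block_lens)
  # linear index into the maxB x n_blocks generation matrix (column-major)
  sel <- unlist(lapply(seq_along(block_lens), function(j)
    (j - 1L) * maxB + seq_len(block_lens[j])))

  clusters <- data.frame(locus = seq_along(cluster_chrom),
                         chrom = cluster_chrom,
                         pos = rep(NA_real_, length(cluster_chrom)), mu = mu,
                         stringsAsFactors = FALSE)
  members <- vector("list", nrow(clusters))
  lead_idx <- integer(nrow(clusters))
  for (j in seq_len(nrow(clusters))) {
    idx <- which(markers$chrom == cluster_chrom[j])
    if (length(idx) < cluster_size)
      stop("chromosome ", cluster_chrom[j], " too small for a cluster")
    lead <- idx[ceiling(length(idx) / 2)]
    lo <- lead - (cluster_size - 1L) %/% 2L
    mem <- lo:(lo + cluster_size - 1L)
    mem <- mem[mem >= min(idx) & mem <= max(idx)]
    members[[j]] <- mem
    lead_idx[j] <- lead
    clusters$pos[j] <- markers$pos[lead]
  }
  structure(list(markers = markers, m = m, block_size = as.integer(block_size),
                 rho = rho, block_lens = block_lens, maxB = maxB, sel = sel,
                 clusters = clusters, members = members, lead_idx = lead_idx,
                 cluster_size = as.integer(cluster_size), rho_tag = rho_tag),
            class = "stat_panel_config")
}

#' @export
print.stat_panel_config <- function(x, ...) {
  cat("stat_panel_config:", x$m, "SNPs,",
      length(unique(x$markers$chrom)), "chromosomes, block size",
      x$block_size, "(rho =", x$rho, ")\n")
  cat("  ", nrow(x$clusters), "causal clusters of", x$cluster_size,
      "SNPs (rho_tag =", x$rho_tag, "):\n")
  print(x$clusters)
  invisible(x)
}

derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 69069 + as.double(index) * 1234567) %%
               2147483629)
}

#' Simulate one statistic-level GWAS replicate
#'
#' Draws a full panel of per-SNP z-scores and two-sided normal
#' p-values under the configuration's LD-block null model and causal
#' clusters (see [stat_panel_config()]). Replicates indexed by
#' `replicate_index` form independent streams under one master `seed`.
#'
#' @param config a [stat_panel_config()].
#' @param replicate_index replicate number (>= 1).
#' @param seed master integer seed.
#' @return A list of class `stat_panel`: `z`, `p` (length-m numeric in
#'   marker order), and the `config`.
#' @export
simulate_stat_panel <- function(config, replicate_index = 1L, seed = 1L) {
  set.seed(derive_seed(seed, replicate_index))
  nb <- length(config$block_lens)
  E <- matrix(stats::rnorm(config$maxB * nb), config$maxB, nb)
  if (config$rho > 0 && config$maxB > 1) {
    s <- sqrt(1 - config$rho^2)
    for (t in 2:config$maxB)
      E[t, ] <- config$rho * E[t - 1L, ] + s * E[t, ]
  }
  z <- as.vector(E)[config$sel]
  for (j in seq_len(nrow(config$clusters))) {
    mem <- config$members[[j]]
    lead <- config$lead_idx[j]
    z_lead <- config$clusters$mu[j] + stats::rnorm(1)
    z[lead] <- z_lead
    tags <- setdiff(mem, lead)
    if (length(tags) > 0) {
      cor_tag <- config$rho_tag^abs(tags - lead)
      z[tags] <- cor_tag * z_lead +
        sqrt(1 - cor_tag^2) * stats::rnorm(length(tags))
    }
  }
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)), config = config),
            class = "stat_panel")
}

#' @export
print.stat_panel <- function(x, ...) {
  cat("stat_panel:", length(x$p), "tests; min p =",
      format(min(x$p), digits = 4), "\n")
  invisible(x)
}

#' Convert a statistic-level panel to a p-value set
#'
#' @param panel a `stat_panel` from [simulate_stat_panel()].
#' @return A [pvalue_set()] in marker order.
#' @export
as_pvalue_set <- function(panel) {
  mk <- panel$config$markers
  pvalue_set(mk$snp_id, mk$chrom, mk$pos, panel$p)
}
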