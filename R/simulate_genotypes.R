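#' Haplotype model with LD blocks
#'
#' Describes a synthetic SNP panel for genotype simulation: per-SNP
#' minor-allele frequencies and a latent-Gaussian AR(1) block copula
#' for linkage disequilibrium. Haplotypes are drawn per LD block from a
#' latent AR(1) Gaussian with parameter `rho` and thresholded at the
#' allele-frequency quantile, so the per-SNP marginal allele frequency
#' equals `maf` and Hardy-Weinberg equilibrium holds by construction
#' (the two haplotypes of an individual are independent).
#'
#' @param maf per-SNP minor-allele frequency in (0, 0.5].
#' @param chrom chromosome label per SNP (default: one chromosome).
#' @param pos base-pair position per SNP, strictly increasing within
#'   chromosome (default: 8,900 bp spacing).
#' @param block_size SNPs per LD block (blocks never span chromosomes).
#' @param rho within-block latent correlation in \[0, 1).
#' @return An object of class `haplotype_model`.
#' @export
haplotype_model <- function(maf, chrom = rep("1", length(maf)),
                            pos = NULL, block_size = 50L, rho = 0.8) {
  maf <- as.numeric(maf)
  if (any(maf <= 0) || any(maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  chrom <- as.character(chrom)
  if (is.null(pos))
    pos <- stats::ave(seq_along(maf), chrom, FUN = seq_along) * 8900
  if (any(stats::ave(pos, chrom, FUN = function(x) c(1, diff(x))) <= 0))
    stop("positions must be strictly increasing within chromosome")
  # block index: consecutive runs of block_size within each chromosome
  within <- stats::ave(seq_along(maf), chrom, FUN = seq_along)
  block <- paste0(chrom, "_", (within - 1L) %/% block_size)
  structure(list(n_snps = length(maf), maf = maf, chrom = chrom,
                 pos = as.numeric(pos), block = block,
                 block_size = as.integer(block_size), rho = rho),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat("haplotype_model:", x$n_snps, "SNPs,",
      length(unique(x$chrom)), "chromosome(s), block size", x$block_size,
      ", rho =", x$rho, "\n")
  invisible(x)
}

# one haplotype matrix (n_hap x n_snps) of 0/1 alleles
draw_haplotypes <- function(model, n_hap) {
  z <- matrix(0, n_hap, model$n_snps)
  s <- sqrt(1 - model$rho^2)
  for (b in unique(model$block)) {
    idx <- which(model$block == b)
    zb <- matrix(stats::rnorm(n_hap * length(idx)), n_hap, length(idx))
    if (model$rho > 0 && length(idx) > 1) {
      for (t in 2:length(idx))
        zb[, t] <- model$rho * zb[, t - 1] + s * zb[, t]
    }
    z[, idx] <- zb
  }
  # allele = 1 (minor) when the latent variable falls below the maf quantile
  sweep(z, 2, stats::qnorm(model$maf), "<") + 0
}

#' Draw unphased genotypes under the haplotype model
#'
#' Each individual is the sum of two independent haplotypes, so
#' genotypes are counts of the minor allele in \{0, 1, 2\}, marginal
#' allele frequencies equal `maf` in expectation, and every SNP is in
#' Hardy-Weinberg equilibrium.
#'
#' @param model a [haplotype_model()].
#' @param n number of individuals.
#' @param seed integer seed (same seed, identical matrix).
#' @return Integer matrix `n x n_snps` of minor-allele counts.
#' @export
draw_genotypes <- function(model, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  draw_haplotypes(model, n) + draw_haplotypes(model, n)
}

#' Multiplicative genotypic-relative-risk disease model
#'
#' Penetrance model for a set of causal loci: an individual carrying
#' `x_j` copies of the risk allele at causal locus `j` is affected with
#' probability `p_base * prod_j grr_j^x_j`. Risk alleles are the minor
#' alleles by convention. `p_base` (the penetrance of the zero-risk-
#' allele genotype) is calibrated with [calibrate_baseline()] so the
#' population prevalence hits a target value.
#'
#' @param causal_index column indices of the causal SNPs in the
#'   genotype matrix / haplotype model.
#' @param grr per-locus genotypic relative risk per risk allele,
#'   `>= 1`.
#' @param maf per-locus risk (minor) allele frequency, used for
#'   prevalence calibration.
#' @param prevalence target population disease probability.
#' @param p_base optional explicit baseline penetrance; computed from
#'   `prevalence` via [calibrate_baseline()] when omitted.
#' @return An object of class `disease_model`.
#' @examples
#' disease_model(1:6, grr = c(1.34, 1.34, 1.34, 1.57, 1.57, 1.57),
#'               maf = c(0.25, 0.36, 0.33, 0.43, 0.31, 0.30),
#'               prevalence = 0.05)
#' @export
disease_model <- function(causal_index, grr, maf, prevalence = 0.05,
                          p_base = NULL) {
  if (length(grr) != length(causal_index) || length(maf) != length(causal_index))
    stop("causal_index, grr and maf must have equal length")
  if (any(grr < 1)) stop("grr must be >= 1")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (is.null(p_base))
    p_base <- calibrate_baseline(maf, grr, prevalence)
  if (p_base * prod(grr^2) > 1)
    stop("model misconfigured: maximum genotype penetrance exceeds 1")
  structure(list(causal_index = as.integer(causal_index), grr = grr,
                 maf = maf, prevalence = prevalence, p_base = p_base),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat("disease_model:", length(x$causal_index), "causal loci, prevalence",
      x$prevalence, ", p_base =", format(x$p_base, digits = 6), "\n")
  print(data.frame(index = x$causal_index, maf = x$maf, grr = x$grr))
  invisible(x)
}

#' Penetrance of a multi-locus genotype
#'
#' Returns `p_base * prod_j grr_j^x_j` for risk-allele counts `x`.
#'
#' @param x vector (or matrix, loci in columns) of risk-allele counts
#'   in \{0, 1, 2\} at the causal loci.
#' @param model a [disease_model()].
#' @return Disease probability (vector if `x` is a matrix).
#' @export
disease_prob <- function(x, model) {
  if (any(x < 0) || any(x > 2) || any(x != floor(x)))
    stop("risk-allele counts must be 0, 1 or 2")
  if (is.matrix(x)) {
    if (ncol(x) != length(model$grr)) stop("one column per causal locus")
    pr <- model$p_base * exp(x %*% log(model$grr))[, 1]
  } else {
    if (length(x) != length(model$grr)) stop("one count per causal locus")
    pr <- model$p_base * prod(model$grr^x)
  }
  if (any(pr > 1))
    stop("model misconfigured: penetrance exceeds 1")
  pr
}

#' Calibrate the baseline penetrance to a target prevalence
#'
#' Under Hardy-Weinberg equilibrium and inter-locus independence the
#' prevalence of the multiplicative model is
#' `p_base * prod_j E[grr_j^X_j]` with `X_j ~ Binomial(2, maf_j)`, and
#' `E[grr^X] = (1-f)^2 + 2f(1-f) grr + f^2 grr^2 = ((1-f) + f*grr)^2`.
#' This returns `p_base = prevalence / prod_j ((1-f_j) + f_j*grr_j)^2`.
#'
#' @param mafs per-locus risk-allele frequencies.
#' @param grrs per-locus genotypic relative risks.
#' @param prevalence target population disease probability.
#' @return The baseline penetrance `p_base`.
#' @examples
#' calibrate_baseline(0.5, 2, 0.05)  # 0.05 / 2.25
#' @export
calibrate_baseline <- function(mafs, grrs, prevalence) {
  if (length(mafs) != length(grrs)) stop("mafs and grrs must match")
  p_base <- prevalence / prod(((1 - mafs) + mafs * grrs)^2)
  if (p_base * prod(grrs^2) > 1)
    stop("calibration impossible: maximum genotype penetrance exceeds 1")
  p_base
}

#' Simulate a case-control genotype panel
#'
#' Rejection sampling from the population: individuals are drawn from
#' the haplotype model, assigned disease status with probability
#' [disease_prob()] at their causal genotypes, and kept until the case
#' and control quotas are both filled exactly.
#'
#' @param model a [haplotype_model()].
#' @param disease a [disease_model()] whose `causal_index` refers to
#'   columns of the genotype matrix.
#' @param n_cases,n_controls quotas (`>= 1` each).
#' @param seed integer seed.
#' @param batch individuals drawn per sampling round.
#' @param max_draws progress check: abort if quotas are not filled
#'   after this many population draws (pathologically small
#'   prevalence).
#' @return A list of class `case_control_data`: `genotypes`
#'   (`(n_cases + n_controls) x n_snps`), `phenotype` (1 = case, in
#'   order cases then controls), `truth` (data frame of causal
#'   chrom/pos), `model`, `disease`.
#' @export
simulate_case_control <- function(model, disease, n_cases, n_controls,
                                  seed = 1L, batch = 2000L,
                                  max_draws = NULL) {
  if (n_cases < 1 || n_controls < 1) stop("quotas must be >= 1")
  set.seed(as.integer(seed %% .Machine$integer.max))
  if (is.null(max_draws))
    max_draws <- ceiling(50 * (n_cases / disease$prevalence + n_controls))
  cases <- controls <- vector("list", 0L)
  n_case <- n_control <- 0L; drawn <- 0L
  while (n_case < n_cases || n_control < n_controls) {
    if (drawn >= max_draws)
      stop("case/control quotas not filled after ", drawn,
           " population draws; prevalence too small for the quotas?")
    g <- draw_genotypes(model, batch)
    drawn <- drawn + batch
    pr <- disease_prob(g[, disease$causal_index, drop = FALSE], disease)
    affected <- stats::runif(batch) < pr
    if (n_case < n_cases && any(affected)) {
      take <- utils::head(which(affected), n_cases - n_case)
      cases[[length(cases) + 1L]] <- g[take, , drop = FALSE]
      n_case <- n_case + length(take)
    }
    if (n_control < n_controls && any(!affected)) {
      take <- utils::head(which(!affected), n_controls - n_control)
      controls[[length(controls) + 1L]] <- g[take, , drop = FALSE]
      n_control <- n_control + length(take)
    }
  }
  genotypes <- rbind(do.call(rbind, cases), do.call(rbind, controls))
  structure(list(genotypes = genotypes,
                 phenotype = rep(c(1L, 0L), c(n_cases, n_controls)),
                 truth = data.frame(chrom = model$chrom[disease$causal_index],
                                    pos = model$pos[disease$causal_index]),
                 model = model, disease = disease),
            class = "case_control_data")
}

#' @export
print.case_control_data <- function(x, ...) {
  cat("case_control_data:", sum(x$phenotype == 1L), "cases,",
      sum(x$phenotype == 0L), "controls,", ncol(x$genotypes), "SNPs\n")
  invisible(x)
}
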