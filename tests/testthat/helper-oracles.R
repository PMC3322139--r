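# Independent oracles used to freeze expected values.

# Brute-force BH step-up: try every k from m down to 0 against the
# definition k = max{ i : p(i) <= i*q/m }; reject the k smallest
# (ties by value share a fate).
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- 0L
  for (i in m:1) {
    if (ps[i] <= i * q / m) { k <- i; break }
  }
  if (k == 0L) rep(FALSE, m) else p <= ps[k]
}

# Exhaustive HWE exact-test oracle: enumerate every genotype
# configuration compatible with the observed allele counts and compute
# conditional probabilities with plain factorials (safe for small n).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- 2 * n_aa + n_Aa
  if (n_minor == 0 || 2 * n - n_minor == 0) return(1)
  configs <- list()
  for (h in 0:n) {
    aa <- (n_minor - h) / 2
    AA <- n - h - aa
    if (aa >= 0 && AA >= 0 && aa == floor(aa))
      configs[[length(configs) + 1L]] <- c(AA = AA, h = h, aa = aa)
  }
  wt <- vapply(configs, function(cf)
    2^cf["h"] * factorial(n) /
      (factorial(cf["AA"]) * factorial(cf["h"]) * factorial(cf["aa"])),
    numeric(1))
  prob <- wt / sum(wt)
  obs <- prob[vapply(configs, function(cf) cf["h"] == n_Aa, logical(1))]
  sum(prob[prob <= obs + 1e-12])
}

# Conditional risk-allele frequency in cases/controls for a single
# causal locus, by enumeration over the three genotypes.
conditional_allele_freq <- function(maf, grr, prevalence) {
  p_base <- prevalence / ((1 - maf) + maf * grr)^2
  x <- 0:2
  px <- dbinom(x, 2, maf)
  pen <- p_base * grr^x
  p_case_x <- px * pen / sum(px * pen)
  p_ctrl_x <- px * (1 - pen) / sum(px * (1 - pen))
  c(case = sum(x * p_case_x) / 2, control = sum(x * p_ctrl_x) / 2)
}

random_pvec <- function(m) {
  p <- runif(m)
  # sprinkle ties and near-threshold values
  if (m >= 4 && runif(1) < 0.5) p[2] <- p[1]
  if (runif(1) < 0.3) p[m] <- 1
  p
}
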