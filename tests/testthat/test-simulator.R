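test_that("genotype draws recover allele frequencies and HWE", {
  maf <- c(0.05, 0.1, 0.25, 0.4, 0.5)
  model <- haplotype_model(maf, rho = 0)
  g <- draw_genotypes(model, 10000, seed = 21)
  n <- nrow(g)
  fhat <- colMeans(g) / 2
  se <- sqrt(maf * (1 - maf) / (2 * n))
  expect_true(all(abs(fhat - maf) < 3 * se))

  # genotype class frequencies near (q^2, 2pq, p^2)
  for (j in seq_along(maf)) {
    f <- maf[j]
    expected <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    observed <- tabulate(g[, j] + 1L, 3L) / n
    se_g <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(observed - expected) < 3 * se_g + 1e-12))
  }
})

test_that("LD decays with distance inside a block and vanishes at rho = 0", {
  maf <- rep(0.3, 10)
  g0 <- draw_genotypes(haplotype_model(maf, rho = 0), 8000, seed = 31)
  g9 <- draw_genotypes(haplotype_model(maf, rho = 0.9), 8000, seed = 31)
  c0 <- cor(g0[, 1], g0[, 2])
  expect_lt(abs(c0), 3 / sqrt(8000))
  adj <- cor(g9[, 1], g9[, 2])
  far <- cor(g9[, 1], g9[, 8])
  expect_gt(adj, 0.5)      # strong LD between neighbours
  expect_gt(adj, far)      # decaying with distance
  expect_gt(far, 0)
})

test_that("genotype correlation matches the latent-model value by Monte Carlo", {
  # adjacent SNPs, rho = 0.9, maf = 0.3: genotype correlation equals the
  # haplotype (tetrachoric-induced) allele correlation; oracle by direct
  # Monte-Carlo integration of the thresholded latent Gaussian
  set.seed(41)
  n <- 4e5
  z1 <- rnorm(n); z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(n)
  thr <- qnorm(0.3)
  oracle <- cor(z1 < thr, z2 < thr)
  g <- draw_genotypes(haplotype_model(rep(0.3, 2), rho = 0.9), 50000,
                      seed = 42)
  expect_lt(abs(cor(g[, 1], g[, 2]) - oracle), 0.02)
})

test_that("disease_prob is the multiplicative GRR penetrance", {
  dm <- disease_model(1:2, grr = c(1.34, 1.57), maf = c(0.25, 0.3),
                      prevalence = 0.05)
  expect_equal(disease_prob(c(0, 0), dm), dm$p_base)
  expect_equal(disease_prob(c(0, 2), dm), dm$p_base * 1.57^2)
  expect_equal(disease_prob(c(2, 1), dm), dm$p_base * 1.34^2 * 1.57)
  # matrix form agrees with scalar form
  x <- rbind(c(0, 0), c(1, 2), c(2, 2))
  expect_equal(disease_prob(x, dm),
               vapply(1:3, function(i) disease_prob(x[i, ], dm), numeric(1)))
  expect_error(disease_prob(c(3, 0), dm), "0, 1 or 2")

  flat <- disease_model(1:2, grr = c(1, 1), maf = c(0.25, 0.3),
                        prevalence = 0.05)
  expect_equal(disease_prob(c(2, 2), flat), 0.05)
})

test_that("baseline calibration has the closed form and recovers prevalence", {
  expect_equal(calibrate_baseline(0.5, 2, 0.05), 0.05 / 2.25)
  expect_equal(calibrate_baseline(c(0.2, 0.3), c(1, 1), 0.1), 0.1)

  # Monte-Carlo prevalence recovery for random configurations
  set.seed(51)
  for (i in 1:20) {
    repeat {
      L <- sample(1:4, 1)
      maf <- runif(L, 0.05, 0.5)
      grr <- runif(L, 1, 2)
      prev <- runif(1, 0.01, 0.2)
      if (prev * prod(grr)^2 <= 0.9) break  # feasible penetrance
    }
    p_base <- calibrate_baseline(maf, grr, prev)
    n <- 1e5
    x <- vapply(seq_len(L), function(j) rbinom(n, 2, maf[j]), numeric(n))
    pr <- p_base * exp(x %*% log(grr))[, 1]
    affected <- runif(n) < pr
    se <- sqrt(prev * (1 - prev) / n)
    expect_lt(abs(mean(affected) - prev), 3 * se)
  }
})

test_that("case-control sampling fills quotas and shifts case allele freq", {
  maf <- c(0.2, 0.3, 0.4)
  model <- haplotype_model(maf, chrom = c("1", "2", "3"), rho = 0)
  dm <- disease_model(2L, grr = 1.57, maf = 0.3, prevalence = 0.05)
  cc <- simulate_case_control(model, dm, 5000, 5000, seed = 71)
  expect_equal(sum(cc$phenotype == 1L), 5000L)
  expect_equal(sum(cc$phenotype == 0L), 5000L)
  expect_true(all(cc$genotypes %in% 0:2))

  f <- conditional_allele_freq(0.3, 1.57, 0.05)
  f_case <- mean(cc$genotypes[cc$phenotype == 1L, 2]) / 2
  f_ctrl <- mean(cc$genotypes[cc$phenotype == 0L, 2]) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 5000))
  expect_gt(f_case, f_ctrl)
  expect_lt(abs(f_case - f["case"]), 3 * se)
  expect_lt(abs(f_ctrl - f["control"]), 3 * se)

  # a null locus shows no shift beyond noise
  f1_diff <- mean(cc$genotypes[cc$phenotype == 1L, 1]) / 2 -
    mean(cc$genotypes[cc$phenotype == 0L, 1]) / 2
  expect_lt(abs(f1_diff), 4 * sqrt(2 * 0.2 * 0.8 / (2 * 5000)))

  expect_identical(simulate_case_control(model, dm, 50, 50, seed = 9)$genotypes,
                   simulate_case_control(model, dm, 50, 50, seed = 9)$genotypes)
})

test_that("per-allele odds ratio approaches the GRR at low prevalence", {
  model <- haplotype_model(0.3, rho = 0)
  dm <- disease_model(1L, grr = 1.57, maf = 0.3, prevalence = 0.001)
  cc <- simulate_case_control(model, dm, 30000, 30000, seed = 81,
                              batch = 100000L)
  g <- cc$genotypes[, 1]
  case <- g[cc$phenotype == 1L]; ctrl <- g[cc$phenotype == 0L]
  or <- (sum(case) * (2 * length(ctrl) - sum(ctrl))) /
    ((2 * length(case) - sum(case)) * sum(ctrl))
  expect_lt(abs(or - 1.57) / 1.57, 0.02)
})

test_that("pathologically small prevalence aborts with a progress error", {
  model <- haplotype_model(0.3, rho = 0)
  dm <- disease_model(1L, grr = 1.1, maf = 0.3, prevalence = 1e-4,
                      p_base = 1e-7)
  expect_error(simulate_case_control(model, dm, 100, 10, seed = 1,
                                     batch = 500L, max_draws = 2000L),
               "quotas not filled")
})

test_that("stat panels are reproducible with independent replicate streams", {
  cfg <- stat_panel_config(markers = marker_map(n_chrom = 4L,
                                                snps_per_chrom = 300L),
                           cluster_chrom = c("1", "3"), mu = c(5, 6))
  a <- simulate_stat_panel(cfg, 1, 99)
  b <- simulate_stat_panel(cfg, 1, 99)
  expect_identical(a$z, b$z)
  expect_false(identical(a$z, simulate_stat_panel(cfg, 2, 99)$z))
  expect_false(identical(a$z, simulate_stat_panel(cfg, 1, 100)$z))
  expect_equal(length(a$p), 1200L)
  expect_true(all(a$p >= 0 & a$p <= 1))
})

test_that("all-null stat panels give uniform p-values", {
  cfg <- stat_panel_config(markers = marker_map(n_chrom = 2L,
                                                snps_per_chrom = 1000L),
                           cluster_chrom = character(0), mu = numeric(0),
                           rho = 0)
  p <- unlist(lapply(1:50, function(i) simulate_stat_panel(cfg, i, 7)$p))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(p)))  # 1% critical value
})

test_that("null z-scores carry the configured AR(1) block correlation", {
  cfg <- stat_panel_config(markers = marker_map(n_chrom = 1L,
                                                snps_per_chrom = 1000L),
                           cluster_chrom = character(0), mu = numeric(0),
                           rho = 0.8, block_size = 50L)
  z <- vapply(1:300, function(i) simulate_stat_panel(cfg, i, 5)$z,
              numeric(1000))
  # correlation across replicates between positions inside one block
  expect_lt(abs(cor(z[2, ], z[3, ]) - 0.8), 0.1)
  expect_lt(abs(cor(z[2, ], z[4, ]) - 0.64), 0.1)
  # block boundary (SNPs 50 and 51 are in different blocks)
  expect_lt(abs(cor(z[50, ], z[51, ])), 0.2)
})

test_that("lead rejection probability matches the normal-shift closed form", {
  cfg <- stat_panel_config(markers = marker_map(n_chrom = 1L,
                                                snps_per_chrom = 200L),
                           cluster_chrom = "1", mu = 5.2, cluster_size = 1L)
  alpha <- 1e-4
  reps <- 2000L
  lead <- cfg$lead_idx[1]
  hit <- vapply(seq_len(reps), function(i)
    simulate_stat_panel(cfg, i, 13)$p[lead] <= alpha, logical(1))
  z_a <- qnorm(1 - alpha / 2)
  closed <- pnorm(5.2 - z_a) + pnorm(-5.2 - z_a)
  se <- sqrt(closed * (1 - closed) / reps)
  expect_lt(abs(mean(hit) - closed), 3 * se)
})

test_that("independent tests give BH realized FDR near q * pi0", {
  cfg <- stat_panel_config(markers = marker_map(n_chrom = 2L,
                                                snps_per_chrom = 500L),
                           cluster_chrom = c("1", "2"), mu = c(6, 6),
                           cluster_size = 1L, rho = 0)
  truth <- cfg$clusters
  reps <- 500L
  fdp <- vapply(seq_len(reps), function(i) {
    panel <- simulate_stat_panel(cfg, i, 17)
    realized_fdr(bh_adjust(panel$p, 0.05), truth, cfg$markers,
                 window_bp = 0)
  }, numeric(1))
  se <- sd(fdp) / sqrt(reps)
  expect_lt(mean(fdp), 0.05 + 3 * se)
  expect_gt(mean(fdp), 0.01)  # BH does reject and some rejections are false
})
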