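test_that("bh_adjust matches the step-up definition on worked cases", {
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(r$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$threshold, 0.03)
  expect_equal(r$n_rejected, 3L)

  expect_equal(bh_adjust(c(0.9, 0.8), q = 0.05)$n_rejected, 0L)
  expect_true(all(bh_adjust(c(0, 0, 0), q = 0.01)$rejected))
})

test_that("bh_adjust agrees with the brute-force oracle on random vectors", {
  set.seed(101)
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- random_pvec(m)
    q <- runif(1, 0.01, 0.2)
    expect_identical(bh_adjust(p, q)$rejected, bh_oracle(p, q))
  }
})

test_that("adjustment procedures validate their inputs", {
  expect_error(bh_adjust(numeric(0)), "no tests")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, 0.1), q = 0), "\\(0, 1\\)")
  expect_error(weighted_bh_adjust(c(0.1, 0.2), c(1.5, 1.5)), "mean-one")
  expect_error(weighted_bh_adjust(c(0.1, 0.2), c(2, 0)), "positive")
  expect_error(psa_adjust(c(0.1, 0.2), U = c(1, 2)), "binary")
})

test_that("bonferroni rejects at the alpha/m threshold, inclusively", {
  r <- bonferroni_adjust(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(r$rejected, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$threshold, 0.0125)
  expect_true(bonferroni_adjust(0.05, alpha = 0.05)$rejected)
})

test_that("bonferroni family-wise error rate matches theory by Monte Carlo", {
  set.seed(202)
  m <- 1000L; reps <- 10000L; alpha <- 0.05
  any_rej <- logical(reps)
  for (i in seq_len(reps))
    any_rej[i] <- bonferroni_adjust(runif(m), alpha)$n_rejected > 0
  fwer_theory <- 1 - (1 - alpha / m)^m  # 0.04877...
  se <- sqrt(fwer_theory * (1 - fwer_theory) / reps)
  expect_lt(abs(mean(any_rej) - fwer_theory), 3 * se)
})

test_that("holm steps down correctly and dominates bonferroni", {
  # 0.02 <= 0.05/2 and 0.04 <= 0.05/1: the walk continues to the end
  expect_equal(holm_adjust(c(0.001, 0.02, 0.04), 0.05)$rejected, rep(TRUE, 3))
  # 0.03 > 0.05/2 stops the walk; 0.04 <= 0.05 alone is not enough
  r <- holm_adjust(c(0.001, 0.03, 0.04), alpha = 0.05)
  expect_equal(r$rejected, c(TRUE, FALSE, FALSE))
  expect_equal(holm_adjust(rep(1, 5), alpha = 0.05)$n_rejected, 0L)

  set.seed(303)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    alpha <- runif(1, 0.01, 0.2)
    h <- holm_adjust(p, alpha)$rejected
    b <- bonferroni_adjust(p, alpha)$rejected
    expect_true(all(h[b]))
  }
})

test_that("weighted BH reproduces the hand-computed binary-weight case", {
  w <- binary_weights(prior_allocation(c(1, 0, 0, 0)), r = 3)
  r <- weighted_bh_adjust(c(0.04, 0.01, 0.5, 0.9), w, q = 0.05)
  expect_equal(r$weighted_p, c(0.02, 0.015, 0.75, 1.35))
  expect_equal(r$rejected, c(TRUE, TRUE, FALSE, FALSE))
  # brute-force BH on the weighted p-values agrees
  expect_identical(r$rejected, bh_oracle(r$weighted_p, 0.05))
})

test_that("weighted BH with unit weights is identical to plain BH", {
  set.seed(404)
  for (i in 1:50) {
    p <- runif(sample(2:200, 1))
    q <- runif(1, 0.01, 0.2)
    a <- bh_adjust(p, q); b <- weighted_bh_adjust(p, rep(1, length(p)), q)
    expect_identical(a$rejected, b$rejected)
    expect_identical(a$threshold, b$threshold)
  }
})

test_that("weighted p-values above 1 are kept unclamped and never rejected", {
  w <- c(2, 2 / 3, 2 / 3, 2 / 3)
  r <- weighted_bh_adjust(c(0.001, 0.9, 0.95, 0.99), w, q = 0.2)
  expect_true(any(r$weighted_p > 1))
  expect_false(any(r$rejected[r$weighted_p > 1]))
})

test_that("raising the level never removes weighted-BH rejections", {
  set.seed(505)
  for (i in 1:50) {
    m <- sample(3:50, 1)
    p <- runif(m)
    w <- runif(m, 0.2, 2); w <- w / mean(w)
    lo <- weighted_bh_adjust(p, w, q = 0.02)$rejected
    hi <- weighted_bh_adjust(p, w, q = 0.1)$rejected
    expect_true(all(hi[lo]))
  }
})

test_that("renormalization of off-constraint weights is explicit only", {
  p <- c(0.01, 0.5)
  expect_error(weighted_bh_adjust(p, c(2, 1)), "mean-one")
  r <- weighted_bh_adjust(p, c(2, 1), renormalize = TRUE)
  expect_equal(r$weighted_p, p / (c(2, 1) / 1.5))
})

test_that("PSA runs BH within each subset and unions the rejections", {
  # power-gain mechanism: a 0.04 p-value passes in a singleton subset
  # but fails genome-wide BH
  p <- c(0.04, 0.2, 0.3, 0.4)
  psa <- psa_adjust(p, U = c(1, 0, 0, 0), q = 0.05)
  expect_equal(psa$rejected, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(psa$threshold["prioritized"]), 0.04)
  expect_equal(bh_adjust(p, q = 0.05)$n_rejected, 0L)
  expect_equal(psa$subset, c("prioritized", rep("non_prioritized", 3)))

  # oracle per subset on a random case
  set.seed(606)
  p <- runif(50); U <- rbinom(50, 1, 0.3)
  r <- psa_adjust(p, U, q = 0.1)
  expect_identical(r$rejected[U == 1], bh_oracle(p[U == 1], 0.1))
  expect_identical(r$rejected[U == 0], bh_oracle(p[U == 0], 0.1))
})

test_that("PSA with an empty prioritized subset degenerates to plain BH", {
  set.seed(707)
  p <- runif(40)
  expect_identical(psa_adjust(p, rep(0L, 40), q = 0.05)$rejected,
                   bh_adjust(p, 0.05)$rejected)
  expect_identical(psa_adjust(p, rep(1L, 40), q = 0.05)$rejected,
                   bh_adjust(p, 0.05)$rejected)
})

test_that("PSA all-null prioritized rejection probability is near the level", {
  set.seed(808)
  m1 <- 1000L; m0 <- 9000L; q <- 0.05; reps <- 2000L
  hit <- logical(reps)
  U <- rep(c(1L, 0L), c(m1, m0))
  for (i in seq_len(reps)) {
    r <- psa_adjust(runif(m1 + m0), U, q)
    hit[i] <- any(r$rejected[seq_len(m1)])
  }
  se <- sqrt(q * (1 - q) / reps)
  expect_lt(abs(mean(hit) - q), 3 * se)
})

test_that("all-null Monte-Carlo realized FDR of BH stays at or below q", {
  set.seed(909)
  m <- 2000L; q <- 0.05; reps <- 10000L
  fdp <- numeric(reps)
  for (i in seq_len(reps)) {
    r <- bh_adjust(runif(m), q)
    fdp[i] <- if (r$n_rejected > 0) 1 else 0  # all rejections are false
  }
  se <- sd(fdp) / sqrt(reps)
  expect_lte(mean(fdp), q + 3 * se)
})

test_that("rejection sets are invariant to input ordering", {
  set.seed(111)
  for (i in 1:30) {
    m <- sample(5:100, 1)
    p <- runif(m)^2
    U <- rbinom(m, 1, 0.3)
    w <- binary_weights(prior_allocation(U), r = 5)$w
    perm <- sample.int(m)
    for (fit in list(
      function(pp) bh_adjust(pp, 0.1)$rejected,
      function(pp) holm_adjust(pp, 0.1)$rejected)) {
      expect_identical(fit(p), fit(p[perm])[order(perm)])
    }
    expect_identical(weighted_bh_adjust(p, w, 0.1)$rejected,
                     weighted_bh_adjust(p[perm], w[perm], 0.1)$rejected[order(perm)])
    expect_identical(psa_adjust(p, U, 0.1)$rejected,
                     psa_adjust(p[perm], U[perm], 0.1)$rejected[order(perm)])
  }
})

test_that("fdr_adjust dispatches to every procedure and prints", {
  p <- pvalue_set(paste0("rs", 1:4), "1", 1:4 * 1000L,
                  c(0.001, 0.02, 0.2, 0.9))
  for (m in c("wga", "bonferroni", "holm")) {
    r <- fdr_adjust(p, method = m, q = 0.05)
    expect_s3_class(r, "fdr_adjustment")
    expect_equal(r$method, m)
  }
  r <- fdr_adjust(p, method = "wei", prioritized = c(1, 0, 0, 0), r = 2)
  expect_equal(r$method, "wei")
  r <- fdr_adjust(p, method = "psa", prioritized = c(1, 0, 0, 0))
  expect_equal(r$method, "psa")
  expect_output(print(r), "prioritized subset analysis")
  expect_named(summary(r), c("method", "level", "m", "n_rejected",
                             "threshold", "by_subset"))
  df <- as.data.frame(r)
  expect_equal(nrow(df), 4L)
})
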