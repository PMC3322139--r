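#' SNPs within a window of any causal locus
#'
#' Truth rule for Monte-Carlo FDR evaluation: a rejected SNP counts as
#' a true rejection iff it lies within `window_bp` of some causal locus
#' on the same chromosome (the same 1 Mb window used for locus-level
#' power). The window is configurable because null status of SNPs in
#' LD with a causal locus is a convention, not an observable.
#'
#' @param markers data frame with `chrom`, `pos`.
#' @param truth causal loci: data frame with `chrom`, `pos`.
#' @param window_bp window half-width in bp.
#' @return Logical vector, `TRUE` for SNPs near a causal locus.
#' @export
truth_mask <- function(markers, truth, window_bp = 1e6) {
  if (window_bp < 0) stop("window_bp must be non-negative")
  mask <- logical(nrow(markers))
  for (j in seq_len(nrow(truth))) {
    mask <- mask | (markers$chrom == as.character(truth$chrom[j]) &
                      abs(markers$pos - truth$pos[j]) <= window_bp)
  }
  mask
}

#' Realized false discovery proportion of a rejection set
#'
#' Computes `V/R`: the number of false rejections (rejected SNPs
#' farther than `window_bp` from every causal locus) over the total
#' number of rejections, with the convention `0/0 = 0`.
#'
#' @param rejected logical rejection flags, one per SNP (or an
#'   `fdr_adjustment` object).
#' @param truth causal loci: data frame with `chrom`, `pos`.
#' @param markers data frame with `chrom`, `pos`, aligned with
#'   `rejected`.
#' @param window_bp truth window in bp.
#' @return The realized FDP in \[0, 1\].
#' @export
realized_fdr <- function(rejected, truth, markers, window_bp = 1e6) {
  if (inherits(rejected, "fdr_adjustment")) rejected <- rejected$rejected
  R <- sum(rejected)
  if (R == 0) return(0)
  V <- sum(rejected & !truth_mask(markers, truth, window_bp))
  V / R
}

#' Overall FDR of a prioritized subset analysis
#'
#' Pools the rejections of the prioritized and the non-prioritized
#' subsets before forming `V/R` (0/0 = 0). Because PSA applies BH
#' within each subset separately, this pooled quantity is exactly the
#' realized FDP of the union rejection set — the quantity whose
#' expectation is *not* guaranteed to stay below the nominal level when
#' the prioritization is uninformative.
#'
#' @param result an `fdr_adjustment` with `method == "psa"`.
#' @inheritParams realized_fdr
#' @return The pooled realized FDP.
#' @export
overall_psa_fdr <- function(result, truth, markers, window_bp = 1e6) {
  if (!inherits(result, "fdr_adjustment") || result$method != "psa")
    stop("'result' must come from psa_adjust()")
  realized_fdr(result$rejected, truth, markers, window_bp)
}

#' Locus-level detection flags
#'
#' A causal locus is detected when at least one SNP within `window_bp`
#' of it (same chromosome) is declared significant.
#'
#' @inheritParams realized_fdr
#' @return Logical vector, one flag per causal locus.
#' @export
locus_power <- function(rejected, truth, markers, window_bp = 1e6) {
  if (inherits(rejected, "fdr_adjustment")) rejected <- rejected$rejected
  vapply(seq_len(nrow(truth)), function(j) {
    near <- markers$chrom == as.character(truth$chrom[j]) &
      abs(markers$pos - truth$pos[j]) <= window_bp
    any(rejected[near])
  }, logical(1))
}

#' Permutation-based FDR estimate
#'
#' Estimates the FDR of a declared signal set from permutation null
#' p-values: with `R` declared signals whose largest p-value is
#' `threshold`, and a `B x m` matrix of null p-values, the estimated
#' number of false positives is the count of null p-values at or below
#' `threshold` divided by `B`, and the estimate is that count over `R`.
#'
#' @param R number of declared signals (>= 1).
#' @param threshold largest p-value among the declared signals.
#' @param null_pvalues `B x m` matrix from
#'   [permutation_null_pvalues()].
#' @return Estimated FDR.
#' @export
permutation_fdr_estimate <- function(R, threshold, null_pvalues) {
  if (R < 1) stop("permutation FDR estimate undefined for R = 0")
  B <- nrow(null_pvalues)
  (sum(null_pvalues <= threshold) / B) / R
}

#' Monte-Carlo FDR and power study over prioritization scenarios
#'
#' The package's evaluation harness: simulates `n_replicates`
#' statistic-level GWAS panels, and for each replicate applies every
#' requested adjustment method under every prioritization scenario,
#' recording the realized false discovery proportion and per-locus
#' detection flags. All methods and scenarios see the *same* simulated
#' panels (paired replicates), which sharpens method contrasts.
#'
#' @param config a [stat_panel_config()]; its `clusters` table is the
#'   causal truth.
#' @param scenarios named list of scenario specs, each a list with
#'   `n_regions`, `region_size_bp` and `covered` (a scenario label like
#'   `"i"`/`"viii"` or an integer vector of covered loci), or directly
#'   a [region_set()].
#' @param methods named list of method specs: `list(method = "wga")`,
#'   `list(method = "wei", r = 5)`, `list(method = "psa")`, optionally
#'   with a `q` entry overriding the study level (e.g. the PSA run at a
#'   lowered per-subset level 0.044).
#' @param n_replicates number of Monte-Carlo replicates.
#' @param seed master seed; panels use replicate streams
#'   `1..n_replicates`, decoy placement its own stream.
#' @param q nominal control level.
#' @param window_bp truth/power window.
#' @return An object of class `scenario_study`: per-combination
#'   replicate FDP matrix (`fdp`), per-combination power flag arrays
#'   (`power`), the combination table (`combos`), scenario region sets
#'   and allocations, and `n_replicates`. Use `summary()` for the
#'   aggregated table.
#' @export
run_scenario_study <- function(config, scenarios, methods,
                               n_replicates = 100L, seed = 1L, q = 0.05,
                               window_bp = 1e6) {
  markers <- config$markers
  truth <- config$clusters
  is_true <- truth_mask(markers, truth, window_bp)
  window_idx <- lapply(seq_len(nrow(truth)), function(j)
    which(markers$chrom == as.character(truth$chrom[j]) &
            abs(markers$pos - truth$pos[j]) <= window_bp))

  # resolve scenarios to region sets and allocations
  region_sets <- list(); alloc <- list()
  for (s in names(scenarios)) {
    sc <- scenarios[[s]]
    regions <- if (inherits(sc, "region_set") || is.data.frame(sc)) sc
    else build_scenario(markers, truth, sc$n_regions, sc$region_size_bp,
                        sc$covered, seed = derive_seed(seed, 900000L +
                                                        match(s, names(scenarios))))
    region_sets[[s]] <- regions
    alloc[[s]] <- allocate_snps(markers, regions, flank_bp = 0)
  }

  combos <- expand.grid(scenario = names(scenarios), method = names(methods),
                        stringsAsFactors = FALSE)
  n_combo <- nrow(combos)
  weights <- vector("list", n_combo)
  for (k in seq_len(n_combo)) {
    spec <- methods[[combos$method[k]]]
    if (spec$method == "wei")
      weights[[k]] <- binary_weights(alloc[[combos$scenario[k]]], spec$r)$w
  }

  fdp <- matrix(NA_real_, n_replicates, n_combo)
  n_rej <- matrix(NA_integer_, n_replicates, n_combo)
  power <- lapply(seq_len(n_combo), function(k)
    matrix(NA, n_replicates, nrow(truth)))

  for (i in seq_len(n_replicates)) {
    p <- simulate_stat_panel(config, i, seed)$p
    for (k in seq_len(n_combo)) {
      spec <- methods[[combos$method[k]]]
      level <- if (!is.null(spec$q)) spec$q else q
      rej <- switch(spec$method,
        wga = bh_core(p, level)$rejected,
        wei = bh_core(p / weights[[k]], level)$rejected,
        psa = {
          U <- alloc[[combos$scenario[k]]]$U
          r <- logical(length(p))
          pri <- U == 1L
          if (any(pri)) r[pri] <- bh_core(p[pri], level)$rejected
          if (any(!pri)) r[!pri] <- bh_core(p[!pri], level)$rejected
          r
        },
        stop("unknown method: ", spec$method))
      R <- sum(rej)
      n_rej[i, k] <- R
      fdp[i, k] <- if (R > 0) sum(rej & !is_true) / R else 0
      power[[k]][i, ] <- vapply(window_idx, function(idx) any(rej[idx]),
                                logical(1))
    }
  }
  structure(list(fdp = fdp, n_rejected = n_rej, power = power,
                 combos = combos, methods = methods,
                 region_sets = region_sets, allocations = alloc,
                 config = config, q = q, window_bp = window_bp,
                 n_replicates = n_replicates, seed = seed),
            class = "scenario_study")
}

#' @export
summary.scenario_study <- function(object, ...) {
  combos <- object$combos
  n <- object$n_replicates
  out <- data.frame(combos,
                    r = vapply(combos$method, function(mn) {
                      spec <- object$methods[[mn]]
                      if (!is.null(spec$r)) spec$r else NA_real_
                    }, numeric(1)),
                    q = vapply(combos$method, function(mn) {
                      spec <- object$methods[[mn]]
                      if (!is.null(spec$q)) spec$q else object$q
                    }, numeric(1)),
                    fdr_mean = colMeans(object$fdp),
                    fdr_se = apply(object$fdp, 2, stats::sd) / sqrt(n),
                    mean_rejections = colMeans(object$n_rejected),
                    n_replicates = n,
                    stringsAsFactors = FALSE)
  pw <- t(vapply(object$power, colMeans,
                 numeric(nrow(object$config$clusters))))
  colnames(pw) <- paste0("power_locus", seq_len(ncol(pw)))
  cbind(out, pw)
}

#' @export
print.scenario_study <- function(x, ...) {
  cat("scenario_study:", x$n_replicates, "replicates x",
      nrow(x$combos), "scenario/method combinations (q =", x$q, ")\n")
  print(summary(x), digits = 4)
  invisible(x)
}
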