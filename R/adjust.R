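#' Multiple-testing adjustment for GWAS p-values
#'
#' `fdr_adjust()` is the front door to the package's multiple-testing
#' procedures. Given raw per-SNP p-values it returns the rejection set of
#' one of five procedures:
#'
#' \describe{
#'   \item{`wga`}{whole-genome single-step FDR adjustment: the
#'     Benjamini-Hochberg (BH) step-up procedure applied once to all
#'     p-values at level `q`.}
#'   \item{`bonferroni`}{Bonferroni FWER control: reject `p <= q/m`.}
#'   \item{`holm`}{Holm's step-down FWER control.}
#'   \item{`wei`}{weighted FDR control: p-values are divided by positive
#'     weights with mean one, then BH is applied to the weighted
#'     p-values. Binary weights derived from a prioritization indicator
#'     and a confidence ratio `r` are the common case (see
#'     [binary_weights()]); arbitrary mean-one weight vectors are also
#'     accepted.}
#'   \item{`psa`}{prioritized subset analysis: BH applied separately, at
#'     the same nominal level, to the prioritized subset (`U == 1`) and
#'     to the non-prioritized subset (`U == 0`); the rejection set is the
#'     union.}
#' }
#'
#' All procedures use inclusive boundary comparisons (`p[(i)] <= i*q/m`),
#' and tied p-values share a common fate: if any copy of a value is
#' rejected, all its duplicates are.
#'
#' @param p numeric vector of raw p-values in \[0, 1\], or a
#'   [pvalue_set()].
#' @param method one of `"wga"`, `"bonferroni"`, `"holm"`, `"wei"`,
#'   `"psa"`.
#' @param q nominal control level in (0, 1): FDR level for
#'   `wga`/`wei`/`psa`, FWER level for `bonferroni`/`holm`.
#' @param weights for `method = "wei"`: positive weight vector with
#'   mean one (tolerance `1e-9` relative), or a [binary_weights()]
#'   scheme.
#' @param prioritized for `method = "psa"` (and for `"wei"` together with
#'   `r`): binary 0/1 indicator, `1` marking prioritized SNPs, or a
#'   [prior_allocation()].
#' @param r for `method = "wei"` with `prioritized` given: ratio of the
#'   prioritized to the non-prioritized weight (see [binary_weights()]).
#' @param q_prioritized,q_non_prioritized optional per-subset levels for
#'   `method = "psa"`, defaulting to `q`. Lowering both to 0.044 is the
#'   adjustment that restores overall 5% FDR control when the
#'   prioritization may be uninformative.
#' @param renormalize if `TRUE`, a weight vector failing the mean-one
#'   constraint is rescaled to mean one instead of raising an error.
#'   Never done silently.
#' @return An object of class `fdr_adjustment`: a list with elements
#'   `method`, `level`, `rejected` (logical, input order), `weighted_p`
#'   (equals `p` except for `wei`), `subset` (per-SNP label,
#'   `"prioritized"`/`"non_prioritized"` for `psa`, `"all"` otherwise),
#'   `threshold` (realized rejection threshold(s) on the (weighted)
#'   p-value scale; per subset for `psa`; `NA` if nothing is rejected)
#'   and `n_rejected`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.5), method = "wga", q = 0.05)
#' fdr_adjust(c(0.04, 0.2, 0.3, 0.4), method = "psa",
#'            prioritized = c(1, 0, 0, 0), q = 0.05)
#' @seealso [bh_adjust()], [weighted_bh_adjust()], [psa_adjust()],
#'   [binary_weights()], [allocate_snps()]
#' @export
fdr_adjust <- function(p, method = c("wga", "bonferroni", "holm", "wei", "psa"),
                       q = 0.05, weights = NULL, prioritized = NULL, r = NULL,
                       q_prioritized = q, q_non_prioritized = q,
                       renormalize = FALSE) {
  method <- match.arg(method)
  pv <- extract_p(p)
  switch(method,
    wga = bh_adjust(pv, q),
    bonferroni = bonferroni_adjust(pv, q),
    holm = holm_adjust(pv, q),
    wei = {
      if (is.null(weights)) {
        if (is.null(prioritized) || is.null(r))
          stop("method 'wei' needs either 'weights' or both 'prioritized' and 'r'")
        weights <- binary_weights(as_allocation(prioritized), r)
      }
      weighted_bh_adjust(pv, weights, q, renormalize = renormalize)
    },
    psa = {
      if (is.null(prioritized))
        stop("method 'psa' needs a 'prioritized' indicator")
      psa_adjust(pv, as_allocation(prioritized)$U, q,
                 q_prioritized = q_prioritized,
                 q_non_prioritized = q_non_prioritized)
    })
}

extract_p <- function(p) {
  if (inherits(p, "pvalue_set")) p$p else as.numeric(p)
}

# BH step-up core: k = max{ i : p(i) <= i*q/m }, reject the k smallest.
# Returns rejections in input order plus the realized threshold.
bh_core <- function(p, q) {
  m <- length(p)
  ps <- sort.int(p, method = "quick")
  ok <- ps <= q * seq_len(m) / m
  k <- if (any(ok)) max(which(ok)) else 0L
  if (k == 0L) {
    list(rejected = rep(FALSE, m), threshold = NA_real_)
  } else {
    thr <- ps[k]
    list(rejected = p <= thr, threshold = thr)
  }
}

new_adjustment <- function(method, level, p, rejected, threshold,
                           weighted_p = p, subset = rep("all", length(p))) {
  structure(list(method = method, level = level, p = p,
                 weighted_p = weighted_p, rejected = rejected,
                 subset = subset, threshold = threshold,
                 n_rejected = sum(rejected), m = length(p)),
            class = "fdr_adjustment")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Rejects the `k` smallest p-values where
#' `k = max{ i : p[(i)] <= i*q/m }` (`p[(i)]` the i-th order statistic),
#' controlling the FDR at level `q` under independence or positive
#' regression dependence. Boundary comparisons are inclusive and ties
#' share a common fate.
#'
#' @inheritParams fdr_adjust
#' @return An `fdr_adjustment` object (see [fdr_adjust()]).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.5), q = 0.05)$rejected
#' @export
bh_adjust <- function(p, q = 0.05) {
  p <- extract_p(p); check_pvalues(p); check_level(q)
  res <- bh_core(p, q)
  new_adjustment("wga", q, p, res$rejected, res$threshold)
}

#' Bonferroni adjustment
#'
#' Rejects `p_i <= alpha/m`, controlling the family-wise error rate.
#'
#' @param p numeric vector of raw p-values, or a [pvalue_set()].
#' @param alpha nominal FWER level in (0, 1).
#' @return An `fdr_adjustment` object.
#' @export
bonferroni_adjust <- function(p, alpha = 0.05) {
  p <- extract_p(p); check_pvalues(p); check_level(alpha, "alpha")
  thr <- alpha / length(p)
  rejected <- p <= thr
  new_adjustment("bonferroni", alpha, p, rejected,
                 if (any(rejected)) thr else NA_real_)
}

#' Holm step-down adjustment
#'
#' Step-down FWER control: walking up the sorted p-values, reject while
#' `p[(i)] <= alpha/(m - i + 1)` and stop at the first failure. Rejects
#' at least as much as Bonferroni at the same level.
#'
#' @inheritParams bonferroni_adjust
#' @return An `fdr_adjustment` object.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  p <- extract_p(p); check_pvalues(p); check_level(alpha, "alpha")
  m <- length(p)
  ps <- sort.int(p, method = "quick")
  ok <- ps <= alpha / (m - seq_len(m) + 1)
  k <- if (ok[1]) {
    fail <- which(!ok)
    if (length(fail) == 0L) m else fail[1] - 1L
  } else 0L
  if (k == 0L) {
    new_adjustment("holm", alpha, p, rep(FALSE, m), NA_real_)
  } else {
    thr <- ps[k]
    new_adjustment("holm", alpha, p, p <= thr, thr)
  }
}

#' Weighted Benjamini-Hochberg adjustment
#'
#' Divides each p-value by its weight (`w > 0`, `mean(w) = 1`) and
#' applies the BH step-up procedure to the weighted p-values
#' `p/w` at level `q`. The mean-one constraint is what preserves FDR
#' control; violating weight vectors raise an error unless
#' `renormalize = TRUE`. Weighted p-values above 1 are kept as-is (they
#' can simply never be rejected; clamping would not change any
#' decision).
#'
#' With all weights equal to 1 this reduces exactly to [bh_adjust()].
#'
#' @inheritParams fdr_adjust
#' @param w positive weight vector with mean 1 (relative tolerance
#'   `1e-9`), or a [binary_weights()] scheme.
#' @return An `fdr_adjustment` object with `weighted_p = p/w`.
#' @examples
#' w <- binary_weights(prior_allocation(c(1, 0, 0, 0)), r = 3)
#' weighted_bh_adjust(c(0.04, 0.01, 0.5, 0.9), w, q = 0.05)
#' @export
weighted_bh_adjust <- function(p, w, q = 0.05, renormalize = FALSE) {
  p <- extract_p(p); check_pvalues(p); check_level(q)
  if (inherits(w, "weight_scheme")) w <- w$w
  w <- as.numeric(w)
  if (length(w) != length(p))
    stop("'w' must have one weight per p-value")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("all weights must be strictly positive")
  if (abs(mean(w) - 1) > 1e-9) {
    if (renormalize) w <- w / mean(w)
    else stop("weights must satisfy the mean-one constraint mean(w) = 1 ",
              "(got mean ", format(mean(w), digits = 12),
              "); pass renormalize = TRUE to rescale explicitly")
  }
  pw <- p / w
  res <- bh_core(pw, q)
  new_adjustment("wei", q, p, res$rejected, res$threshold, weighted_p = pw)
}

#' Prioritized subset analysis (PSA)
#'
#' Splits the tests into a prioritized subset (`U == 1`) and a
#' non-prioritized subset (`U == 0`) and applies the BH procedure
#' independently within each subset, by default at the same nominal
#' level. The combined rejection set is the union. An empty subset is
#' legal: the result then equals plain BH on the other subset.
#'
#' Because BH runs separately in each subset, the FDR is controlled
#' within each subset but the overall (pooled) FDR carries no guarantee;
#' see [overall_psa_fdr()].
#'
#' @inheritParams fdr_adjust
#' @param U binary 0/1 vector, `1` marking the prioritized subset.
#' @return An `fdr_adjustment` object; `subset` labels each SNP
#'   `"prioritized"` or `"non_prioritized"`, and `threshold` is a named
#'   vector with one realized threshold per non-empty subset.
#' @examples
#' psa_adjust(c(0.04, 0.2, 0.3, 0.4), U = c(1, 0, 0, 0), q = 0.05)
#' @export
psa_adjust <- function(p, U, q = 0.05, q_prioritized = q,
                       q_non_prioritized = q) {
  p <- extract_p(p); check_pvalues(p); check_level(q)
  check_level(q_prioritized, "q_prioritized")
  check_level(q_non_prioritized, "q_non_prioritized")
  U <- check_indicator(U, length(p))
  pri <- U == 1L
  rejected <- logical(length(p))
  thr <- c(prioritized = NA_real_, non_prioritized = NA_real_)
  if (any(pri)) {
    res1 <- bh_core(p[pri], q_prioritized)
    rejected[pri] <- res1$rejected
    thr["prioritized"] <- res1$threshold
  }
  if (any(!pri)) {
    res0 <- bh_core(p[!pri], q_non_prioritized)
    rejected[!pri] <- res0$rejected
    thr["non_prioritized"] <- res0$threshold
  }
  new_adjustment("psa", q, p, rejected, thr,
                 subset = ifelse(pri, "prioritized", "non_prioritized"))
}

check_indicator <- function(U, m) {
  U <- as.integer(U)
  if (length(U) != m)
    stop("'U' must have the same length as 'p'")
  if (any(is.na(U)) || !all(U %in% c(0L, 1L)))
    stop("'U' must be a binary 0/1 indicator")
  U
}

#' @export
print.fdr_adjustment <- function(x, ...) {
  label <- c(wga = "whole-genome BH (WGA)", bonferroni = "Bonferroni",
             holm = "Holm step-down", wei = "weighted BH (WEI)",
             psa = "prioritized subset analysis (PSA)")[x$method]
  cat(label, "at level", x$level, "\n")
  cat("  m =", x$m, "tests;", x$n_rejected, "rejected\n")
  if (x$method == "psa") {
    cat("  prioritized subset: m1 =", sum(x$subset == "prioritized"),
        "(", sum(x$rejected[x$subset == "prioritized"]), "rejected )\n")
    cat("  thresholds:",
        paste(names(x$threshold), format(x$threshold, digits = 4),
              sep = " = ", collapse = ", "), "\n")
  } else if (!is.na(x$threshold[1])) {
    cat("  realized threshold:", format(x$threshold[1], digits = 4),
        if (x$method == "wei") "(weighted p scale)" else "", "\n")
  }
  invisible(x)
}

#' @export
summary.fdr_adjustment <- function(object, ...) {
  out <- list(method = object$method, level = object$level, m = object$m,
              n_rejected = object$n_rejected, threshold = object$threshold,
              by_subset = table(subset = object$subset,
                                rejected = object$rejected))
  class(out) <- "summary.fdr_adjustment"
  out
}

#' @export
print.summary.fdr_adjustment <- function(x, ...) {
  cat("method:", x$method, " level:", x$level, " m:", x$m,
      " rejected:", x$n_rejected, "\n")
  print(x$by_subset)
  invisible(x)
}

#' @export
as.data.frame.fdr_adjustment <- function(x, ...) {
  data.frame(p = x$p, weighted_p = x$weighted_p, subset = x$subset,
             rejected = x$rejected, stringsAsFactors = FALSE)
}

#' Rejection-threshold plot
#'
#' Plots sorted (weighted) p-values against rank together with the BH
#' step-up line `i*q/m`, the usual visual account of the step-up
#' decision.
#'
#' @param x an `fdr_adjustment` object.
#' @param n_show number of smallest p-values to display.
#' @param ... passed to [plot()].
#' @export
plot.fdr_adjustment <- function(x, n_show = min(x$m, 200L), ...) {
  ps <- sort(x$weighted_p)[seq_len(n_show)]
  plot(seq_len(n_show), ps, xlab = "rank i", ylab = "sorted (weighted) p",
       pch = 16, cex = 0.6,
       main = paste(x$method, "at level", x$level), ...)
  graphics::abline(0, x$level / x$m, col = "red")
  invisible(x)
}
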