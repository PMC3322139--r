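#' Prior allocation of SNPs into prioritized / non-prioritized subsets
#'
#' Wraps the binary indicator `U` (1 = prioritized) with the derived
#' counts `m1`, `m0` and the prioritized fraction `epsilon = m1/m` used
#' when deriving binary weights.
#'
#' @param U binary 0/1 vector, one element per SNP.
#' @return An object of class `prior_allocation`.
#' @export
prior_allocation <- function(U) {
  U <- check_indicator(U, length(U))
  m1 <- sum(U == 1L)
  structure(list(U = U, m = length(U), m1 = m1, m0 = length(U) - m1,
                 epsilon = m1 / length(U)),
            class = "prior_allocation")
}

as_allocation <- function(x) {
  if (inherits(x, "prior_allocation")) x else prior_allocation(x)
}

#' @export
print.prior_allocation <- function(x, ...) {
  cat("prior_allocation: m =", x$m, "; prioritized m1 =", x$m1,
      sprintf("(epsilon = %.4g)\n", x$epsilon))
  invisible(x)
}

#' Binary weights from a prioritization indicator and confidence ratio
#'
#' Derives the two-level weight vector of binary weighted FDR control:
#' all prioritized SNPs share weight `w1`, all others weight `w0`, with
#' `w1/w0 = r` and the mean-one constraint `(m1*w1 + m0*w0)/m = 1`.
#' Solving the two equations gives
#' `w1 = r*m/(r*m1 + m0)` and `w0 = m/(r*m1 + m0)`.
#'
#' `r` expresses the analyst's confidence in the prior: `r = 1` (or a
#' degenerate allocation with `m1 = 0` or `m1 = m`) gives unit weights,
#' so weighted BH reduces to plain BH.
#'
#' @param allocation a [prior_allocation()] (or a bare 0/1 vector).
#' @param r ratio of prioritized to non-prioritized weight, `> 0`.
#' @return An object of class `weight_scheme`: list with `r`, `w1`,
#'   `w0` and the per-SNP weight vector `w`.
#' @examples
#' binary_weights(prior_allocation(c(1, 0)), r = 2)  # w1 = 4/3, w0 = 2/3
#' @export
binary_weights <- function(allocation, r) {
  allocation <- as_allocation(allocation)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0)
    stop("'r' must be a single positive number")
  m <- allocation$m; m1 <- allocation$m1; m0 <- allocation$m0
  if (m1 == 0L || m0 == 0L) {
    w1 <- w0 <- 1
  } else {
    denom <- r * m1 + m0
    w1 <- r * m / denom
    w0 <- m / denom
  }
  w <- ifelse(allocation$U == 1L, w1, w0)
  structure(list(r = r, w1 = w1, w0 = w0, w = w, allocation = allocation),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("binary weight scheme: r = %g, w1 = %.6g, w0 = %.6g (m1 = %d, m0 = %d)\n",
              x$r, x$w1, x$w0, x$allocation$m1, x$allocation$m0))
  invisible(x)
}

#' Construct a region table
#'
#' Regions are 1-based, inclusive intervals on a chromosome, typically
#' genes or prioritized windows.
#'
#' @param chrom chromosome label per region.
#' @param start_bp,end_bp 1-based inclusive bounds, `start_bp <= end_bp`.
#' @param source free-text provenance (e.g. gene name).
#' @return A data frame of class `region_set`.
#' @export
region_set <- function(chrom, start_bp, end_bp,
                       source = rep(NA_character_, length(chrom))) {
  x <- data.frame(chrom = as.character(chrom),
                  start_bp = as.numeric(start_bp),
                  end_bp = as.numeric(end_bp),
                  source = as.character(source),
                  stringsAsFactors = FALSE)
  if (any(is.na(x$start_bp)) || any(is.na(x$end_bp)))
    stop("region bounds must be numeric")
  if (any(x$start_bp < 0))
    stop("region start must be non-negative")
  if (any(x$start_bp > x$end_bp))
    stop("region start_bp must not exceed end_bp")
  class(x) <- c("region_set", "data.frame")
  x
}

#' Allocate SNPs to the prioritized subset from regions
#'
#' A SNP is prioritized (`U = 1`) when it lies on the same chromosome as
#' some region and within `flank_bp` of the region boundary, i.e.
#' `pos` in `[start_bp - flank_bp, end_bp + flank_bp]`. Overlapping
#' regions do not double count (set semantics), so the allocation is
#' idempotent and invariant to region order. A gene table with a 1 Mb
#' flank reproduces the "SNPs within 1 Mb of each gene" prioritization
#' rule (a 2 Mb-plus-gene-length span per gene).
#'
#' @param markers a [pvalue_set()] or data frame with columns `chrom`
#'   and `pos`.
#' @param regions a [region_set()] (or data frame with `chrom`,
#'   `start_bp`, `end_bp`).
#' @param flank_bp non-negative flank added on both sides of each
#'   region, in base pairs.
#' @return A [prior_allocation()]. Regions on chromosomes absent from
#'   the marker map are ignored with a warning.
#' @export
allocate_snps <- function(markers, regions, flank_bp = 0) {
  if (!is.numeric(flank_bp) || length(flank_bp) != 1L || flank_bp < 0)
    stop("'flank_bp' must be a single non-negative number")
  chrom <- as.character(markers$chrom)
  pos <- as.numeric(markers$pos)
  U <- integer(length(pos))
  if (!is.null(regions) && nrow(regions) > 0) {
    unknown <- !(regions$chrom %in% chrom)
    if (any(unknown)) {
      warning("ignoring ", sum(unknown),
              " region(s) on chromosome(s) absent from the marker map: ",
              paste(unique(regions$chrom[unknown]), collapse = ", "))
      regions <- regions[!unknown, , drop = FALSE]
    }
    for (i in seq_len(nrow(regions))) {
      hit <- chrom == regions$chrom[i] &
        pos >= regions$start_bp[i] - flank_bp &
        pos <= regions$end_bp[i] + flank_bp
      U[hit] <- 1L
    }
  }
  prior_allocation(U)
}

# Factor C registry: which causal loci (1..6) fall inside prioritized
# regions under each prioritization-accuracy scenario.
scenario_covered_loci <- list(
  i = integer(0),
  ii = 6L,
  iii = c(1L, 6L),
  iv = c(1L, 2L, 5L, 6L),
  v = c(4L, 5L, 6L),
  vi = c(1L, 4L, 5L, 6L),
  vii = c(1L, 2L, 4L, 5L, 6L),
  viii = 1:6
)

#' Causal-locus subsets of the prioritization-accuracy scenarios
#'
#' Returns the registry mapping scenario labels `"i"` through `"viii"`
#' to the causal loci (numbered 1-6; 1-3 small effect, 4-6 large
#' effect) covered by the prioritized regions: (i) none, (ii) locus 6,
#' (iii) loci 1 and 6, (iv) loci 1, 2, 5, 6, (v) loci 4-6,
#' (vi) loci 1, 4, 5, 6, (vii) all but locus 3, (viii) all six.
#'
#' @param scenario optional scenario label; if given, returns that
#'   entry's integer vector.
#' @return A named list, or an integer vector if `scenario` is given.
#' @export
prioritization_scenarios <- function(scenario = NULL) {
  if (is.null(scenario)) return(scenario_covered_loci)
  scenario <- match.arg(as.character(scenario), names(scenario_covered_loci))
  scenario_covered_loci[[scenario]]
}

#' Build prioritized regions for a simulation scenario
#'
#' Constructs the prioritized-region set of a simulation scenario: one
#' region of `region_size_bp` centered on each covered causal locus,
#' plus decoy regions (up to `n_regions` total) placed uniformly at
#' random on the marker map. Decoys are non-overlapping and their
#' centers are kept at least `region_size_bp + decoy_buffer_bp` away
#' from every causal locus, so decoy regions are unambiguously null:
#' no SNP inside (or within 1 Mb of) a decoy is near a causal locus.
#'
#' @param markers marker map (data frame with `chrom`, `pos`).
#' @param truth causal loci: data frame with `chrom` and `pos`.
#' @param n_regions total number of prioritized regions (6, 14 or 22 in
#'   the standard grid).
#' @param region_size_bp size of each region in bp (2 Mb or 20 Mb in
#'   the standard grid).
#' @param covered_loci indices into `truth` of the causal loci to cover
#'   (a scenario label such as `"viii"` is also accepted and resolved
#'   via [prioritization_scenarios()]).
#' @param seed integer seed; the same seed yields identical regions.
#' @param decoy_buffer_bp extra clearance between a decoy center and any
#'   causal locus, beyond the region size (default 2 Mb).
#' @param max_tries placement attempts per decoy before giving up.
#' @return A [region_set()] with `source` labelling each region
#'   `"causal_<j>"` or `"decoy_<k>"`.
#' @export
build_scenario <- function(markers, truth, n_regions, region_size_bp,
                           covered_loci, seed = 1L,
                           decoy_buffer_bp = 2e6, max_tries = 1000L) {
  if (is.character(covered_loci))
    covered_loci <- prioritization_scenarios(covered_loci)
  covered_loci <- as.integer(covered_loci)
  if (length(covered_loci) > n_regions)
    stop("more covered loci than regions")
  if (length(covered_loci) > 0 &&
      (any(covered_loci < 1L) || any(covered_loci > nrow(truth))))
    stop("covered_loci out of range")
  half <- region_size_bp / 2
  chroms <- unique(as.character(markers$chrom))
  chrom_len <- vapply(chroms, function(cc)
    max(markers$pos[markers$chrom == cc]), numeric(1))

  out_chrom <- character(0); out_start <- numeric(0); out_end <- numeric(0)
  out_src <- character(0)
  for (j in covered_loci) {
    out_chrom <- c(out_chrom, as.character(truth$chrom[j]))
    out_start <- c(out_start, max(1, truth$pos[j] - half))
    out_end <- c(out_end, truth$pos[j] + half)
    out_src <- c(out_src, paste0("causal_", j))
  }

  n_decoys <- n_regions - length(covered_loci)
  if (n_decoys > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    min_causal_dist <- region_size_bp + decoy_buffer_bp
    for (k in seq_len(n_decoys)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cc <- sample(chroms, 1, prob = chrom_len)
        len <- chrom_len[[cc]]
        if (len <= region_size_bp) next
        center <- stats::runif(1, half, len - half)
        # clearance from every causal locus on this chromosome
        on_cc <- as.character(truth$chrom) == cc
        if (any(on_cc) && any(abs(truth$pos[on_cc] - center) < min_causal_dist))
          next
        start <- center - half; end <- center + half
        same <- out_chrom == cc
        if (any(same) && any(pmax(out_start[same], start) <=
                             pmin(out_end[same], end)))
          next
        out_chrom <- c(out_chrom, cc)
        out_start <- c(out_start, start)
        out_end <- c(out_end, end)
        out_src <- c(out_src, paste0("decoy_", k))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place non-overlapping decoy region ", k,
             " after ", max_tries, " attempts")
    }
  }
  region_set(out_chrom, round(out_start), round(out_end), out_src)
}
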