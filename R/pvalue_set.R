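#' Construct a per-SNP p-value set
#'
#' A `pvalue_set` is a plain data frame with columns `snp_id`, `chrom`,
#' `pos` and `p`, validated so that downstream adjustment procedures can
#' assume clean input: unique SNP identifiers, non-negative base-pair
#' positions and p-values in \[0, 1\]. Row order is preserved and
#' meaningful (results are reported in input order).
#'
#' @param snp_id character vector of unique marker identifiers.
#' @param chrom chromosome label per marker (opaque string, matched
#'   exactly against region files).
#' @param pos integer base-pair coordinate per marker (1-based).
#' @param p raw p-value per marker, in \[0, 1\].
#' @return A data frame of class `pvalue_set`.
#' @examples
#' ps <- pvalue_set(paste0("rs", 1:3), "1", c(100L, 200L, 300L),
#'                  c(0.01, 0.5, 0.9))
#' @export
pvalue_set <- function(snp_id, chrom, pos, p) {
  x <- data.frame(snp_id = as.character(snp_id),
                  chrom = as.character(chrom),
                  pos = as.integer(pos),
                  p = as.numeric(p),
                  stringsAsFactors = FALSE)
  validate_pvalue_set(x)
}

validate_pvalue_set <- function(x) {
  required <- c("snp_id", "chrom", "pos", "p")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop("pvalue_set is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(x) < 1L)
    stop("pvalue_set must contain at least one SNP (no tests to adjust)")
  if (anyDuplicated(x$snp_id))
    stop("duplicate snp_id values: ",
         paste(unique(x$snp_id[duplicated(x$snp_id)]), collapse = ", "))
  if (any(is.na(x$p)) || any(x$p < 0) || any(x$p > 1))
    stop("all p-values must lie in [0, 1]")
  if (any(is.na(x$pos)) || any(x$pos < 0))
    stop("positions must be non-negative integers")
  class(x) <- c("pvalue_set", "data.frame")
  x
}

#' @export
print.pvalue_set <- function(x, ...) {
  cat("pvalue_set with", nrow(x), "SNPs on",
      length(unique(x$chrom)), "chromosome(s)\n")
  NextMethod()
}

check_pvalues <- function(p) {
  if (length(p) == 0L)
    stop("no p-values supplied: there are no tests to adjust")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("all p-values must lie in [0, 1]")
  invisible(p)
}

check_level <- function(q, name = "q") {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    stop("'", name, "' must be a single number in (0, 1)")
  invisible(q)
}
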