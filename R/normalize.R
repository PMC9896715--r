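#' Filter lowly expressed genes
#'
#' Keeps genes with at least `min_count` reads in at least
#' `ceiling(min_fraction * n_samples)` samples; the sample axis is never
#' touched.  Idempotent by construction.
#'
#' @param counts Count matrix (genes x samples).
#' @param min_count Minimum count per qualifying sample (default 1).
#' @param min_fraction Minimum fraction of samples (default 0.3).
#' @return Filtered count matrix.
#' @export
filter_genes <- function(counts, min_count = 1, min_fraction = 0.3) {
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  if (!any(keep)) warning("no genes pass the expression filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' The per-sample factor is the median, over genes whose geometric mean
#' across samples is positive, of the ratio of the sample's count to the
#' gene's geometric mean.
#'
#' @param counts Count matrix.
#' @param pseudo_reference If `TRUE`, fall back to a pseudo-reference built
#'   from positive counts only, for matrices where no gene is expressed in
#'   every sample.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    if (!pseudo_reference)
      stop("degenerate input: no gene has positive counts in every sample; ",
           "consider pseudo_reference = TRUE")
    # positive-count fallback: geometric mean over positive entries only
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    loggeo <- rowMeans(lc, na.rm = TRUE)
    ok <- is.finite(loggeo) & rowSums(counts > 0) > 0
    if (!any(ok)) stop("degenerate input: all-zero count matrix")
  }
  sf <- apply(counts, 2, function(cnts) {
    r <- log(cnts[ok]) - loggeo[ok]
    exp(stats::median(r[is.finite(r)]))
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate input: could not compute positive size factors")
  sf
}

#' Median-of-ratios log2 normalization
#'
#' `log2(count / size_factor + pseudocount)`; with the default pseudocount
#' an all-zero gene maps to a row of zeros.
#'
#' @inheritParams size_factors
#' @param pseudocount Added inside the log (default 1).
#' @return Matrix of log2-scale values with `method` attribute `"mor_log2"`.
#' @export
mor_log2 <- function(counts, pseudocount = 1, pseudo_reference = FALSE) {
  sf <- size_factors(counts, pseudo_reference = pseudo_reference)
  out <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  attr(out, "method") <- "mor_log2"
  out
}

#' Shifted-log display transform
#'
#' `log2(count / size_factor + pseudocount)` on median-of-ratios scaled
#' counts; stands in for a variance-stabilizing transform for display.
#'
#' @inheritParams mor_log2
#' @return Matrix with `method` attribute `"shifted_log"`.
#' @export
shifted_log <- function(counts, pseudocount = 1, pseudo_reference = FALSE) {
  out <- mor_log2(counts, pseudocount, pseudo_reference)
  attr(out, "method") <- "shifted_log"
  out
}

# Trimmed-mean-of-M-values factor of `obs` against reference column `ref`
# (edgeR-style: 30% trim on M, 5% on A, precision weights).
tmm_pair_factor <- function(obs, ref, logratio_trim = 0.3, sum_trim = 0.05) {
  obs <- as.numeric(obs)  # doubles: integer library sizes overflow in n*y
  ref <- as.numeric(ref)
  n_o <- sum(obs)
  n_r <- sum(ref)
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  po <- obs[keep] / n_o
  pr <- ref[keep] / n_r
  M <- log2(po / pr)
  A <- 0.5 * log2(po * pr)
  w <- (n_o - obs[keep]) / (n_o * obs[keep]) +
       (n_r - ref[keep]) / (n_r * ref[keep])
  fin <- is.finite(M) & is.finite(A) & A > -1e10
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep2)) return(1)
  f <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) 1 else 2^f
}

#' TMM normalization factors
#'
#' The reference sample is the one whose upper-quartile (of library-scaled
#' counts) is closest to the mean upper-quartile; per-sample factors are
#' precision-weighted means of M-values after trimming 30% of M and 5% of A
#' at both tails, then normalized to geometric mean 1.
#'
#' @param counts Filtered count matrix.
#' @return Named numeric factors, geometric mean 1.
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  lib <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)),
               function(j) stats::quantile(counts[, j] / lib[j], 0.75,
                                           names = FALSE),
               numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)),
              function(j) tmm_pair_factor(counts[, j], counts[, ref]),
              numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' TMM counts-per-million log normalization
#'
#' `log2(CPM + 0.5)` computed with effective library sizes
#' (library size x TMM factor); the normalization used upstream of the
#' tumour-normal-difference classifier features.
#'
#' @param counts Filtered count matrix.
#' @return Matrix of log2 values with `method` attribute `"tmm_cpm_log"` and
#'   the factors in `attr(, "tmm_factors")`.
#' @export
tmm_cpm_log <- function(counts) {
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  cpm <- sweep(counts, 2, eff / 1e6, "/")
  out <- log2(cpm + 0.5)
  attr(out, "method") <- "tmm_cpm_log"
  attr(out, "tmm_factors") <- f
  out
}
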