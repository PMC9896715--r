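#' Gene-wise dispersion estimation with trend shrinkage
#'
#' Method-of-moments gene-wise estimates on size-factor-normalized counts,
#' floored at 1e-8, a parametric mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu` fitted robustly across genes, and a log-scale
#' blend `alpha = exp(w log alpha_trend + (1-w) log alpha_gene)`.  With
#' residual degrees of freedom <= 1 (e.g. paired per-patient designs) the
#' gene-wise estimate carries no information and the trend is used alone
#' (`w = 1`).
#'
#' @param counts Count matrix.
#' @param design Design matrix (samples x p), full rank.
#' @param sf Size factors (defaults to median-of-ratios on `counts`).
#' @param w Shrinkage weight toward the trend in `[0, 1]`; default 0.5,
#'   forced to 1 when `nrow(design) - ncol(design) <= 1`.
#' @return List with `genewise`, `trend`, `final` (per-gene alpha), the
#'   trend coefficients `a0`, `a1`, and the weight `w` used.
#' @export
estimate_dispersions <- function(counts, design, sf = NULL, w = 0.5) {
  n <- ncol(counts)
  p <- ncol(design)
  if (n < 2) stop("design error: need >= 2 samples")
  if (n <= p) stop("design error: fewer samples than design columns")
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  if (n - p <= 1) w <- 1

  q <- sweep(counts, 2, sf, "/")
  # project out the design: residual variance around fitted means
  H <- design %*% solve(crossprod(design), t(design))
  qhat <- q %*% t(H)
  resid2 <- rowSums((q - qhat)^2) / (n - p)
  mu <- rowMeans(q)
  xim <- mean(1 / sf)
  genewise <- pmax((resid2 - xim * mu) / mu^2, 1e-8)
  genewise[!is.finite(genewise) | mu <= 0] <- 1e-8

  tr <- fit_dispersion_trend(mu, genewise)
  trend <- pmax(tr$a0 + tr$a1 / pmax(mu, 1e-8), 1e-8)
  final <- exp(w * log(trend) + (1 - w) * log(genewise))
  list(genewise = genewise, trend = trend, final = pmax(final, 1e-8),
       a0 = tr$a0, a1 = tr$a1, w = w)
}

# Robust parametric trend alpha(mu) = a0 + a1/mu fitted by an iterated
# Gamma GLM over genes, excluding extreme-ratio outliers each round.
fit_dispersion_trend <- function(mu, alpha) {
  use <- is.finite(mu) & mu > 0 & is.finite(alpha) & alpha > 1e-7
  if (sum(use) < 10)
    return(list(a0 = max(stats::median(alpha), 1e-8), a1 = 0))
  m <- mu[use]; a <- alpha[use]
  a0 <- max(stats::median(a), 1e-8); a1 <- 0
  for (it in 1:10) {
    pred <- pmax(a0 + a1 / m, 1e-10)
    ratio <- a / pred
    keep <- ratio > 1e-4 & ratio < 15
    if (sum(keep) < 10) break
    fit <- tryCatch(
      stats::glm(a[keep] ~ I(1 / m[keep]),
                 family = stats::Gamma(link = "identity"),
                 start = c(a0, a1)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) break
    co <- stats::coef(fit)
    if (!all(is.finite(co))) break
    new0 <- max(co[1], 1e-8); new1 <- max(co[2], 0)
    if (abs(new0 - a0) < 1e-6 * (a0 + 1e-8) && abs(new1 - a1) < 1e-6 * (a1 + 1e-8)) {
      a0 <- new0; a1 <- new1; break
    }
    a0 <- new0; a1 <- new1
  }
  list(a0 = a0, a1 = a1)
}

# Drop aliased (linearly dependent or all-zero) columns of a design matrix.
drop_aliased <- function(X) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) return(X)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  X[, keep, drop = FALSE]
}

#' Negative-binomial Wald test for a design contrast
#'
#' Per gene, fits an NB log-link GLM with size-factor offsets by iteratively
#' reweighted least squares (fixed per-gene dispersion), estimates the
#' requested contrast, and reports a two-sided normal-tail Wald p-value with
#' Benjamini-Hochberg adjustment across genes.  Non-converged genes are
#' flagged and given p = 1.
#'
#' @param counts Count matrix.
#' @param design Design matrix (samples x p, full rank after alias drop).
#' @param dispersions Per-gene dispersion vector.
#' @param contrast Numeric contrast over design columns; default tests the
#'   last column.
#' @param sf Size factors (median-of-ratios by default).
#' @param ridge Optional ridge precision on non-intercept coefficients
#'   (natural-log scale); 0 disables (default).  A Normal(0, 4) prior on the
#'   log2 coefficient corresponds to `ridge = 1 / (4 * log(2)^2)`.
#' @return `data.frame` with gene_id, log2fc, se, pvalue, padj, converged;
#'   `call` column unset (see [call_de()]).
#' @export
wald_test_nb <- function(counts, design, dispersions, contrast = NULL,
                         sf = NULL, ridge = 0) {
  design <- drop_aliased(design)
  if (nrow(design) != ncol(counts))
    stop("design error: design rows must match samples")
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  if (is.null(contrast)) {
    contrast <- numeric(ncol(design))
    contrast[ncol(design)] <- 1
  }
  if (length(contrast) != ncol(design))
    stop("design error: contrast length must match design columns")
  fit <- .nb_glm_genewise(counts, design, log(sf),
                          rep_len(dispersions, nrow(counts)), contrast,
                          ridge = ridge)
  log2fc <- fit$estimate / log(2)
  se <- fit$se / log(2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  bad <- !is.finite(p) | fit$converged == 0L
  p[bad] <- 1
  log2fc[!is.finite(log2fc)] <- 0
  p <- pmin(pmax(p, 1e-300), 1)
  data.frame(gene_id = rownames(counts), log2fc = log2fc, se = se,
             pvalue = p, padj = stats::p.adjust(p, method = "BH"),
             converged = fit$converged == 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differential expression from thresholds
#'
#' A gene is `up` iff `padj < alpha` and `log2fc > lfc_min`, `down` iff
#' `padj < alpha` and `log2fc < -lfc_min`, else `none`.
#'
#' @param results DE table with `padj` and `log2fc`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc_min Absolute log2 fold-change threshold (default 1).
#' @return The table with a `call` column.
#' @export
call_de <- function(results, alpha = 0.05, lfc_min = 1) {
  stopifnot(all(c("padj", "log2fc") %in% colnames(results)))
  call <- rep("none", nrow(results))
  sig <- !is.na(results$padj) & results$padj < alpha
  call[sig & results$log2fc > lfc_min] <- "up"
  call[sig & results$log2fc < -lfc_min] <- "down"
  results$call <- call
  results
}

# Align a sample table to count matrix columns; returns the table reordered.
align_samples <- function(counts, samples) {
  samples <- validate_sample_table(samples)
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss) > 0)
    stop("samples absent from sample table: ", paste(miss, collapse = ", "))
  samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
}

#' Cohort-level (all-patients) differential expression
#'
#' All tumour samples against all normal samples with patient identity as a
#' blocking covariate: design `~ patient_id + sample_type`, tested
#' coefficient tumour vs normal.
#'
#' @param counts Filtered count matrix.
#' @param samples Sample table covering every column of `counts`.
#' @param alpha,lfc_min Call thresholds, see [call_de()].
#' @param shrink_w Dispersion-trend shrinkage weight.
#' @param ridge Optional ridge prior, see [wald_test_nb()].
#' @return DE table with calls.
#' @export
run_all_patients <- function(counts, samples, alpha = 0.05, lfc_min = 1,
                             shrink_w = 0.5, ridge = 0) {
  samples <- align_samples(counts, samples)
  if (length(unique(samples$patient_id)) < 2)
    stop("design error: need >= 2 patients")
  one_type <- tapply(samples$sample_type, samples$patient_id,
                     function(x) length(unique(x)) == 1)
  if (any(one_type))
    warning("patients with a single sample type contribute no information: ",
            paste(names(one_type)[one_type], collapse = ", "))
  patient <- factor(samples$patient_id)
  type <- factor(samples$sample_type, levels = c("normal", "tumour"))
  X <- stats::model.matrix(~ patient + type)
  X <- drop_aliased(X)
  sf <- size_factors(counts, pseudo_reference = TRUE)
  disp <- estimate_dispersions(counts, X, sf = sf, w = shrink_w)
  contrast <- as.numeric(colnames(X) == "typetumour")
  res <- wald_test_nb(counts, X, disp$final, contrast = contrast, sf = sf,
                      ridge = ridge)
  call_de(res, alpha, lfc_min)
}

#' Per-patient paired differential expression
#'
#' Each analysed patient's tumour regions are compared with that patient's
#' single adjacent normal sample (design: sample type only).  Patients
#' without >= 2 tumour samples and exactly 1 normal sample are skipped with
#' a warning.  Dispersion estimation is forced to the trend because 3-6
#' samples cannot support gene-wise estimates.
#'
#' @inheritParams run_all_patients
#' @param min_tumour Minimum tumour samples per analysed patient (default 2).
#' @return Named list of DE tables, one per analysed patient.
#' @export
run_per_patient <- function(counts, samples, alpha = 0.05, lfc_min = 1,
                            min_tumour = 2, ridge = 0) {
  samples <- align_samples(counts, samples)
  split_idx <- split(seq_len(nrow(samples)), samples$patient_id)
  eligible <- vapply(split_idx, function(idx) {
    tt <- table(samples$sample_type[idx])
    sum(samples$sample_type[idx] == "tumour") >= min_tumour &&
      sum(samples$sample_type[idx] == "normal") == 1
  }, logical(1))
  if (!any(eligible)) stop("no eligible patients for per-patient analysis")
  if (any(!eligible))
    warning("skipping patients without ", min_tumour,
            " tumour + 1 normal sample: ",
            paste(names(split_idx)[!eligible], collapse = ", "))
  out <- lapply(split_idx[eligible], function(idx) {
    sub <- counts[, idx, drop = FALSE]
    type <- factor(samples$sample_type[idx], levels = c("normal", "tumour"))
    X <- stats::model.matrix(~ type)
    sf <- size_factors(sub, pseudo_reference = TRUE)
    disp <- estimate_dispersions(sub, X, sf = sf, w = 1)
    res <- wald_test_nb(sub, X, disp$final, sf = sf, ridge = ridge)
    call_de(res, alpha, lfc_min)
  })
  out
}

#' Differential expression between patient groups
#'
#' Tests whether the tumour-vs-normal effect differs between two patient
#' groups using a nested design: group, group:nested-patient and
#' group:sample-type interactions, with patients renumbered within each
#' group.  The tested contrast is the difference of the two groups' tumour
#' effects (g1 minus g0).
#'
#' @inheritParams run_all_patients
#' @param grouping `data.frame` with patient_id and group columns.
#' @param g0,g1 Group labels to contrast (log2fc > 0 means stronger tumour
#'   up-regulation in `g1`).
#' @return DE table with calls.
#' @export
run_between_groups <- function(counts, samples, grouping, g0, g1,
                               alpha = 0.05, lfc_min = 1, shrink_w = 0.5,
                               ridge = 0) {
  samples <- align_samples(counts, samples)
  grp <- stats::setNames(as.character(grouping$group), grouping$patient_id)
  keep <- samples$patient_id %in% names(grp)[grp %in% c(g0, g1)]
  samples <- samples[keep, , drop = FALSE]
  counts <- counts[, samples$sample_id, drop = FALSE]
  pg <- factor(grp[samples$patient_id], levels = c(g0, g1))
  if (any(table(unique(data.frame(p = samples$patient_id, g = pg))$g) < 2))
    stop("design error: both groups need >= 2 patients")
  # renumber patients within each group so the nesting is estimable:
  # intercept, group main effect, within-group patient offsets (reference =
  # first patient of each group), and one tumour effect per group
  pn <- integer(nrow(samples))
  for (g in levels(pg)) {
    sel <- pg == g
    pn[sel] <- match(samples$patient_id[sel], unique(samples$patient_id[sel]))
  }
  tumour <- as.numeric(samples$sample_type == "tumour")
  X <- cbind("(Intercept)" = 1,
             stats::setNames(data.frame(as.numeric(pg == g1)),
                             paste0("pg", g1)))
  X <- as.matrix(X)
  for (g in levels(pg)) for (j in seq_len(max(pn[pg == g]))[-1]) {
    X <- cbind(X, as.numeric(pg == g & pn == j))
    colnames(X)[ncol(X)] <- paste0("pg", g, ":patient", j)
  }
  for (g in levels(pg)) {
    X <- cbind(X, as.numeric(pg == g) * tumour)
    colnames(X)[ncol(X)] <- paste0("pg", g, ":typetumour")
  }
  X2 <- drop_aliased(X)
  if (ncol(X2) < ncol(X))
    stop("design error: aliased columns after nesting: ",
         paste(setdiff(colnames(X), colnames(X2)), collapse = ", "))
  c0 <- paste0("pg", g0, ":typetumour")
  c1 <- paste0("pg", g1, ":typetumour")
  contrast <- as.numeric(colnames(X2) == c1) - as.numeric(colnames(X2) == c0)
  sf <- size_factors(counts, pseudo_reference = TRUE)
  disp <- estimate_dispersions(counts, X2, sf = sf, w = shrink_w)
  res <- wald_test_nb(counts, X2, disp$final, contrast = contrast, sf = sf,
                      ridge = ridge)
  call_de(res, alpha, lfc_min)
}
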