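#' Kaplan-Meier estimate with risk table
#'
#' Product-limit estimator (via the survival package), optionally stratified
#' by group.
#'
#' @param time Follow-up times in days.
#' @param event Event indicator (1 = recurrence, 0 = censored).
#' @param group Optional group labels for stratified curves.
#' @return `data.frame` with (group,) time, n_risk, n_event, n_censor, surv.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               n_censor = fit$n.censor, surv = fit$surv, row.names = NULL)
  } else {
    g <- factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ g)
    strata <- rep(names(fit$strata), fit$strata)
    data.frame(group = sub("^g=", "", strata), time = fit$time,
               n_risk = fit$n.risk, n_event = fit$n.event,
               n_censor = fit$n.censor, surv = fit$surv, row.names = NULL)
  }
}

#' Weighted log-rank test (log-rank, Peto-Peto, modified Peto-Peto)
#'
#' K-sample weighted log-rank test.  At each distinct event time the weight
#' is 1 (`logrank`), the left-continuous pooled Kaplan-Meier estimate
#' (`peto`), or that estimate times `n/(n+1)` with `n` the number at risk
#' (`modified_peto`, the default used for all survival comparisons).  The
#' statistic is the quadratic form of the weighted observed-minus-expected
#' vector in its estimated covariance (one group dropped), with K-1 degrees
#' of freedom and a chi-square upper-tail p-value.
#'
#' @param time,event Survival data.
#' @param group Group labels (>= 2 groups).
#' @param weight `"modified_peto"` (default), `"peto"` or `"logrank"`.
#' @return List of class `mrde_test` with statistic, df, p, method.
#' @export
weighted_logrank <- function(time, event,
                             group, weight = c("modified_peto", "peto",
                                               "logrank")) {
  weight <- match.arg(weight)
  g <- factor(group)
  K <- nlevels(g)
  if (K < 2) stop("need >= 2 groups")
  if (sum(event) == 0) {
    warning("no events: p set to 1")
    return(test_result(0, K - 1, 1, paste0("weighted logrank (", weight, ")")))
  }
  o <- order(time)
  time <- time[o]; event <- event[o]; g <- g[o]
  et <- unique(time[event == 1])
  n <- length(time)

  # left-continuous pooled KM evaluated at each event time
  surv_left <- numeric(length(et))
  s <- 1
  for (i in seq_along(et)) {
    surv_left[i] <- s
    ni <- sum(time >= et[i])
    di <- sum(time == et[i] & event == 1)
    s <- s * (1 - di / ni)
  }

  U <- numeric(K)
  V <- matrix(0, K, K)
  for (i in seq_along(et)) {
    at_risk <- time >= et[i]
    ni <- sum(at_risk)
    nij <- tabulate(g[at_risk], K)
    di <- sum(time == et[i] & event == 1)
    dij <- tabulate(g[time == et[i] & event == 1], K)
    wi <- switch(weight,
                 logrank = 1,
                 peto = surv_left[i],
                 modified_peto = surv_left[i] * ni / (ni + 1))
    U <- U + wi * (dij - di * nij / ni)
    if (ni > 1) {
      vshare <- di * (ni - di) / (ni - 1)
      p_j <- nij / ni
      Vi <- vshare * (diag(p_j, K) - tcrossprod(p_j))
      V <- V + wi^2 * Vi
    }
  }
  idx <- seq_len(K - 1)
  Vsub <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(
    as.numeric(t(U[idx]) %*% solve(Vsub, U[idx])),
    error = function(e) {
      pinv <- MASS::ginv(Vsub)
      as.numeric(t(U[idx]) %*% pinv %*% U[idx])
    })
  if (!is.finite(stat) || stat < 0) stat <- 0
  p <- stats::pchisq(stat, df = K - 1, lower.tail = FALSE)
  test_result(stat, K - 1, p, paste0("weighted logrank (", weight, ")"))
}

test_result <- function(statistic, df, p, method, side = "two", ...) {
  out <- list(statistic = unname(statistic), df = df, p = unname(p),
              method = method, side = side, ...)
  class(out) <- "mrde_test"
  out
}

#' @export
print.mrde_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 5),
      if (!is.null(x$df) && !is.na(x$df)) paste0("(df = ", x$df, ")"),
      "\n  p =", format(x$p, digits = 5), paste0("(", x$side, "-sided)"), "\n")
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples together have at most 12 observations
#' and there are no ties; otherwise a normal approximation with midranks and
#' continuity correction.  The direction of a one-sided test must be given
#' explicitly.
#'
#' @param x,y Numeric samples.
#' @param side `"two"`, `"less"` (x tends smaller) or `"greater"`.
#' @return `mrde_test` with the rank-sum statistic and p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, side = c("two", "less", "greater")) {
  side <- match.arg(side)
  if (length(x) == 0 || length(y) == 0) stop("non-empty samples required")
  alt <- switch(side, two = "two.sided", less = "less", greater = "greater")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = TRUE))
  test_result(unname(res$statistic), NA_integer_, res$p.value,
              if (exact) "Wilcoxon rank-sum (exact)"
              else "Wilcoxon rank-sum (normal approximation)",
              side = if (side == "two") "two" else "one")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities not exceeding the
#' observed table's.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return `mrde_test` with p-value and odds-ratio estimate.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(test_result(NA_real_, NA_integer_, 1, "Fisher exact (2x2)"))
  res <- stats::fisher.test(tab)
  test_result(unname(res$estimate), NA_integer_, res$p.value,
              "Fisher exact (2x2)")
}

#' Monte-Carlo Fisher test for r x c tables
#'
#' P-value estimated as the (plus-one corrected) fraction of
#' margin-preserving sampled tables whose probability does not exceed the
#' observed table's.
#'
#' @param tab r x c matrix of non-negative integers.
#' @param n_mc Number of sampled tables (default 1e5).
#' @param seed Integer seed for reproducibility.
#' @return `mrde_test`.
#' @export
fisher_rxc <- function(tab, n_mc = 100000, seed = 1L) {
  tab <- as.matrix(tab)
  res <- withr::with_seed(as.integer(seed),
    stats::fisher.test(tab, simulate.p.value = TRUE, B = n_mc))
  test_result(NA_real_, NA_integer_, res$p.value,
              sprintf("Fisher exact (Monte Carlo, B = %d)", as.integer(n_mc)))
}

#' Pearson chi-square test of independence
#'
#' @param tab Contingency table.
#' @return `mrde_test` with statistic, df = (r-1)(c-1), p.
#' @export
chisq_independence <- function(tab) {
  res <- suppressWarnings(stats::chisq.test(as.matrix(tab), correct = FALSE))
  test_result(unname(res$statistic), unname(res$parameter), res$p.value,
              "Pearson chi-square independence")
}

#' Chi-square goodness of fit with standardized residuals
#'
#' `sum((O - E)^2 / E)` with df = k - 1 and residuals `(O - E) / sqrt(E)`;
#' the default expectation is uniform over the k categories.
#'
#' @param observed Non-negative counts over k categories.
#' @param expected Expected counts (default: uniform, `sum(observed)/k`).
#' @return `mrde_test` with `residuals` holding the standardized residuals.
#' @export
chisq_gof <- function(observed, expected = NULL) {
  if (sum(observed) <= 0) stop("observed counts must sum to > 0")
  k <- length(observed)
  if (is.null(expected)) expected <- rep(sum(observed) / k, k)
  if (length(expected) != k || any(expected <= 0))
    stop("expected must be positive, one per category")
  resid <- (observed - expected) / sqrt(expected)
  stat <- sum(resid^2)
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  test_result(stat, k - 1L, p, "chi-square goodness of fit",
              residuals = resid)
}

#' Benjamini-Hochberg adjusted p-values
#' @param pvalues Raw p-values in `[0, 1]`.
#' @return Adjusted values (monotone, clipped to `[0, 1]`).
#' @export
bh_fdr <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Bonferroni adjusted p-values
#' @param pvalues Raw p-values.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(pvalues) stats::p.adjust(pvalues, method = "bonferroni")

#' Table-1-style association tests between patient groups and covariates
#'
#' For each covariate: categorical variables are tested with Fisher's exact
#' test when any expected cell count is below 5 (Monte Carlo for tables
#' larger than 2x2) and the Pearson chi-square test otherwise; continuous
#' variables with the two-sided Wilcoxon rank-sum test (two groups only).
#'
#' @param grouping `data.frame` with patient_id, group.
#' @param clinical Clinical table with patient_id and covariate columns.
#' @param covariates Covariate column names (default: everything except
#'   patient_id, rfs_days, recurrence_event).
#' @param seed Seed for Monte-Carlo Fisher tests.
#' @return `data.frame` with variable, test, p.
#' @export
associate_covariates <- function(grouping, clinical, covariates = NULL,
                                 seed = 1L) {
  merged <- merge(grouping, clinical, by = "patient_id")
  if (is.null(covariates))
    covariates <- setdiff(colnames(clinical),
                          c("patient_id", "rfs_days", "recurrence_event"))
  rows <- lapply(covariates, function(v) {
    x <- merged[[v]]
    ok <- !is.na(x)
    g <- factor(merged$group[ok])
    x <- x[ok]
    if (is.numeric(x)) {
      if (nlevels(g) != 2)
        return(data.frame(variable = v, test = "wilcoxon", p = NA_real_))
      p <- wilcoxon_rank_sum(x[g == levels(g)[1]], x[g == levels(g)[2]],
                             side = "two")$p
      data.frame(variable = v, test = "wilcoxon", p = p)
    } else {
      tab <- table(factor(x), g)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        if (all(dim(tab) == c(2, 2))) {
          p <- fisher_exact_2x2(tab)$p
          data.frame(variable = v, test = "fisher", p = p)
        } else {
          p <- fisher_rxc(tab, seed = seed)$p
          data.frame(variable = v, test = "fisher_mc", p = p)
        }
      } else {
        p <- chisq_independence(tab)$p
        data.frame(variable = v, test = "chisq", p = p)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
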