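#' Per-patient log2 fold-change matrix
#'
#' @param per_patient Named list of per-patient DE tables.
#' @param gene_subset Genes to include (rows); must be within the shared
#'   universe.
#' @return Numeric matrix genes x patients; cells where a gene was filtered
#'   out for a patient are 0 with the corresponding `attr(, "mask")` bit set.
#' @export
build_lfc_matrix <- function(per_patient, gene_subset) {
  patients <- names(per_patient)
  M <- matrix(0, length(gene_subset), length(patients),
              dimnames = list(gene_subset, patients))
  mask <- matrix(FALSE, length(gene_subset), length(patients),
                 dimnames = dimnames(M))
  for (p in patients) {
    tab <- per_patient[[p]]
    idx <- match(gene_subset, tab$gene_id)
    hit <- !is.na(idx)
    M[hit, p] <- tab$log2fc[idx[hit]]
    mask[!hit, p] <- TRUE
  }
  attr(M, "mask") <- mask
  M
}

#' Categorical dysregulation matrix
#'
#' Collapses per-patient calls into a three-valued matrix: +1 for `up`,
#' -1 for `down`, 0 otherwise (including genes filtered out for a patient).
#'
#' @inheritParams build_lfc_matrix
#' @return Integer matrix with values in \{-1, 0, +1\}.
#' @export
categorize <- function(per_patient, gene_subset) {
  patients <- names(per_patient)
  M <- matrix(0L, length(gene_subset), length(patients),
              dimnames = list(gene_subset, patients))
  for (p in patients) {
    tab <- per_patient[[p]]
    idx <- match(gene_subset, tab$gene_id)
    hit <- !is.na(idx)
    v <- integer(sum(hit))
    calls <- tab$call[idx[hit]]
    v[calls == "up"] <- 1L
    v[calls == "down"] <- -1L
    M[hit, p] <- v
  }
  M
}

# Penalized complete-data log-likelihood: data term plus the Dirichlet(1.5)
# pseudo-count prior on theta and the mixing proportions.  The CEM steps
# each maximize this objective, so it is non-decreasing within a restart.
lbm_loglik <- function(nklc, z, w, log_theta, log_pr, log_pc) {
  sum(nklc * log_theta) + sum(log_pr[z]) + sum(log_pc[w]) +
    0.5 * sum(log_theta) + 0.5 * sum(log_pr) + 0.5 * sum(log_pc)
}

# category counts per (row cluster, col cluster, category)
lbm_counts <- function(Mcat, z, w, L, K, ncat) {
  n <- array(0, dim = c(L, K, ncat))
  Zi <- matrix(0, length(z), L); Zi[cbind(seq_along(z), z)] <- 1
  Wi <- matrix(0, length(w), K); Wi[cbind(seq_along(w), w)] <- 1
  for (c in seq_len(ncat))
    n[, , c] <- t(Zi) %*% (Mcat == c) %*% Wi
  n
}

#' Categorical latent block model co-clustering
#'
#' Classification EM for a latent block model over the three categories
#' \{-1, 0, +1\}: rows (genes) and columns (patients) are hard-assigned to
#' clusters maximizing the complete-data log-likelihood given the
#' block-specific category probabilities, which are then re-estimated as
#' smoothed frequencies (pseudo-count 0.5 per category).  The best of
#' `n_restarts` random initializations is returned; a fixed seed gives an
#' identical fit.
#'
#' @param M Categorical matrix (values in -1/0/+1), genes x patients.
#' @param n_row_clusters,n_col_clusters Gene- and patient-side cluster
#'   counts (defaults 3).
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Maximum CEM iterations per restart (default 200).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param seed Integer seed.
#' @return `lbm_fit` list: `row_clusters`, `col_clusters`, `theta`
#'   (L x K x 3 over categories -1/0/+1), `prop_rows`, `prop_cols`,
#'   `loglik`, `loglik_trace`, `n_restarts`, `seed`.
#' @export
lbm_cocluster <- function(M, n_row_clusters = 3, n_col_clusters = 3,
                          n_restarts = 20, max_iter = 200, tol = 1e-8,
                          seed = 1L) {
  stopifnot(all(M %in% c(-1L, 0L, 1L)))
  L <- n_row_clusters; K <- n_col_clusters
  if (L > nrow(M) || K > ncol(M))
    stop("config error: more clusters than rows/columns")
  if (nrow(unique(M)) < 2 || ncol(M) < 2)
    if (L > 1 || K > 1)
      stop("degenerate matrix: need >= 2 distinct rows and columns")
  Mcat <- M + 2L  # categories 1..3 for -1/0/+1
  ncat <- 3L
  nr <- nrow(M); nc <- ncol(M)
  Mc <- lapply(seq_len(ncat), function(c) (Mcat == c) * 1)

  run_restart <- function() {
    z <- sample.int(L, nr, replace = TRUE)
    w <- sample.int(K, nc, replace = TRUE)
    # guarantee non-empty start
    z[sample.int(nr, L)] <- seq_len(L)
    w[sample.int(nc, K)] <- seq_len(K)
    ll_old <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      nklc <- lbm_counts(Mcat, z, w, L, K, ncat)
      tot <- apply(nklc, c(1, 2), sum)
      theta <- sweep(nklc + 0.5, c(1, 2), tot + 0.5 * ncat, "/")
      log_theta <- log(theta)
      log_pr <- log(tabulate(z, L) + 0.5) - log(nr + 0.5 * L)
      log_pc <- log(tabulate(w, K) + 0.5) - log(nc + 0.5 * K)

      # row step: S[i, l] = sum_c (Mc %*% Wi)[i, k] log_theta[l, k, c]
      Wi <- matrix(0, nc, K); Wi[cbind(seq_len(nc), w)] <- 1
      S <- matrix(rep(log_pr, each = nr), nr, L)
      for (c in seq_len(ncat))
        S <- S + (Mc[[c]] %*% Wi) %*% t(log_theta[, , c])
      z <- max.col(S, ties.method = "first")
      z <- fix_empty(z, S, L)

      # column step
      Zi <- matrix(0, nr, L); Zi[cbind(seq_len(nr), z)] <- 1
      Sc <- matrix(rep(log_pc, each = nc), nc, K)
      for (c in seq_len(ncat))
        Sc <- Sc + t(Mc[[c]]) %*% Zi %*% log_theta[, , c]
      w <- max.col(Sc, ties.method = "first")
      w <- fix_empty(w, Sc, K)

      nklc <- lbm_counts(Mcat, z, w, L, K, ncat)
      ll <- lbm_loglik(nklc, z, w, log_theta, log_pr, log_pc)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    list(z = z, w = w, loglik = ll_old, trace = trace)
  }

  best <- withr::with_seed(as.integer(seed), {
    fits <- lapply(seq_len(n_restarts), function(r) run_restart())
    fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  })
  nklc <- lbm_counts(Mcat, best$z, best$w, L, K, ncat)
  tot <- apply(nklc, c(1, 2), sum)
  theta <- sweep(nklc + 0.5, c(1, 2), tot + 0.5 * ncat, "/")
  dimnames(theta) <- list(NULL, NULL, c("-1", "0", "1"))
  fit <- list(row_clusters = stats::setNames(best$z, rownames(M)),
              col_clusters = stats::setNames(best$w, colnames(M)),
              theta = theta,
              prop_rows = tabulate(best$z, L) / nr,
              prop_cols = tabulate(best$w, K) / nc,
              loglik = best$loglik,
              loglik_trace = best$trace,
              n_restarts = n_restarts,
              seed = as.integer(seed),
              M = M)
  class(fit) <- "lbm_fit"
  fit
}

# reseed empty clusters with the worst-fitting element (documented fallback)
fix_empty <- function(assign, scores, K) {
  for (k in seq_len(K)) {
    if (!any(assign == k)) {
      fit_of_own <- scores[cbind(seq_along(assign), assign)]
      movable <- which(tabulate(assign, K)[assign] > 1)
      worst <- movable[which.min(fit_of_own[movable])]
      assign[worst] <- k
    }
  }
  assign
}

#' Canonical patient group labels from a block-model fit
#'
#' Patient clusters are relabelled PG0..PG(K-1) in ascending order of the
#' mean number of up-regulated (+1) cells per patient, so the
#' up-regulation-rich cluster always receives the highest index regardless
#' of the arbitrary cluster numbering of the fit.
#'
#' @param fit An `lbm_fit` from [lbm_cocluster()].
#' @return `data.frame` with patient_id and group (`PG0`, `PG1`, ...);
#'   group sizes in `attr(, "sizes")`.
#' @export
assign_groups <- function(fit) {
  w <- fit$col_clusters
  up_per_patient <- colSums(fit$M == 1L)
  K <- max(w)
  mean_up <- vapply(seq_len(K),
                    function(k) mean(up_per_patient[w == k]), numeric(1))
  mean_up[is.nan(mean_up)] <- Inf  # empty clusters sort last
  new_label <- stats::setNames(order(order(mean_up)) - 1L, seq_len(K))
  group <- paste0("PG", new_label[w])
  out <- data.frame(patient_id = names(w), group = group,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "sizes") <- table(out$group)
  out
}

#' Deterministic heatmap orderings
#'
#' Complete-linkage agglomerative orderings of rows and columns for display.
#'
#' @param M Numeric matrix.
#' @param method Linkage (default `"complete"`).
#' @return List with `row_order` and `col_order` index permutations.
#' @export
order_heatmap <- function(M, method = "complete") {
  ord <- function(X) {
    if (nrow(X) < 3) return(seq_len(nrow(X)))
    stats::hclust(stats::dist(X), method = method)$order
  }
  list(row_order = ord(M), col_order = ord(t(M)))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Cluster label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
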