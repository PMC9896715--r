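test_that("fold-change matrix echoes per-patient estimates with masking", {
  pp <- list(P1 = toy_de_table(c("a", "b"), c("up", "none"),
                               lfc = c(2.5, 0.1)),
             P2 = toy_de_table(c("a", "b"), c("down", "up"),
                               lfc = c(-1.7, 3.0)))
  M <- build_lfc_matrix(pp, c("a", "b"))
  expect_equal(M, matrix(c(2.5, 0.1, -1.7, 3.0), 2, 2,
                         dimnames = list(c("a", "b"), c("P1", "P2"))),
               ignore_attr = TRUE)
  expect_equal(colnames(M), names(pp))

  # gene absent for one patient: 0 with the mask bit set
  pp$P2 <- toy_de_table("a", "down", lfc = -1.7)
  M2 <- build_lfc_matrix(pp, c("a", "b"))
  expect_equal(M2["b", "P2"], 0)
  expect_true(attr(M2, "mask")["b", "P2"])
  expect_false(attr(M2, "mask")["a", "P2"])
})

test_that("categorical matrix maps calls to -1/0/+1 and preserves marginals", {
  pp <- list(P1 = toy_de_table(c("a", "b", "c"), c("up", "none", "down")))
  M <- categorize(pp, c("a", "b", "c"))
  expect_equal(unname(M[, 1]), c(1L, 0L, -1L))
  expect_true(all(M %in% c(-1L, 0L, 1L)))

  withr::with_seed(41, {
    genes <- paste0("g", 1:30)
    pp <- lapply(1:8, function(p)
      toy_de_table(genes, sample(c("up", "down", "none"), 30, TRUE)))
    names(pp) <- paste0("P", 1:8)
    M <- categorize(pp, genes)
    for (p in names(pp)) {
      expect_equal(sum(M[, p] == 1L), sum(pp[[p]]$call == "up"))
      expect_equal(sum(M[, p] == -1L), sum(pp[[p]]$call == "down"))
    }
  })
})

test_that("CEM recovers planted blocks and is found by exhaustive search", {
  # 6x6 matrix with 2x2 planted blocks of distinct categories
  M <- rbind(matrix(1L, 3, 6), matrix(0L, 3, 6))
  M[1:3, 4:6] <- -1L
  M[4:6, 4:6] <- 1L
  dimnames(M) <- list(paste0("g", 1:6), paste0("p", 1:6))
  fit <- lbm_cocluster(M, n_row_clusters = 2, n_col_clusters = 2,
                       n_restarts = 10, seed = 1)
  expect_equal(adjusted_rand_index(fit$row_clusters, rep(1:2, each = 3)), 1)
  expect_equal(adjusted_rand_index(fit$col_clusters, rep(1:2, each = 3)), 1)

  # brute force: enumerate every 2-cluster row/column partition and score
  # with the same smoothed-likelihood objective; CEM must attain the optimum
  score <- function(z, w) {
    n <- array(0, c(2, 2, 3))
    for (c in 1:3)
      for (k in 1:2) for (l in 1:2)
        n[k, l, c] <- sum((M + 2L)[z == k, w == l] == c)
    tot <- apply(n, c(1, 2), sum)
    th <- sweep(n + 0.5, c(1, 2), tot + 1.5, "/")
    pr <- (tabulate(z, 2) + 0.5) / (6 + 1)
    pc <- (tabulate(w, 2) + 0.5) / (6 + 1)
    sum(n * log(th)) + sum(log(pr)[z]) + sum(log(pc)[w]) +
      0.5 * sum(log(th)) + 0.5 * sum(log(pr)) + 0.5 * sum(log(pc))
  }
  parts <- lapply(1:31, function(b) 1L + as.integer(intToBits(b)[1:6]))
  best <- -Inf
  for (z in parts) for (w in parts) best <- max(best, score(z, w))
  got <- score(fit$row_clusters, fit$col_clusters)
  expect_equal(got, best, tolerance = 1e-9)
})

test_that("CEM objective is non-decreasing and seeded runs are identical", {
  pl <- planted_categorical(60, 24, modal_prob = 0.75, seed = 42)
  fit <- lbm_cocluster(pl$M, 3, 3, n_restarts = 5, seed = 3)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  fit2 <- lbm_cocluster(pl$M, 3, 3, n_restarts = 5, seed = 3)
  expect_identical(fit$col_clusters, fit2$col_clusters)
  expect_identical(fit$loglik, fit2$loglik)

  # theta rows are probability vectors
  expect_equal(unname(apply(fit$theta, c(1, 2), sum)),
               matrix(1, 3, 3), tolerance = 1e-12)

  # permuting row order changes bookkeeping, not the partition
  perm <- withr::with_seed(4, sample(nrow(pl$M)))
  fitp <- lbm_cocluster(pl$M[perm, ], 3, 3, n_restarts = 5, seed = 3)
  expect_equal(adjusted_rand_index(fitp$col_clusters, fit$col_clusters), 1)
})

test_that("degenerate all-zero matrix concentrates theta on category 0", {
  M <- matrix(0L, 4, 4, dimnames = list(paste0("g", 1:4), paste0("p", 1:4)))
  fit <- lbm_cocluster(M, 1, 1, n_restarts = 2, seed = 1)
  expect_gt(fit$theta[1, 1, "0"], 0.9)
  expect_lt(fit$theta[1, 1, "1"], 0.05)
})

test_that("planted patient groups are recovered at realistic sizes", {
  pl <- planted_categorical(300, 60, modal_prob = 0.8, seed = 44)
  fit <- lbm_cocluster(pl$M, 3, 3, n_restarts = 20, seed = 5)
  expect_gte(adjusted_rand_index(fit$col_clusters, pl$col_truth), 0.9)
})

test_that("canonical group labels order clusters by up-regulation richness", {
  # cluster A patients average fewer +1 cells than cluster B
  M <- cbind(matrix(0L, 20, 6),
             matrix(rbinom(20 * 6, 1, 0.9), 20, 6))
  dimnames(M) <- list(paste0("g", 1:20), paste0("p", 1:12))
  fit <- lbm_cocluster(M, 2, 2, n_restarts = 5, seed = 6)
  g <- assign_groups(fit)
  up_per_group <- tapply(colSums(M == 1L)[g$patient_id], g$group, mean)
  expect_true(up_per_group["PG0"] < up_per_group["PG1"])

  # relabelling fit clusters changes nothing after canonicalization
  fit_swapped <- fit
  fit_swapped$col_clusters <- 3L - fit$col_clusters
  fit_swapped$row_clusters <- 3L - fit$row_clusters
  g2 <- assign_groups(fit_swapped)
  expect_equal(g2$group, g$group)
})

test_that("heatmap orderings are permutations placing identical rows together", {
  M <- rbind(a = c(1, 1, 0), b = c(0, 5, 9), c = c(1, 1, 0), d = c(8, 0, 2))
  ord <- order_heatmap(M)
  expect_setequal(ord$row_order, 1:4)
  expect_setequal(ord$col_order, 1:3)
  pos <- match(c(1, 3), ord$row_order)  # identical rows a and c adjacent
  expect_equal(abs(diff(pos)), 1)
  expect_identical(order_heatmap(M), ord)  # deterministic
})
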