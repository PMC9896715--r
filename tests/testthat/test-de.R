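two_group_design <- function(n_per_group) {
  X <- cbind(1, rep(c(0, 1), each = n_per_group))
  colnames(X) <- c("(Intercept)", "grp")
  X
}

test_that("dispersion estimation recovers the generating regime", {
  withr::with_seed(21, {
    X <- two_group_design(25)
    # Poisson data: final dispersions collapse toward zero
    mp <- toy_counts(matrix(rpois(1000 * 50, exp(5)), 1000, 50))
    dp <- estimate_dispersions(mp, X, sf = rep(1, 50))
    expect_lte(median(dp$final), 0.01)
    # NB alpha = 0.2: gene-wise method-of-moments lands near the truth
    mn <- toy_counts(matrix(rnbinom(1000 * 50, mu = exp(5), size = 5),
                            1000, 50))
    dn <- estimate_dispersions(mn, X, sf = rep(1, 50))
    expect_gt(median(dn$genewise), 0.1)
    expect_lt(median(dn$genewise), 0.3)
  })
})

test_that("paired designs with no residual df use the trend alone", {
  withr::with_seed(22, {
    m <- toy_counts(matrix(rnbinom(200 * 3, mu = 100, size = 20), 200, 3))
    X <- cbind(1, c(0, 1, 1))
    d <- estimate_dispersions(m, X, sf = rep(1, 3), w = 0.5)
    expect_equal(d$w, 1)  # n - p = 1 forces pure trend
    expect_equal(d$final, d$trend, tolerance = 1e-12)
  })
})

test_that("Wald test is null-centred on flat genes and recovers planted fold changes", {
  withr::with_seed(23, {
    X <- two_group_design(5)
    flat <- toy_counts(matrix(rep(c(40, 55, 62, 47, 51), 2), nrow = 1))
    res <- wald_test_nb(flat, X, 0.05, sf = rep(1, 10))
    expect_lt(abs(res$log2fc), 0.01)
    expect_gt(res$pvalue, 0.9)

    ng <- 200
    cnt <- toy_counts(matrix(rnbinom(ng * 10,
                                     mu = rep(c(150, 600), each = ng * 5),
                                     size = 20), ng, 10))
    res <- wald_test_nb(cnt, X, rep(0.05, ng), sf = rep(1, 10))
    expect_gte(mean(abs(res$log2fc - 2) < 0.5), 0.9)
    expect_true(all(res$padj >= res$pvalue))
    # BH adjusted values are monotone in p-rank
    o <- order(res$pvalue)
    expect_true(all(diff(res$padj[o]) >= -1e-12))
  })
})

test_that("Wald p-values agree with an exact Poisson oracle in rank", {
  withr::with_seed(24, {
    ng <- 500
    lam <- exp(4)
    fold <- ifelse(runif(ng) < 0.3, 2, 1)
    c1 <- matrix(rpois(ng * 5, lam), ng, 5)
    c2 <- matrix(rpois(ng * 5, lam * fold), ng, 5)
    cnt <- toy_counts(cbind(c1, c2))
    res <- wald_test_nb(cnt, two_group_design(5), rep(1e-8, ng),
                        sf = rep(1, 10))
    # conditional binomial test: exact for two-group Poisson totals
    oracle <- vapply(seq_len(ng), function(g)
      binom.test(sum(c2[g, ]), sum(cnt[g, ]), 0.5)$p.value, numeric(1))
    expect_gte(cor(res$pvalue, oracle, method = "spearman"), 0.95)
  })
})

test_that("DE calls follow the padj and fold-change thresholds", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(1.5, -0.5, 3.0, -2.0),
                    padj = c(0.04, 0.04, 0.06, 0.01))
  out <- call_de(tab)
  expect_equal(out$call, c("up", "none", "none", "down"))
})

test_that("all-patients analysis recovers core genes and is order-invariant", {
  co <- simulate_cohort(sim_config(n_patients = 10, n_genes = 400, seed = 25))
  f <- filter_genes(co$counts)
  ap <- run_all_patients(f, co$samples)
  core_up <- intersect(names(co$truth$gene_class)[
    co$truth$gene_class == "CORE_UP"], ap$gene_id)
  core_down <- intersect(names(co$truth$gene_class)[
    co$truth$gene_class == "CORE_DOWN"], ap$gene_id)
  expect_gte(mean(ap$call[match(core_up, ap$gene_id)] == "up"), 0.8)
  expect_gte(mean(ap$call[match(core_down, ap$gene_id)] == "down"), 0.8)

  perm <- sample(ncol(f))
  ap2 <- run_all_patients(f[, perm], co$samples)
  expect_equal(ap2$log2fc, ap$log2fc, tolerance = 1e-6)
  expect_identical(ap2$call, ap$call)
})

test_that("per-patient analysis yields one table per eligible patient", {
  co <- simulate_cohort(sim_config(n_patients = 8, n_genes = 300, seed = 26))
  f <- filter_genes(co$counts)
  pp <- run_per_patient(f, co$samples)
  expect_length(pp, 8)
  expect_setequal(names(pp), unique(co$samples$patient_id))

  # a patient whose tumour counts equal the normal counts yields no calls
  pid <- co$samples$patient_id[1]
  idx <- which(co$samples$patient_id == pid)
  nidx <- idx[co$samples$sample_type[idx] == "normal"]
  sub <- f[, idx]
  sub[, ] <- f[, rep(nidx, length(idx))]  # all columns identical
  st <- co$samples[idx, ]
  ppx <- run_per_patient(sub, st)
  expect_true(all(ppx[[pid]]$call == "none"))

  # ineligible patients are skipped with a warning
  st2 <- co$samples[co$samples$patient_id %in% co$samples$patient_id[1:20], ]
  drop_t <- st2$sample_id[st2$sample_type == "tumour"][1]
  pid1 <- st2$patient_id[st2$sample_id == drop_t]
  keep <- st2$sample_id[!(st2$patient_id == pid1 &
                            st2$sample_type == "tumour" &
                            st2$sample_id != drop_t)]
  st3 <- st2[st2$sample_id %in% keep, ]  # pid1 left with 1 tumour sample
  expect_warning(run_per_patient(f[, st3$sample_id], st3), "skipping")
})

test_that("between-group contrast is estimable and sign-symmetric", {
  co <- simulate_cohort(sim_config(n_patients = 8, n_genes = 200, seed = 27,
                                   tumour_regions_range = 1:1))
  # 2 groups x >=2 patients x (1 tumour + 1 normal): rank check by design
  grp <- data.frame(patient_id = unique(co$samples$patient_id),
                    group = rep(c("PG0", "PG1"), 4))
  f <- filter_genes(co$counts)
  r01 <- run_between_groups(f, co$samples, grp, "PG0", "PG1")
  r10 <- run_between_groups(f, co$samples, grp, "PG1", "PG0")
  expect_equal(r01$log2fc, -r10$log2fc, tolerance = 1e-5)

  # identical tumour effects in both groups: few significant null genes
  expect_lte(mean(r01$padj < 0.05, na.rm = TRUE), 0.05)
})

test_that("all-patients engine tracks the established NB Wald implementation", {
  co <- simulate_cohort(sim_config(n_patients = 6, n_genes = 300, seed = 28))
  f <- filter_genes(co$counts)
  ours <- run_all_patients(f, co$samples)

  cd <- data.frame(patient = factor(co$samples$patient_id),
                   type = factor(co$samples$sample_type,
                                 levels = c("normal", "tumour")))
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    f[, co$samples$sample_id], cd, ~ patient + type))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, name = "type_tumour_vs_normal")

  expect_gte(cor(ours$log2fc, ref$log2FoldChange, use = "complete.obs"), 0.98)
  expect_gte(cor(ours$pvalue, ref$pvalue, method = "spearman",
                 use = "complete.obs"), 0.9)
  # size factors agree with the reference median-of-ratios implementation
  expect_equal(unname(size_factors(f)),
               unname(DESeq2::estimateSizeFactorsForMatrix(f)),
               tolerance = 1e-6)
})
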