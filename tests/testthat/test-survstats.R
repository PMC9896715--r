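test_that("Kaplan-Meier estimate matches the hand product-limit", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  # S = 2/3 on [1, 3), 0 at 3 (last subject at risk fails)
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 0)

  km0 <- km_estimate(c(5, 8, 2), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  km2 <- km_estimate(1:4, rep(1, 4))
  expect_equal(km2$surv, (4 - 1:4) / 4)  # (n - i) / n at each event
})

test_that("weighted log-rank vanishes for exchangeable groups and reduces to log-rank", {
  t1 <- c(3, 5, 8, 12, 20)
  ev <- c(1, 1, 0, 1, 1)
  res <- weighted_logrank(c(t1, t1), c(ev, ev), rep(c("A", "B"), each = 5))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # single event time: every weight is the same constant, so all flavours
  # give the same p
  tt <- c(4, 4, 9, 9)
  e1 <- c(1, 1, 0, 0)
  g <- c("A", "B", "A", "B")
  expect_equal(weighted_logrank(tt, e1, g, "logrank")$p,
               weighted_logrank(tt, e1, g, "modified_peto")$p,
               tolerance = 1e-12)
})

test_that("weighted log-rank matches a brute-force risk-set oracle", {
  # group A events at 1,2,3; group B at 10,11,12; no censoring
  time <- c(1, 2, 3, 10, 11, 12)
  event <- rep(1, 6)
  group <- rep(c("A", "B"), each = 3)

  oracle <- function(wfun) {
    et <- sort(unique(time[event == 1]))
    U <- 0; V <- 0; s <- 1
    for (t in et) {
      ni <- sum(time >= t)
      ni_a <- sum(time >= t & group == "A")
      di <- sum(time == t & event == 1)
      di_a <- sum(time == t & event == 1 & group == "A")
      w <- wfun(s, ni)
      U <- U + w * (di_a - di * ni_a / ni)
      if (ni > 1)
        V <- V + w^2 * di * (ni - di) / (ni - 1) * (ni_a / ni) * (1 - ni_a / ni)
      s <- s * (1 - di / ni)
    }
    U^2 / V
  }
  expect_equal(weighted_logrank(time, event, group, "logrank")$statistic,
               oracle(function(s, n) 1), tolerance = 1e-12)
  expect_equal(weighted_logrank(time, event, group, "peto")$statistic,
               oracle(function(s, n) s), tolerance = 1e-12)
  expect_equal(weighted_logrank(time, event, group, "modified_peto")$statistic,
               oracle(function(s, n) s * n / (n + 1)), tolerance = 1e-12)
})

test_that("Peto weight agrees with the survival package's rho = 1 test", {
  withr::with_seed(51, {
    for (i in 1:5) {
      n <- 40
      g <- rep(c(0, 1), each = n / 2)
      tt <- rexp(n, 1 / 300)
      cc <- runif(n, 0, 900)
      ev <- as.integer(tt <= cc)
      tm <- pmin(tt, cc)
      ours <- weighted_logrank(tm, ev, g, "peto")$statistic
      ref <- survival::survdiff(survival::Surv(tm, ev) ~ g, rho = 1)$chisq
      expect_equal(ours, unname(ref), tolerance = 1e-8)
    }
  })
})

test_that("K-group log-rank handles three groups with df = K - 1", {
  withr::with_seed(52, {
    g <- rep(c("A", "B", "C"), each = 30)
    tm <- rexp(90, 1 / c(100, 200, 400)[as.integer(factor(g))])
    res <- weighted_logrank(tm, rep(1, 90), g)
    expect_equal(res$df, 2)
    expect_lt(res$p, 0.01)
  })
})

test_that("Wilcoxon rank-sum covers exact, approximate and mirrored paths", {
  # exact path: all of x below all of y, one-sided
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), side = "less")
  expect_equal(r$p, 1 / choose(6, 3), tolerance = 1e-12)
  expect_match(r$method, "exact")
  # mirrored one-sided p
  r2 <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3), side = "greater")
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  # identical samples (ties force the normal approximation): p = 1
  r3 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), side = "two")
  expect_equal(r3$p, 1)
  expect_match(r3$method, "approximation")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Fisher 2x2 reproduces the published sex-by-group association", {
  # female/male by patient group
  res <- fisher_exact_2x2(rbind(c(4, 10), c(38, 26)))
  expect_lt(abs(res$p - 0.043), 0.001)
  # degenerate margin
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(5, 9)))$p, 1)
})

test_that("Fisher 2x2 equals full hypergeometric enumeration", {
  withr::with_seed(53, {
    for (i in 1:10) {
      tab <- matrix(rpois(4, 8) + 1, 2, 2)
      m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
      support <- max(0, k - n):min(k, m)
      probs <- dhyper(support, m, n, k)
      p_obs <- dhyper(tab[1, 1], m, n, k)
      oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
      expect_equal(fisher_exact_2x2(tab)$p, oracle, tolerance = 1e-9)
    }
  })
})

test_that("Monte-Carlo Fisher agrees with the exact 2x2 path and is seeded", {
  tab <- rbind(c(4, 10), c(38, 26))
  p_mc <- fisher_rxc(tab, n_mc = 20000, seed = 2)$p
  expect_lt(abs(p_mc - fisher_exact_2x2(tab)$p), 0.01)
  expect_identical(fisher_rxc(tab, n_mc = 5000, seed = 3)$p,
                   fisher_rxc(tab, n_mc = 5000, seed = 3)$p)
  # forced association
  expect_lte(fisher_rxc(diag(10, 3), n_mc = 5000, seed = 4)$p, 0.01)
})

test_that("chi-square independence matches the closed form and is symmetric", {
  res <- chisq_independence(rbind(c(30, 10), c(10, 30)))
  expect_equal(res$statistic, 20.0, tolerance = 1e-9)
  expect_equal(res$df, 1)
  same <- chisq_independence(rbind(c(5, 10), c(5, 10)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  tab <- rbind(c(12, 3, 7), c(2, 9, 4))
  expect_equal(chisq_independence(tab)$statistic,
               chisq_independence(t(tab)[, c(2, 1)])$statistic,
               tolerance = 1e-12)
})

test_that("goodness of fit returns the statistic and standardized residuals", {
  res <- chisq_gof(c(600, 250, 150), rep(1000 / 3, 3))
  expect_equal(res$statistic, 335.0, tolerance = 0.1)
  expect_equal(res$residuals, c(14.61, -4.56, -10.04), tolerance = 0.01)
  expect_equal(sum(res$residuals^2), res$statistic, tolerance = 1e-9)

  res0 <- chisq_gof(c(25, 25), c(25, 25))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$residuals, c(0, 0))
  expect_error(chisq_gof(c(0, 0)), "sum")
})

test_that("multiplicity corrections follow the step-up / scaling rules", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.3, 0.001, 0.02)
  expect_true(all(bh_fdr(p) >= p))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bonferroni(c(0.01, 0.2)), c(0.02, 0.4))
  expect_equal(bonferroni(c(1, 0.5)), c(1, 1))
})

test_that("covariate association picks tests by expected counts", {
  withr::with_seed(54, {
    grouping <- data.frame(patient_id = paste0("P", 1:60),
                           group = rep(c("PG0", "PG1"), each = 30))
    clinical <- data.frame(
      patient_id = paste0("P", 1:60),
      rfs_days = rexp(60, 1 / 400), recurrence_event = rbinom(60, 1, 0.5),
      sex = sample(c("f", "m"), 60, TRUE, prob = c(0.1, 0.9)),  # sparse cell
      stage = sample(c("I", "II", "III"), 60, TRUE),
      afp = rlnorm(60, 3, 1))
    out <- associate_covariates(grouping, clinical)
    expect_setequal(out$variable, c("sex", "stage", "afp"))
    expect_equal(out$test[out$variable == "afp"], "wilcoxon")
    expect_true(out$test[out$variable == "sex"] %in% c("fisher", "chisq"))
    expect_true(all(out$p >= 0 & out$p <= 1, na.rm = TRUE))
  })
})
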