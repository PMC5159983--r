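test_that("Welch t-test matches its closed form and stats::t.test", {
  # identical groups: t = 0, p = 1
  r <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # worked example: a = 1:4, b = 3:6 -> t = -2.191, df = 6 by the Welch
  # formula (equal group variances make Welch df = 2n - 2 here)
  r2 <- welch_ttest(1:4, 3:6)
  expect_equal(r2$t, -2.19089023, tolerance = 1e-7)
  expect_equal(r2$df, 6)

  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(3:15, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:15, 1), mean = runif(1, -1, 1))
    want <- t.test(a, b)
    got <- welch_ttest(a, b)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(want$parameter), tolerance = 1e-12)
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
    want_pooled <- t.test(a, b, var.equal = TRUE)
    got_pooled <- welch_ttest(a, b, var_equal = TRUE)
    expect_equal(got_pooled$t, unname(want_pooled$statistic), tolerance = 1e-12)
    expect_equal(got_pooled$p, want_pooled$p.value, tolerance = 1e-12)
  }
})

test_that("Welch p-value agrees with a permutation oracle", {
  set.seed(29)
  a <- rnorm(8, 0.3); b <- rnorm(9)
  got <- welch_ttest(a, b)
  pool <- c(a, b)
  n <- length(a)
  tstat <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }
  perm <- replicate(1e5, abs(tstat(sample(length(pool), n))))
  p_perm <- mean(perm >= abs(got$t))
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / 1e5)
  expect_lt(abs(got$p - p_perm), mc_err + 0.02)
})

test_that("degenerate zero-variance groups follow the declared conventions", {
  r_eq <- welch_ttest(c(2, 2, 2), c(2, 2))
  expect_equal(r_eq$p, 1)
  expect_true(r_eq$degenerate)
  r_ne <- welch_ttest(c(2, 2, 2), c(3, 3))
  expect_equal(r_ne$p, 0)
  expect_true(r_ne$degenerate)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("bh_fdr reproduces the textbook step-up rule", {
  r1 <- bh_fdr(0.01)
  expect_equal(r1$q, 0.01)
  expect_true(r1$rejected)
  expect_false(any(bh_fdr(rep(1, 10))$rejected))
  r3 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(r3$rejected))  # largest i with p_(i) <= 0.05 i/4 is i = 4
  expect_equal(length(bh_fdr(numeric(0))$q), 0L)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- bh_fdr(p)
    want <- bh_stepup_oracle(p)
    expect_equal(got$q, want$q, tolerance = 1e-12)
    expect_equal(got$rejected, want$rejected)
  }
})

test_that("feature_scan tests per feature, skips degenerate rows, ranks hits", {
  set.seed(59)
  vals <- matrix(rnorm(20 * 10, 80, 2), 20,
                 dimnames = list(sprintf("f%d", 1:20), NULL))
  groups <- rep(c("ASD", "TD"), each = 5)
  vals[3, groups == "ASD"] <- vals[3, groups == "ASD"] + 30  # planted
  vals[7, groups == "ASD"] <- NA  # entirely missing in one group
  vals[9, ] <- 50  # zero variance in both groups
  res <- feature_scan(vals, groups, "HMD")
  expect_s3_class(res, "feature_stat_table")
  expect_equal(res$feature_id[1], "f3")  # planted feature ranks first
  expect_equal(attr(res, "n_skipped"), 2L)
  expect_setequal(attr(res, "skipped_ids"), c("f7", "f9"))
  expect_equal(nrow(res), 18L)
  # per-feature results equal the scalar Welch test
  for (fid in c("f1", "f3", "f12")) {
    want <- welch_ttest(vals[fid, groups == "ASD"], vals[fid, groups == "TD"])
    row <- res[res$feature_id == fid, ]
    expect_equal(row$t, want$t, tolerance = 1e-12)
    expect_equal(row$p, want$p, tolerance = 1e-12)
  }
  # q values are BH within this family
  ord <- match(res$feature_id, res$feature_id)
  expect_equal(res$q, bh_stepup_oracle(res$p)$q, tolerance = 1e-12)
  expect_equal(res$rejected, res$q <= 0.05)
})

test_that("a null cohort scan keeps the empirical FDR near its level", {
  set.seed(61)
  fdrs <- replicate(60, {
    sim <- simulate_domain_matrix(150, n_a = 12, n_b = 12)
    res <- feature_scan(sim$values, sim$groups, "HMD")
    n_rej <- sum(res$rejected)
    if (n_rej == 0) 0 else 1  # all rejections are false under the null
  })
  se <- sqrt(0.05 * 0.95 / 60)
  expect_lte(mean(fdrs), 0.05 + 3 * se)
})

test_that("chromstate_profile averages per CpG then per sample then per group", {
  g <- c(auto1 = 10000)
  elements <- data.frame(chrom = "auto1", start = c(0, 5000),
                         end = c(1000, 6000), state = c("TssA", "Het"))
  t1 <- cpg_track(data.frame(chrom = "auto1", pos = c(10, 20),
                             meth = c(1, 2), total = c(5, 5)), "s1", g)
  t2 <- cpg_track(data.frame(chrom = "auto1", pos = c(10, 5500),
                             meth = c(3, 1), total = c(5, 2)), "s2", g)
  groups <- c(s1 = "TD", s2 = "ASD")
  pr <- chromstate_profile(list(s1 = t1, s2 = t2), elements, groups)
  # element 1 in s1: mean of 1/5 and 2/5 = 0.3 (per-CpG mean, not pooled)
  expect_equal(pr$per_sample[1, "s1"], 0.3)
  expect_equal(pr$per_sample[1, "s2"], 0.6)
  expect_equal(pr$elements$mean_TD[1], 0.3)
  expect_equal(pr$elements$mean_ASD[1], 0.6)
  expect_true(is.na(pr$per_sample[2, "s1"]))  # element with no covered CpG

  # identical data in both groups gives identical box summaries
  pr2 <- chromstate_profile(list(s1 = t1, s2 = t1), elements, groups)
  tdrow <- pr2$states[pr2$states$group == "TD", -2]
  asdrow <- pr2$states[pr2$states$group == "ASD", -2]
  rownames(tdrow) <- rownames(asdrow) <- NULL
  expect_equal(tdrow, asdrow)
})

test_that("chromstate element values equal a brute-force double loop", {
  set.seed(67)
  g <- c(auto1 = 1e5)
  elements <- data.frame(chrom = "auto1", start = seq(0, 9e4, 1e4),
                         end = seq(0, 9e4, 1e4) + 4000,
                         state = rep(c("Enh", "Quies"), 5))
  tracks <- setNames(lapply(1:3, function(i) random_track(150, g,
                                                          sprintf("s%d", i))),
                     sprintf("s%d", 1:3))
  groups <- setNames(c("ASD", "TD", "ASD"), names(tracks))
  pr <- chromstate_profile(tracks, elements, groups)
  for (s in names(tracks)) {
    tr <- tracks[[s]]
    for (e in seq_len(nrow(elements))) {
      sel <- tr$pos >= elements$start[e] & tr$pos < elements$end[e] &
        tr$total > 0
      if (!any(sel)) {
        expect_true(is.na(pr$per_sample[e, s]))
      } else {
        expect_equal(pr$per_sample[e, s], mean(tr$meth[sel] / tr$total[sel]))
      }
    }
  }
})

test_that("univariate regressions recover exact slopes on the declared unit scale", {
  set.seed(131)
  x <- c(1, 2, 3, 4, 5, 6)
  # near-exact linear response (tiny noise keeps the fit non-degenerate)
  responses <- data.frame(pmd_mean = 2 * x + rnorm(6, 0, 1e-8))
  predictors <- data.frame(covar = x)
  rep <- univariate_regressions(responses, predictors,
                                units = c(pmd_mean = 5))
  # slope 2 on the raw percent scale = 0.4 in 5-percentage-point units
  expect_equal(rep$estimate, 0.4, tolerance = 1e-6)
  expect_lt(rep$p, 1e-10)
})

test_that("regression coefficients and HC1 intervals match matrix oracles", {
  set.seed(71)
  n <- 47
  predictors <- data.frame(run = factor(sample(c("r1", "r2"), n, TRUE)),
                           coverage = runif(n, 1, 2),
                           diagnosis = factor(sample(c("TD", "ASD"), n, TRUE),
                                              levels = c("TD", "ASD")))
  y_pct <- 55 + 2 * predictors$coverage + rnorm(n, 0, 1) *
    (1 + predictors$coverage)  # heteroscedastic
  responses <- data.frame(pmd_mean = y_pct)
  rep <- univariate_regressions(responses, predictors,
                                units = c(pmd_mean = 5),
                                adjust = list(pmd_mean = "coverage"))
  # the coverage row equals the normal-equations solution
  row <- rep[rep$predictor == "coverage" & is.na(rep$adjusted_for), ]
  X <- cbind(1, predictors$coverage)
  beta <- solve(crossprod(X), crossprod(X, y_pct / 5))
  expect_equal(row$estimate, unname(beta[2, 1]), tolerance = 1e-10)
  # HC1 robust CI matches the hand-computed sandwich
  V <- hc1_oracle(X, y_pct / 5)
  tq <- qt(0.975, n - 2)
  expect_equal(row$robust_se, sqrt(V[2, 2]), tolerance = 1e-10)
  expect_equal(row$robust_ci_lo, row$estimate - tq * sqrt(V[2, 2]),
               tolerance = 1e-10)
  # adjusted model: response ~ run + coverage
  arow <- rep[rep$predictor == "run" & !is.na(rep$adjusted_for), ]
  Xa <- model.matrix(~ run + coverage, predictors)
  betaa <- solve(crossprod(Xa), crossprod(Xa, y_pct / 5))
  expect_equal(arow$estimate, unname(betaa[2, 1]), tolerance = 1e-10)
  # rank-deficient designs are reported, naming the collinear column
  bad <- data.frame(coverage = predictors$coverage,
                    dup = predictors$coverage)
  expect_error(univariate_regressions(data.frame(pmd_mean = y_pct), bad,
                                      adjust = list(pmd_mean = "dup")),
               "collinear")
})

test_that("permuted predictors are rejected at no more than the nominal rate", {
  set.seed(73)
  n <- 30
  y <- rnorm(n, 60, 3)
  rej <- replicate(200, {
    rep <- univariate_regressions(data.frame(m = y),
                                  data.frame(x = rnorm(n)),
                                  units = c(m = 5))
    any(rep$rejected)
  })
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(rej), 0.05 + 3 * se)
})

test_that("AIC selection picks the parsimonious truth and ties break first", {
  set.seed(79)
  n <- 47
  picks <- replicate(100, {
    y <- rnorm(n, 5, 1)  # intercept-only truth
    noise <- rnorm(n)
    sel <- model_select_robust(y, data.frame(noise = noise),
                               list(intercept = character(0),
                                    with_noise = "noise"))
    sel$selected
  })
  expect_gt(mean(picks == "intercept"), 0.7)

  # identical candidates: deterministic tie-break to the first declared
  x <- rnorm(20); y <- 1 + x + rnorm(20)
  dup <- model_select_robust(y, data.frame(a = x, b = x),
                             list(first = "a", second = "b"))
  expect_equal(dup$selected, "first")
})

test_that("model AIC values and robust intervals match direct formulas", {
  set.seed(83)
  n <- 40
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- 2 + 0.5 * d$x1 + rnorm(n)
  sel <- model_select_robust(y, d, list(m1 = "x1", m2 = c("x1", "x2")))
  aic1 <- AIC(lm(y ~ x1, data = d))
  aic2 <- AIC(lm(y ~ x1 + x2, data = d))
  expect_equal(sel$aic$aic, c(aic1, aic2), tolerance = 1e-10)
  # robust CI of the selected model equals the HC1 oracle
  Xs <- model.matrix(~ x1, d)
  V <- hc1_oracle(Xs, y)
  got <- sel$coefficients
  expect_equal(got$robust_se, unname(sqrt(diag(V))), tolerance = 1e-10)
  # HC1 AIC values computed under the Gaussian likelihood with the constant
  # counted: n_params = coefficients + error variance
  expect_equal(sel$aic$n_params, c(3, 4))
  # missing data would make candidate sample sets differ
  d2 <- d; d2$x2[1] <- NA
  expect_error(model_select_robust(y, d2, list(m1 = "x1",
                                               m2 = c("x1", "x2"))),
               "differing sample")
})

test_that("large-sample homoscedastic HC1 widths track the classical widths", {
  set.seed(89)
  n <- 1000
  x <- rnorm(n)
  y <- 1 + 0.3 * x + rnorm(n)
  sel <- model_select_robust(y, data.frame(x = x), list(m = "x"))
  fit <- lm(y ~ x)
  classical <- summary(fit)$coefficients["x", "Std. Error"]
  robust <- sel$coefficients$robust_se[sel$coefficients$term == "x"]
  expect_lt(abs(robust - classical) / classical, 0.10)
})

test_that("AICc applies the small-sample correction on top of AIC", {
  set.seed(97)
  n <- 15
  d <- data.frame(x1 = rnorm(n))
  y <- rnorm(n)
  plain <- model_select_robust(y, d, list(m0 = character(0), m1 = "x1"))
  corr <- model_select_robust(y, d, list(m0 = character(0), m1 = "x1"),
                              aicc = TRUE)
  k <- plain$aic$n_params
  expect_equal(corr$aic$aic, plain$aic$aic + 2 * k * (k + 1) / (n - k - 1))
})
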