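test_that("identical subjects pool to the common value with a zero contrast", {
  t <- hormone_times
  fits <- lapply(1:6, function(i) {
    s <- rhythm_series(t, make_cosine(t, 300, 160, 10),
                       subject_id = paste0("s", i),
                       group = if (i <= 3) "case" else "control",
                       marker = "cortisol")
    fit_cosinor(s)
  })
  # zero between-subject variance is the documented degenerate case: the
  # pooled values are exact and the per-outcome fallback is signalled
  expect_warning(
    pc <- pool_cosinor(subject_estimates(fits, center = 10)),
    class = "rhythmkit_pooling_fallback"
  )
  expect_equal(pc$groups$estimate[pc$groups$parameter == "mesor"],
               c(300, 300), tolerance = 1e-6)
  expect_equal(pc$groups$estimate[pc$groups$parameter == "amplitude"],
               c(160, 160), tolerance = 1e-6)
  expect_equal(pc$contrasts$B, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(unname(pc$significance_rate), c(100, 100))
})

test_that("multivariate REML agrees with an independent meta-analytic fitter", {
  skip_if_not_installed("metafor")
  cohort <- generate_hormone_cohort(cohort_spec(n_cases = 14, n_controls = 10,
                                                seed = 21))
  fits <- fit_cohort(cohort$measurements, "cortisol")
  est <- subject_estimates(fits)
  pc <- pool_cosinor(est)

  tab <- est$table
  yi <- c(t(as.matrix(tab[, c("mesor", "amplitude", "acrophase")])))
  outc <- factor(rep(c("m", "a", "p"), nrow(tab)), levels = c("m", "a", "p"))
  subj <- rep(tab$subject_id, each = 3)
  grp <- rep(as.numeric(tab$group == "case"), each = 3)
  V <- as.matrix(Matrix::bdiag(lapply(est$vcov, function(v) {
    v[!is.finite(v)] <- 0; v
  })))
  ok <- is.finite(yi)
  ref <- metafor::rma.mv(yi[ok] ~ 0 + outc[ok] + outc[ok]:grp[ok],
                         V = V[ok, ok], random = ~ outc[ok] | subj[ok],
                         struct = "UN", method = "REML",
                         control = list(iter.max = 1000, rel.tol = 1e-9))
  b <- coef(ref)
  ctr <- pc$groups[pc$groups$group == "control", ]
  expect_equal(ctr$estimate[ctr$parameter == "mesor"], unname(b[1]),
               tolerance = 1e-4)
  expect_equal(ctr$estimate[ctr$parameter == "amplitude"], unname(b[2]),
               tolerance = 1e-4)
  expect_equal(pc$contrasts$B[1:2], unname(b[4:5]), tolerance = 1e-4)
  expect_equal(pc$contrasts$B[3], unname(b[6]), tolerance = 1e-4)
})

test_that("relabelling the groups flips difference contrasts and inverts ratios", {
  fits <- make_stage2_estimates(10, 8, delta = c(40, -25, 1), seed = 5)
  pc1 <- pool_cosinor(subject_estimates(fits, center = 10))
  swapped <- lapply(fits, function(f) {
    f$group <- if (f$group == "case") "control" else "case"
    f
  })
  pc2 <- pool_cosinor(subject_estimates(swapped, center = 10))
  expect_equal(pc1$contrasts$B, -pc2$contrasts$B, tolerance = 1e-5)

  lg <- lapply(make_stage2_estimates(10, 8, delta = c(0.2, -0.4, 1),
                                     mu = c(3, 2, 10),
                                     sd_between = c(0.3, 0.2, 1),
                                     se_within = c(0.15, 0.1, 0.5), seed = 6),
               function(f) { f$log_scale <- TRUE; f })
  pr1 <- pool_cosinor(subject_estimates(lg, center = 10))
  lg2 <- lapply(lg, function(f) {
    f$group <- if (f$group == "case") "control" else "case"; f
  })
  pr2 <- pool_cosinor(subject_estimates(lg2, center = 10))
  amp1 <- pr1$contrasts$B[pr1$contrasts$parameter == "amplitude"]
  amp2 <- pr2$contrasts$B[pr2$contrasts$parameter == "amplitude"]
  expect_equal(pr1$contrasts$type[2], "ratio")
  expect_equal(amp1, 1 / amp2, tolerance = 1e-5)
})

test_that("pooled group means stay inside the hull of the subject estimates", {
  fits <- make_stage2_estimates(12, 9, seed = 9)
  est <- subject_estimates(fits, center = 10)
  pc <- pool_cosinor(est)
  for (g in c("case", "control")) {
    sub <- est$table[est$table$group == g, ]
    for (par in c("mesor", "amplitude")) {
      val <- pc$groups$estimate[pc$groups$group == g &
                                  pc$groups$parameter == par]
      expect_gte(val, min(sub[[par]]))
      expect_lte(val, max(sub[[par]]))
    }
  }
})

test_that("contrast CIs attain nominal coverage for a known mesor shift", {
  hits <- 0L
  n_rep <- 120
  for (r in seq_len(n_rep)) {
    fits <- make_stage2_estimates(20, 10, delta = c(50, 0, 0), seed = 4000 + r)
    pc <- pool_cosinor(subject_estimates(fits, center = 10))
    b <- pc$contrasts[pc$contrasts$parameter == "mesor", ]
    hits <- hits + (b$lower <= 50 && 50 <= b$upper)
  }
  # 99% binomial envelope around 0.95 at 120 replicates
  env <- 2.576 * sqrt(0.95 * 0.05 / n_rep)
  expect_gte(hits / n_rep, 0.95 - env)
  expect_lte(hits / n_rep, min(0.95 + env, 1))
})

test_that("confounder adjustment is accepted and keeps the true effect in the CI", {
  fits <- make_stage2_estimates(25, 15, delta = c(50, 0, 0), seed = 77)
  cov <- data.frame(subject_id = sprintf("s%03d", 1:40),
                    age = rnorm(40, 60, 8), sex = rbinom(40, 1, 0.7),
                    bmi = rnorm(40, 25, 4), egfr = rnorm(40, 75, 20),
                    alcohol = rpois(40, 3))
  est <- subject_estimates(fits, center = 10, covariates = cov)
  pc <- pool_cosinor(est, adjust = TRUE)
  expect_true(pc$adjusted)
  b <- pc$contrasts[pc$contrasts$parameter == "mesor", ]
  expect_gt(b$upper, 50 - 30)
  expect_lt(b$lower, 50 + 30)
})

test_that("pooling demands two groups of at least two subjects", {
  fits <- make_stage2_estimates(1, 5, seed = 2)
  expect_error(pool_cosinor(subject_estimates(fits, center = 10)),
               "at least 2 subjects")
})

test_that("log-scale estimates back-transform to medians and ratios", {
  r <- retransform_log(0, -0.1, 0.1)
  expect_equal(r$estimate, 1)
  expect_equal(r$lower, exp(-0.1), tolerance = 1e-12)
  expect_equal(r$upper, exp(0.1), tolerance = 1e-12)
  expect_equal(round(retransform_log(log(5.2) - log(8.8)), 1), 0.6)
  set.seed(8)
  l <- rnorm(50); u <- l + rexp(50)
  rt <- retransform_log(l, l, u)
  expect_true(all(rt$lower < rt$upper))
})

test_that("the cohort significance rate counts individually rhythmic subjects", {
  expect_equal(significance_rate(c(0.001, 0.001, 0.001)), 100)
  expect_equal(significance_rate(c(0.01, 0.2, 0.03, 0.8)), 50)
  expect_error(significance_rate(numeric(0)), "no fits")
  fits <- lapply(1:4, function(i) fit_cosinor(noisy_series(i, A = 8, sigma = 0.5)))
  expect_equal(significance_rate(fits), 100)
})

test_that("the significance rate of rhythm-free subjects stays near the test size", {
  null_fits <- lapply(1:800, function(i) {
    fit_cosinor(noisy_series(20000 + i, M = 10, A = 0, sigma = 1))
  })
  rate <- significance_rate(null_fits)  # percent
  env <- 100 * 2.576 * sqrt(0.05 * 0.95 / 800)
  expect_gte(rate, 5 - env)
  expect_lte(rate, 5 + env)
})
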