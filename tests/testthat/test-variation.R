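melatonin_lod <- assay_config(lod = 8, substitute = 4)

test_that("detection-limit substitution replaces strictly-below values only", {
  s <- rhythm_series(c(9, 13, 17, 21, 25, 29, 33),
                     c(6.5, 8.0, 12, 30, 120, 60, 7.9))
  out <- apply_lod(s, melatonin_lod)
  expect_equal(out$values, c(4, 8, 12, 30, 120, 60, 4))
  expect_equal(out$censored, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # idempotent
  out2 <- apply_lod(out, melatonin_lod)
  expect_identical(out2$values, out$values)
  expect_identical(out2$censored, out$censored)
  # substitute must sit below the limit
  expect_error(assay_config(lod = 8, substitute = 9), "substitute")
})

test_that("the censored count is monotone nonincreasing in the detection limit", {
  set.seed(10)
  vals <- rlnorm(20, log(15), 1)
  s <- rhythm_series(seq(1, 77, by = 4), vals)
  lods <- c(2, 5, 8, 12, 20)
  n_cens <- vapply(lods, function(l) {
    sum(apply_lod(s, assay_config(l))$censored)
  }, 0)
  expect_true(all(diff(n_cens) >= 0))  # higher limit censors at least as much
})

test_that("circadian variation is max/min and scale invariant", {
  s <- rhythm_series(c(9, 13, 17, 21, 25, 29, 33),
                     c(4, 4, 10, 40, 120, 60, 8),
                     censored = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                     subject_id = "p1", marker = "melatonin")
  v <- summarize_variation(s)
  expect_equal(v$minimum, 4)
  expect_equal(v$maximum, 120)
  expect_equal(v$circadian_variation, 30)
  expect_equal(v$n_below_lod, 2)
  expect_false(v$all_below_lod)

  const <- summarize_variation(rhythm_series(1:4, rep(7, 4)))
  expect_equal(const$circadian_variation, 1)

  k <- 3.7
  sk <- rhythm_series(s$times, k * s$values)
  expect_equal(summarize_variation(sk)$circadian_variation,
               v$circadian_variation)
  expect_error(summarize_variation(rhythm_series(1:4, c(-1, 2, 3, 4))),
               "positive")
})

test_that("an all-censored subject is flagged for downstream exclusion", {
  s <- rhythm_series(c(9, 13, 17, 21, 25, 29, 33), c(7, 6, 5, 3, 2, 1, 7.5))
  out <- apply_lod(s, melatonin_lod)
  expect_true(all(out$censored))
  expect_true(summarize_variation(out)$all_below_lod)
})

test_that("Firth slope on a separated 2x2 equals the half-cell-corrected log odds ratio", {
  # x = 1 rows are all events: a zero cell, so the unpenalized MLE diverges
  d <- data.frame(y = c(rep(0, 7), rep(1, 3), rep(1, 8)),
                  x = c(rep(0, 10), rep(1, 8)))
  fit <- firth_logistic(y ~ x, d)
  co <- fit$coefficients
  haldane <- log((8.5 * 7.5) / (0.5 * 3.5))
  expect_equal(co$estimate[co$term == "x"], haldane, tolerance = 1e-4)
  expect_true(all(is.finite(co$estimate)))
  expect_true(all(is.finite(co$lower) & is.finite(co$upper)))
})

test_that("Firth shrinks the slope of non-separated data toward zero", {
  d <- data.frame(y = c(0, 0, 0, 1, 0, 1, 1, 1, 0, 1),
                  x = c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0))
  firth <- firth_logistic(y ~ x, d)$coefficients
  mle <- glm(y ~ x, binomial, d)$coefficients
  b_f <- firth$estimate[firth$term == "x"]
  expect_lt(abs(b_f), abs(unname(mle["x"])))
  expect_gt(b_f * unname(mle["x"]), 0)  # same sign
})

test_that("Firth estimates stay finite on random separated designs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    x <- rnorm(n)
    y <- as.numeric(x > quantile(x, runif(1, 0.2, 0.8)))  # complete separation
    fit <- firth_logistic(y ~ x, data.frame(y = y, x = x))
    expect_true(all(is.finite(fit$coefficients$estimate)))
    expect_true(all(fit$coefficients$se < 1e3))
  }
  expect_error(firth_logistic(y ~ x, data.frame(y = rep(1, 8), x = rnorm(8))),
               "constant")
})

test_that("a 9 vs 61 detectable split with a group covariate yields finite CIs", {
  set.seed(33)
  group <- rep(c(1, 0), c(46, 24))
  y <- numeric(70)
  y[group == 0] <- 0                      # every control reaches the limit
  y[group == 1] <- rbinom(46, 1, 9 / 46)  # ~9 detectable minima, all in cases
  y <- y * 0; y[sample(which(group == 1), 9)] <- 1
  fit <- firth_logistic(y ~ group, data.frame(y = y, group = group))
  co <- fit$coefficients[fit$coefficients$term == "group", ]
  expect_true(is.finite(co$estimate) && is.finite(co$lower) && is.finite(co$upper))
  expect_lt(co$upper - co$lower, 50)
})

test_that("profile-penalized intervals bracket the estimate and cover the Wald ones' role", {
  d <- data.frame(y = c(rep(0, 7), rep(1, 3), rep(1, 8)),
                  x = c(rep(0, 10), rep(1, 8)))
  wald <- firth_logistic(y ~ x, d, ci = "wald")$coefficients
  prof <- firth_logistic(y ~ x, d, ci = "profile")$coefficients
  expect_true(all(prof$lower < prof$estimate & prof$estimate < prof$upper))
  # profile CI is asymmetric under sparse data but of comparable magnitude
  expect_lt(abs(log((prof$upper[2] - prof$lower[2]) /
                      (wald$upper[2] - wald$lower[2]))), log(3))
})

test_that("adjusted regression reduces to the group mean difference when orthogonal", {
  set.seed(12)
  g <- rep(0:1, each = 15)
  y <- 3 + 2 * g + rnorm(30)
  conf <- data.frame(z1 = rep(rnorm(15), 2), z2 = rep(runif(15), 2))
  fit <- adjusted_regression(y, g, NULL)
  expect_equal(fit$B, mean(y[g == 1]) - mean(y[g == 0]), tolerance = 1e-10)
  # exactly balanced confounders leave the group coefficient untouched
  fit2 <- adjusted_regression(y, g, conf)
  expect_equal(fit2$B, fit$B, tolerance = 1e-10)
})

test_that("adjusted regression CIs cover a known group effect", {
  hits <- 0L
  for (r in 1:200) {
    set.seed(6000 + r)
    g <- rep(0:1, each = 30)
    conf <- data.frame(age = rnorm(60, 60, 10), bmi = rnorm(60, 25, 4))
    y <- 2 * g + 0.05 * conf$age + rnorm(60)
    fit <- adjusted_regression(y, g, conf)
    hits <- hits + (fit$lower <= 2 && 2 <= fit$upper)
  }
  env <- 2.576 * sqrt(0.95 * 0.05 / 200)
  expect_gte(hits / 200, 0.95 - env)
  expect_lte(hits / 200, min(1, 0.95 + env))
})

test_that("log-transformed regression recovers a true ratio", {
  set.seed(99)
  g <- rep(0:1, each = 60)
  y <- exp(log(20) + log(0.5) * g + rnorm(120, 0, 0.4))
  fit <- adjusted_regression(y, g, transform = "log")
  expect_equal(fit$type, "multiplication factor")
  expect_equal(fit$B, 0.5, tolerance = 0.12)
  # +1 offset rule admits zeros
  y0 <- pmax(round(y - 15), 0)
  fit0 <- adjusted_regression(y0, g, transform = "log1p")
  expect_true(is.finite(fit0$B))
})

test_that("missing covariate rows are dropped listwise with a note", {
  g <- rep(0:1, each = 10)
  y <- rnorm(20)
  conf <- data.frame(z = c(NA, rnorm(18), NA))
  expect_message(fit <- adjusted_regression(y, g, conf), "2 row")
  expect_equal(fit$n_used, 18)
  expect_error(adjusted_regression(y, g, data.frame(z = g)), "collinear")
})

test_that("dip classification respects the 10% boundary and partitions subjects", {
  # mean day/night systolic profile: 104 vs 98 -> 5.8% fall, non-dipper
  r <- classify_dip(c(10, 14, 18, 22 - 1e-9, 2, 4), c(104, 104, 104, 104, 98, 98))
  expect_equal(r$dip_fraction, (104 - 98) / 104, tolerance = 1e-12)
  expect_equal(r$class, "non_dipper")
  # exactly 10% fall counts as dipper ("at least 10%")
  r10 <- classify_dip(c(10, 14, 2, 4), c(100, 100, 90, 90))
  expect_equal(r10$class, "dipper")
  riser <- classify_dip(c(10, 14, 2, 4), c(95, 95, 100, 100))
  expect_equal(riser$class, "riser")
  expect_error(classify_dip(c(10, 14), c(1, 2)), "night")

  abpm <- generate_abpm(n = 24, seed = 4)
  ds <- dip_summary(abpm)
  fr <- attr(ds, "fractions")
  expect_true(all(abs(rowSums(fr[, c("dipper", "non_dipper", "riser")]) - 100) < 1e-9))
})
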