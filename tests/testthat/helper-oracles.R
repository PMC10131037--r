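# Independent oracles and fixture builders used across the suite.

make_cosine <- function(times, M, A, phi, period = 24) {
  M + A * cos(2 * pi / period * (times - phi))
}

hormone_times <- c(9, 13, 17, 21, 25, 29, 33)

noisy_series <- function(seed, M = 20, A = 6, phi = 3, sigma = 1,
                         times = hormone_times) {
  set.seed(seed)
  rhythm_series(times, make_cosine(times, M, A, phi) +
                  rnorm(length(times), 0, sigma))
}

# Brute-force grid search over (M, A, phi) for the cosinor SSE minimum:
# three refinement stages ending at 1e-4 resolution around the running
# optimum.  Fully independent of the closed-form least-squares path.
grid_search_sse <- function(times, values, period = 24) {
  w <- 2 * pi / period
  Sy <- sum(values); Syy <- sum(values^2); n <- length(values)
  sse_grid <- function(M_grid, A_grid, phi_grid) {
    best <- c(sse = Inf, M = NA, A = NA, phi = NA)
    for (phi in phi_grid) {
      cvec <- cos(w * (times - phi))
      S1 <- sum(cvec^2); S2 <- sum(values * cvec); S3 <- sum(cvec)
      for (A in A_grid) {
        # sse over the M grid, expanded quadratic form
        sse <- Syy + A^2 * S1 + n * M_grid^2 - 2 * A * S2 -
          2 * M_grid * Sy + 2 * A * M_grid * S3
        j <- which.min(sse)
        if (sse[j] < best["sse"]) {
          best <- c(sse = sse[j], M = M_grid[j], A = A, phi = phi)
        }
      }
    }
    best
  }
  rng <- diff(range(values))
  best <- sse_grid(seq(min(values), max(values), length.out = 80),
                   seq(0, rng, length.out = 80),
                   seq(0, period, length.out = 241)[-241])
  for (step in c(0.01, 1e-3, 1e-4)) {
    span <- step * 12
    best <- sse_grid(seq(best["M"] - span, best["M"] + span, by = step),
                     seq(max(best["A"] - span, 0), best["A"] + span, by = step),
                     seq(best["phi"] - span, best["phi"] + span, by = step))
  }
  best
}

# Independent ANOVA decomposition of the zero-amplitude F statistic:
# regression SS of the two centred harmonic covariates via explicitly
# solved 2x2 normal equations.
anova_F_oracle <- function(times, values, period = 24) {
  w <- 2 * pi / period
  x1 <- cos(w * times) - mean(cos(w * times))
  x2 <- sin(w * times) - mean(sin(w * times))
  yc <- values - mean(values)
  a11 <- sum(x1^2); a12 <- sum(x1 * x2); a22 <- sum(x2^2)
  b1 <- sum(x1 * yc); b2 <- sum(x2 * yc)
  det <- a11 * a22 - a12^2
  c1 <- (a22 * b1 - a12 * b2) / det
  c2 <- (a11 * b2 - a12 * b1) / det
  ss_reg <- c1 * b1 + c2 * b2
  ss_tot <- sum(yc^2)
  n <- length(values)
  (ss_reg / 2) / ((ss_tot - ss_reg) / (n - 3))
}

# vectorized null-F simulation at fixed design (shared across tests)
simulate_null_F <- function(n_rep, times = hormone_times, seed = 1) {
  set.seed(seed)
  w <- 2 * pi / 24
  X <- cbind(1, cos(w * times), sin(w * times))
  H <- X %*% solve(crossprod(X), t(X))
  n <- length(times)
  Y <- matrix(rnorm(n * n_rep), n, n_rep)
  fitted <- H %*% Y
  sse <- colSums((Y - fitted)^2)
  ss_tot <- colSums(scale(Y, scale = FALSE)^2)
  ((ss_tot - sse) / 2) / (sse / (n - 3))
}

# stage-2 fixture: per-subject parameter triples with known stage-1 noise,
# bypassing the curve-fitting stage (for pooling-only simulations)
make_stage2_estimates <- function(n_case, n_ctrl, delta = c(50, 0, 0),
                                  mu = c(300, 160, 10), sd_between = c(30, 20, 1),
                                  se_within = c(15, 10, 0.5), seed = 1) {
  set.seed(seed)
  n <- n_case + n_ctrl
  group <- rep(c("case", "control"), c(n_case, n_ctrl))
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- mu + (group[i] == "case") * delta +
      rnorm(3, 0, sd_between)
    est <- truth + rnorm(3, 0, se_within)
    fits[[i]] <- as_cosinor_fit(
      mesor = est[1], amplitude = max(est[2], 1e-3), acrophase = est[3] %% 24,
      se_mesor = se_within[1], se_amplitude = se_within[2],
      se_acrophase = se_within[3], n = 7,
      subject_id = sprintf("s%03d", i), group = group[i], marker = "synthetic"
    )
    fits[[i]]$p_value <- 0.01  # individually rhythmic by construction
    fits[[i]]$vcov <- NULL
  }
  fits
}
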