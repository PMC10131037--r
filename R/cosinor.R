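# Single-component cosinor kernel: least-squares fit of
#   Y(t) = M + A * cos(omega * (t - phi)),  omega = 2*pi/period,
# via the linearization Y = M + beta*cos(omega t) + gamma*sin(omega t),
# with delta-method standard errors and the zero-amplitude F test.

#' Construct a rhythm time series
#'
#' Container for one subject's timestamped measurements of a single marker.
#' Times are decimal hours since the first-sample midnight and may exceed 24
#' for series spanning midnight (use [unwrap_times()] on wrapped clock times).
#'
#' @param times Numeric vector of sampling times (decimal hours).
#' @param values Numeric vector of measurements, same length as `times`.
#' @param censored Logical vector flagging below-detection-limit values;
#'   defaults to all `FALSE`.
#' @param subject_id,group,marker Optional labels carried through the fit.
#' @param strict Require strictly increasing times (`TRUE` for single-subject
#'   series; pooled designs with replicate time points set this to `FALSE`).
#' @return An object of class `rhythm_series`.
#' @examples
#' rhythm_series(c(9, 13, 17, 21, 25, 29, 33), c(29, 4, 4, 13, 101, 152, 29))
#' @export
rhythm_series <- function(times, values, censored = NULL,
                          subject_id = NA_character_, group = NA_character_,
                          marker = NA_character_, strict = TRUE) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length")
  }
  if (length(times) < 4L) {
    stop("insufficient data: a rhythm series needs at least 4 observations")
  }
  if (anyNA(times) || any(!is.finite(times))) stop("`times` must be finite")
  if (anyNA(values) || any(!is.finite(values))) stop("`values` must be finite")
  if (strict && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing (see unwrap_times())")
  }
  censored <- censored %||% rep(FALSE, length(values))
  censored <- as.logical(censored)
  if (length(censored) != length(values)) stop("`censored` length mismatch")
  structure(
    list(times = times, values = values, censored = censored,
         subject_id = subject_id, group = group, marker = marker),
    class = "rhythm_series"
  )
}

#' @export
print.rhythm_series <- function(x, ...) {
  cat("rhythm series:", x$subject_id, "/", x$marker, "(", x$group, ")\n")
  cat("  n =", length(x$times), " span", min(x$times), "-", max(x$times), "h,",
      sum(x$censored), "censored\n")
  invisible(x)
}

#' Fit a single-component cosinor
#'
#' Least-squares fit of `Y = M + beta*cos(omega*t) + gamma*sin(omega*t)` with
#' `omega = 2*pi/period`. The amplitude is `A = sqrt(beta^2 + gamma^2)` and
#' the acrophase `phi = atan2(gamma, beta)/omega mod period` is the clock time
#' at which the fitted wave peaks. Standard errors for `A` and `phi` come from
#' the delta method applied to `cov(beta, gamma)`; rhythm detection uses the
#' zero-amplitude F test (see [zero_amplitude_test()]). Duplicate clock times
#' (e.g. the two 09:00 draws of a 24-h protocol, entered as t = 9 and t = 33)
#' are treated as independent replicates at the same phase.
#'
#' @param series A [rhythm_series()] object.
#' @param period Fixed period in hours (default 24; single harmonic only).
#' @param log_scale If `TRUE`, fit on `log(values)` (used for skewed markers
#'   such as melatonin and cardiac troponin); all values must be positive, and
#'   mesor/amplitude are then on the log scale (see [retransform_log()]).
#' @return An object of class `cosinor_fit` with elements `mesor`,
#'   `amplitude`, `acrophase`, `beta`, `gamma`, `period`, `omega`, `se`
#'   (named vector for mesor/amplitude/acrophase), `vcov` (3x3 covariance of
#'   `(M, beta, gamma)`), `F_stat`, `p_value`, `perfect_fit`, `phi_defined`,
#'   `n`, `sse`, `ss_total`, `log_scale` and the series labels.
#' @examples
#' t <- c(9, 13, 17, 21, 25, 29, 33)
#' y <- 10 + 3 * cos(2 * pi * (t - 4) / 24)
#' fit_cosinor(rhythm_series(t, y))
#' @export
fit_cosinor <- function(series, period = 24, log_scale = FALSE) {
  stopifnot(inherits(series, "rhythm_series"), period > 0)
  t <- series$times
  y <- series$values
  n <- length(y)
  if (n < 4L) stop("insufficient data: cosinor fit needs at least 4 observations")
  if (log_scale) {
    if (any(y <= 0)) {
      stop("log_scale = TRUE requires strictly positive values")
    }
    y <- log(y)
  }
  omega <- 2 * pi / period
  X <- cbind(mesor = 1, beta = cos(omega * t), gamma = sin(omega * t))
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    stop("degenerate sampling design: cosine and sine covariates are collinear")
  }
  coefs <- qr.coef(qrX, y)
  fitted <- drop(X %*% coefs)
  res <- y - fitted
  sse <- sum(res^2)
  ss_total <- sum((y - mean(y))^2)
  df_res <- n - 3L
  scale_y <- max(abs(y), 1)
  perfect <- sse <= 1e-12 * max(ss_total, scale_y^2)
  sigma2 <- if (perfect) 0 else sse / df_res
  XtXinv <- chol2inv(qr.R(qrX))
  vc <- sigma2 * XtXinv
  dimnames(vc) <- list(colnames(X), colnames(X))

  M <- unname(coefs[1]); beta <- unname(coefs[2]); gamma <- unname(coefs[3])
  A <- sqrt(beta^2 + gamma^2)
  phi_defined <- A > 1e-10 * scale_y
  phi <- if (phi_defined) (atan2(gamma, beta) / omega) %% period else NA_real_

  se_M <- sqrt(vc[1, 1])
  if (A > 0) {
    # delta method on (beta, gamma) -> (A, phi)
    se_A <- sqrt((beta^2 * vc[2, 2] + gamma^2 * vc[3, 3] +
                    2 * beta * gamma * vc[2, 3]) / A^2)
    var_phi_rad <- (gamma^2 * vc[2, 2] + beta^2 * vc[3, 3] -
                      2 * beta * gamma * vc[2, 3]) / A^4
    se_phi <- sqrt(var_phi_rad) / omega
    if (!is.finite(se_A) || (se_A > 0 && A / se_A < 1e-6)) se_phi <- NaN
  } else {
    se_A <- sqrt((vc[2, 2] + vc[3, 3]) / 2)  # direction-averaged bound
    se_phi <- NaN
  }
  if (!phi_defined) se_phi <- NaN

  fit <- structure(
    list(mesor = M, amplitude = A, acrophase = phi,
         beta = beta, gamma = gamma, period = period, omega = omega,
         se = c(mesor = se_M, amplitude = se_A, acrophase = se_phi),
         vcov = vc, n = n, sse = sse, ss_total = ss_total,
         df_residual = df_res, log_scale = log_scale,
         phi_defined = phi_defined, perfect_fit = perfect,
         subject_id = series$subject_id, group = series$group,
         marker = series$marker),
    class = "cosinor_fit"
  )
  zt <- zero_amplitude_test(fit)
  fit$F_stat <- zt$F
  fit$p_value <- zt$p
  fit$perfect_fit <- zt$perfect_fit
  fit
}

#' Build a cosinor fit from known parameter values
#'
#' Constructs a `cosinor_fit` object directly from mesor/amplitude/acrophase
#' values (and optional standard errors), e.g. to feed published group-level
#' estimates into [compare_groups()] or the report layer without raw data.
#'
#' @param mesor,amplitude,acrophase Parameter values (acrophase in hours).
#' @param se_mesor,se_amplitude,se_acrophase Standard errors (default `NA`).
#' @param n Sample size behind the estimates, if known.
#' @param period Period in hours.
#' @param log_scale Whether the mesor/amplitude are on a log scale.
#' @param p_value Zero-amplitude test p value, if known.
#' @param ... Labels (`subject_id`, `group`, `marker`, `species`, `organ`,
#'   `gene`) stored on the object.
#' @return A `cosinor_fit` object (without residual information).
#' @examples
#' as_cosinor_fit(mesor = 331.9, amplitude = 165.5, acrophase = 10.1)
#' @export
as_cosinor_fit <- function(mesor, amplitude, acrophase,
                           se_mesor = NA_real_, se_amplitude = NA_real_,
                           se_acrophase = NA_real_, n = NA_integer_,
                           period = 24, log_scale = FALSE,
                           p_value = NA_real_, ...) {
  stopifnot(amplitude >= 0)
  omega <- 2 * pi / period
  phi <- if (is.na(acrophase)) NA_real_ else acrophase %% period
  structure(
    c(list(mesor = mesor, amplitude = amplitude, acrophase = phi,
           beta = amplitude * cos(omega * (if (is.na(phi)) 0 else phi)),
           gamma = amplitude * sin(omega * (if (is.na(phi)) 0 else phi)),
           period = period, omega = omega,
           se = c(mesor = se_mesor, amplitude = se_amplitude,
                  acrophase = se_acrophase),
           vcov = NULL, n = n, sse = NA_real_, ss_total = NA_real_,
           df_residual = NA_integer_, log_scale = log_scale,
           phi_defined = amplitude > 0 && !is.na(acrophase),
           perfect_fit = FALSE, F_stat = NA_real_, p_value = p_value),
      list(...)),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("cosinor fit (period", x$period, "h",
      if (isTRUE(x$log_scale)) ", log scale" else "", ")\n", sep = "")
  est <- c(mesor = x$mesor, amplitude = x$amplitude, acrophase = x$acrophase)
  tab <- cbind(estimate = est, se = x$se)
  print(round(tab, 4))
  if (!is.na(x$acrophase)) {
    cat("  peak at", format_clock(x$acrophase, wrap = TRUE), "\n")
  } else {
    cat("  acrophase undefined (zero amplitude)\n")
  }
  if (is.finite(x$F_stat %||% NA_real_)) {
    cat(sprintf("  zero-amplitude test: F(2, %d) = %.3f, p = %.4g%s\n",
                x$df_residual, x$F_stat, x$p_value,
                if (isTRUE(x$perfect_fit)) " (perfect fit)" else ""))
  }
  invisible(x)
}

#' Predicted cosinor curve
#'
#' @param object A `cosinor_fit`.
#' @param times Times (hours) at which to evaluate the fitted wave.
#' @param response If `TRUE` and the fit is on a log scale, exponentiate back
#'   to the measurement scale.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.cosinor_fit <- function(object, times, response = FALSE, ...) {
  mu <- object$mesor + object$beta * cos(object$omega * times) +
    object$gamma * sin(object$omega * times)
  if (response && isTRUE(object$log_scale)) mu <- exp(mu)
  mu
}

#' Zero-amplitude F test for rhythm detection
#'
#' Tests the joint nullity of the cosine/sine coefficients:
#' `F = ((SS_total - SS_residual)/2) / (SS_residual/(n - 3))`, referred to an
#' F distribution with `(2, n - 3)` degrees of freedom. A series is declared
#' rhythmic when the test rejects. A perfect fit (zero residual sum of
#' squares) reports `p = 0` with `perfect_fit = TRUE`.
#'
#' @param fit A `cosinor_fit` from [fit_cosinor()].
#' @return List with `F`, `p`, `df = c(2, n - 3)` and `perfect_fit`.
#' @export
zero_amplitude_test <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (!is.finite(fit$sse) || !is.finite(fit$ss_total)) {
    stop("fit carries no residual information (constructed from parameters?)")
  }
  n <- fit$n
  if (n < 4L) stop("zero-amplitude test needs n >= 4")
  df2 <- n - 3L
  ss_rhythm <- max(fit$ss_total - fit$sse, 0)
  if (fit$perfect_fit || fit$sse <= 1e-12 * max(fit$ss_total, 1)) {
    return(list(F = Inf, p = 0, df = c(2L, df2), perfect_fit = TRUE))
  }
  Fstat <- (ss_rhythm / 2) / (fit$sse / df2)
  list(F = Fstat, p = stats::pf(Fstat, 2, df2, lower.tail = FALSE),
       df = c(2L, df2), perfect_fit = FALSE)
}

#' Centre an acrophase in a 24-h window
#'
#' Maps a clock-hour acrophase into the half-open window of width 24 centred
#' at `center`, i.e. returns `phi + 24k` in `(center - 12, center + 12]`.
#' Centring makes pooled acrophases approximately normal on the linear scale
#' (e.g. troponin acrophases centred around 09:00).
#'
#' @param phi Acrophase(s) in hours, any real value (reduced mod 24).
#' @param center Window centre, clock hours in `[0, 24)`.
#' @return Numeric vector in `(center - 12, center + 12]`.
#' @examples
#' center_acrophase(23, center = 9)  # -1
#' @export
center_acrophase <- function(phi, center = 9) {
  stopifnot(is.numeric(phi), is.numeric(center), length(center) == 1L)
  d <- (phi - center) %% 24
  d[!is.na(d) & d > 12] <- d[!is.na(d) & d > 12] - 24
  center + d
}

#' Signed circular difference of two acrophases
#'
#' Minimal signed difference `phi1 - phi2` wrapped to `(-12, 12]` hours, the
#' convention used for acrophase-shift B coefficients (e.g. a case acrophase
#' of 02:43 against a control acrophase of 22:48 is a shift of +03:55).
#'
#' @param phi1,phi2 Acrophases in clock hours.
#' @return Signed difference in hours, in `(-12, 12]`.
#' @examples
#' circular_diff(parse_clock("02:43"), parse_clock("22:48"))  # +3.9167 h
#' @export
circular_diff <- function(phi1, phi2) {
  d <- (phi1 - phi2) %% 24
  d[!is.na(d) & d > 12] <- d[!is.na(d) & d > 12] - 24
  d
}
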