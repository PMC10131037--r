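# Non-cosinor quantitative analyses: detection-limit substitution,
# maximum/minimum circadian variation, Firth penalized logistic regression,
# confounder-adjusted linear regression, and nocturnal dipper classification.

#' Assay detection-limit configuration
#'
#' @param lod Detection limit in marker units (melatonin: 8 pmol/L).
#' @param substitute Value assigned to measurements strictly below the limit
#'   (default half the limit, the standard half-LOD convention; melatonin:
#'   4 pmol/L).
#' @return Object of class `assay_config`.
#' @examples
#' assay_config(lod = 8)
#' @export
assay_config <- function(lod, substitute = lod / 2) {
  stopifnot(is.numeric(lod), length(lod) == 1L, lod > 0)
  if (!(substitute > 0 && substitute < lod)) {
    stop("`substitute` must satisfy 0 < substitute < lod")
  }
  structure(list(lod = lod, substitute = substitute), class = "assay_config")
}

#' Substitute below-detection-limit values
#'
#' Replaces every value strictly below the detection limit by the substitute
#' value and flags it as censored; values at or above the limit are left
#' untouched. Idempotent: the substitute is itself below the limit, so a
#' second application changes nothing.
#'
#' @param series A [rhythm_series()].
#' @param config An [assay_config()].
#' @return The series with substituted values and updated `censored` flags.
#' @examples
#' s <- rhythm_series(c(9, 13, 17, 21), c(6.5, 8, 12, 30))
#' apply_lod(s, assay_config(lod = 8))$values  # 4, 8, 12, 30
#' @export
apply_lod <- function(series, config) {
  stopifnot(inherits(series, "rhythm_series"), inherits(config, "assay_config"))
  below <- series$values < config$lod
  series$values[below] <- config$substitute
  series$censored <- series$censored | below
  series
}

#' Summarise 24-h variation of a series
#'
#' Minimum, maximum and circadian variation (maximum/minimum) over a
#' subject's 24-h series, plus censoring bookkeeping. Detection-limit
#' substitution ([apply_lod()]) must already have been applied; subjects with
#' every sample below the limit carry no rhythm information and are flagged
#' `all_below_lod` for downstream exclusion.
#'
#' @param series A [rhythm_series()] with positive values.
#' @return Data frame row with `subject_id`, `marker`, `minimum`, `maximum`,
#'   `circadian_variation`, `n_below_lod`, `all_below_lod`.
#' @examples
#' s <- rhythm_series(c(9, 13, 17, 21, 25, 29, 33), c(4, 4, 10, 40, 120, 60, 8))
#' summarize_variation(s)
#' @export
summarize_variation <- function(series) {
  stopifnot(inherits(series, "rhythm_series"))
  if (any(series$values <= 0)) {
    stop("circadian variation requires strictly positive values")
  }
  mn <- min(series$values)
  mx <- max(series$values)
  data.frame(
    subject_id = series$subject_id, marker = series$marker,
    minimum = mn, maximum = mx, circadian_variation = mx / mn,
    n_below_lod = sum(series$censored),
    all_below_lod = all(series$censored),
    stringsAsFactors = FALSE
  )
}

#' Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' `l(b) + 0.5 * log det I(b)` by a modified Newton iteration with
#' step-halving. The penalty guarantees finite coefficient estimates even
#' under complete separation and reduces small-sample bias. Confidence
#' intervals are Wald by default, with profile-penalized-likelihood intervals
#' available (`ci = "profile"`), which are preferable near separation.
#'
#' @param formula Model formula with a binary (0/1 or two-level factor)
#'   outcome.
#' @param data Data frame.
#' @param conf_level Confidence level.
#' @param ci `"wald"` or `"profile"`.
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `firth_fit`: coefficients, standard errors,
#'   confidence limits, p-values, number of iterations, penalized
#'   log-likelihood and the interval type used.
#' @examples
#' d <- data.frame(y = c(0, 0, 0, 1, 1, 1, 1, 0), x = c(0, 0, 1, 1, 1, 0, 1, 0))
#' firth_logistic(y ~ x, d)
#' @export
firth_logistic <- function(formula, data, conf_level = 0.95,
                           ci = c("wald", "profile"),
                           max_iter = 100L, tol = 1e-10) {
  ci <- match.arg(ci)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y) - 1
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  if (length(unique(y)) < 2L) stop("outcome is constant; model not estimable")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (ncol(X) < 2L) stop("at least one covariate is required")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    info <- crossprod(X * W, X)
    sum(y * eta - log1p(exp(eta))) +
      0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
  }

  newton <- function(b, X, y, offset = 0) {
    ll_old <- -Inf
    iters <- 0L
    repeat {
      iters <- iters + 1L
      eta <- drop(X %*% b) + offset
      p <- stats::plogis(eta)
      W <- p * (1 - p)
      XW <- X * W
      info <- crossprod(XW, X)
      info_inv <- tryCatch(solve(info), error = function(e) NULL)
      if (is.null(info_inv)) stop("information matrix singular during Firth iteration")
      h <- rowSums((X %*% info_inv) * XW)  # hat diagonal
      U <- drop(crossprod(X, y - p + h * (0.5 - p)))
      step <- drop(info_inv %*% U)
      ll_full <- function(bb) {
        ee <- drop(X %*% bb) + offset
        pp <- stats::plogis(ee)
        WW <- pp * (1 - pp)
        sum(y * ee - log1p(exp(ee))) +
          0.5 * as.numeric(determinant(crossprod(X * WW, X), TRUE)$modulus)
      }
      lam <- 1
      repeat {
        b_new <- b + lam * step
        ll_new <- ll_full(b_new)
        if (is.finite(ll_new) && (ll_new >= ll_old - 1e-12 || lam < 1e-6)) break
        lam <- lam / 2
      }
      b <- b_new
      if ((abs(ll_new - ll_old) < tol && max(abs(U)) < 1e-5) || iters >= max_iter) {
        if (iters >= max_iter && max(abs(U)) > 1e-3) {
          stop("Firth iteration did not converge after ", max_iter,
               " steps (max |score| = ", signif(max(abs(U)), 3), ")")
        }
        return(list(b = b, info_inv = info_inv, ll = ll_new, iters = iters))
      }
      ll_old <- ll_new
    }
  }

  res <- newton(rep(0, ncol(X)), X, y)
  b <- res$b
  se <- sqrt(diag(res$info_inv))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- b - zq * se
  upper <- b + zq * se
  if (ci == "profile") {
    crit <- stats::qchisq(conf_level, 1)
    for (j in seq_along(b)) {
      # profile the full penalized likelihood over the remaining coefficients
      prof <- function(bj) {
        obj <- function(bm) {
          bb <- numeric(ncol(X)); bb[j] <- bj; bb[-j] <- bm
          -pen_ll(bb)
        }
        o <- stats::optim(b[-j], obj, method = "BFGS",
                          control = list(maxit = 300))
        2 * (res$ll + o$value) - crit
      }
      lower[j] <- expand_root(prof, b[j], -1, 2 * se[j])
      upper[j] <- expand_root(prof, b[j], +1, 2 * se[j])
    }
  }
  pz <- 2 * stats::pnorm(-abs(b / se))
  out <- data.frame(term = colnames(X), estimate = unname(b), se = unname(se),
                    lower = unname(lower), upper = unname(upper),
                    p = unname(pz), stringsAsFactors = FALSE)
  structure(list(coefficients = out, loglik_penalized = res$ll,
                 iterations = res$iters, ci = ci, n = length(y),
                 conf_level = conf_level),
            class = "firth_fit")
}

# walk outwards from b0 in direction dir until f changes sign, then uniroot
expand_root <- function(f, b0, dir, step) {
  lo <- b0
  hi <- b0 + dir * step
  for (k in 1:40) {
    fh <- f(hi)
    if (isTRUE(fh > 0)) {
      return(stats::uniroot(f, sort(c(lo, hi)), tol = 1e-6)$root)
    }
    lo <- hi
    hi <- hi + dir * step
  }
  warning("profile bound search did not bracket; returning Wald-style bound")
  hi
}

#' @export
print.firth_fit <- function(x, digits = 4, ...) {
  cat("Firth penalized logistic regression (", x$ci, " CI, n = ", x$n, ")\n",
      sep = "")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Confounder-adjusted linear regression for a group effect
#'
#' Ordinary least squares of an outcome on the exposure (group) plus a fixed
#' confounder set, with the transform conventions used for skewed outcomes:
#' `"log"` (B back-transforms to a multiplication factor), `"log1p"` (log
#' after adding 1 so zero values are admissible; B is a multiplication factor
#' on outcome + 1), and `"quadratic"` (regression on the squared outcome; B
#' is back-transformed through the square root at the confounder means).
#' Rows with any missing value are dropped listwise with a message.
#'
#' @param outcome Numeric outcome per subject.
#' @param exposure Binary/two-level group indicator per subject (the reported
#'   B is the second level versus the first).
#' @param confounders Optional data frame of confounders (e.g. sex, age, BMI,
#'   kidney function, alcohol consumption).
#' @param transform One of `"identity"`, `"log"`, `"log1p"`, `"quadratic"`.
#' @param conf_level Confidence level.
#' @return List of class `adjusted_regression`: `B`, `lower`, `upper`, `p`,
#'   `type` (difference or multiplication factor), `transform`, `n_used`,
#'   `n_dropped`, and the underlying `lm` fit.
#' @examples
#' set.seed(1)
#' g <- rep(0:1, each = 20)
#' adjusted_regression(2 * g + rnorm(40), g)
#' @export
adjusted_regression <- function(outcome, exposure, confounders = NULL,
                                transform = c("identity", "log", "log1p",
                                              "quadratic"),
                                conf_level = 0.95) {
  transform <- match.arg(transform)
  exposure <- if (is.factor(exposure)) as.numeric(exposure) - 1
              else as.numeric(exposure)
  d <- data.frame(.y = as.numeric(outcome), .g = exposure)
  if (!is.null(confounders)) {
    confounders <- as.data.frame(confounders)
    d <- cbind(d, confounders)
  }
  keep <- stats::complete.cases(d)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped for missing data")
    d <- d[keep, , drop = FALSE]
  }
  y <- switch(transform,
              identity = d$.y,
              log = { if (any(d$.y <= 0)) stop("log transform needs positive outcomes"); log(d$.y) },
              log1p = { if (any(d$.y < 0)) stop("log1p transform needs nonnegative outcomes"); log1p(d$.y) },
              quadratic = d$.y^2)
  d$.y <- y
  fit <- stats::lm(.y ~ ., data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ci <- stats::confint(fit, ".g", level = conf_level)
  B <- unname(stats::coef(fit)[".g"])
  lo <- ci[1]; hi <- ci[2]
  p <- summary(fit)$coefficients[".g", 4]
  type <- "difference"
  if (transform %in% c("log", "log1p")) {
    B <- exp(B); lo <- exp(lo); hi <- exp(hi)
    type <- "multiplication factor"
  } else if (transform == "quadratic") {
    # back through sqrt at the reference prediction (confounder means)
    ref <- d; ref$.g <- 0
    m0 <- mean(stats::predict(fit, ref))
    back <- function(bb) sqrt(pmax(m0 + bb, 0)) - sqrt(pmax(m0, 0))
    B <- back(B); lo <- back(lo); hi <- back(hi)
    type <- "difference (retransformed)"
  }
  structure(list(B = B, lower = lo, upper = hi, p = p, type = type,
                 transform = transform, n_used = nrow(d),
                 n_dropped = n_dropped, fit = fit),
            class = "adjusted_regression")
}

#' @export
print.adjusted_regression <- function(x, digits = 3, ...) {
  cat(sprintf("Adjusted regression (%s): B = %.*f (%.*f; %.*f), p = %.3g [%s]\n",
              x$transform, digits, x$B, digits, x$lower, digits, x$upper,
              x$p, x$type))
  invisible(x)
}

#' Classify the nocturnal dip of a 24-h BP/HR profile
#'
#' Computes day and night window means and the dip fraction
#' `(day - night)/day`, and classifies the profile as `dipper` (fall of at
#' least 10%), `riser` (nocturnal rise, dip < 0) or `non_dipper` (in
#' between). Default windows are 07:00-23:00 (day) and 23:00-07:00 (night).
#'
#' @param times Clock times of the measurements in hours (`[0, 24)`).
#' @param values Measurements (mmHg or beats/min).
#' @param day Numeric length-2 vector `c(start, end)` of the day window in
#'   clock hours; the night window is its complement.
#' @return List with `day_mean`, `night_mean`, `dip_fraction`, `class`.
#' @examples
#' classify_dip(c(10, 14, 18, 2, 4), c(105, 106, 101, 97, 99))
#' @export
classify_dip <- function(times, values, day = c(7, 23)) {
  stopifnot(length(times) == length(values), length(day) == 2L)
  tt <- times %% 24
  in_day <- tt >= day[1] & tt < day[2]
  if (!any(in_day) || !any(!in_day)) {
    stop("both day and night windows must contain measurements")
  }
  dm <- mean(values[in_day])
  nm <- mean(values[!in_day])
  dip <- (dm - nm) / dm
  cls <- if (dip >= 0.10) "dipper" else if (dip < 0) "riser" else "non_dipper"
  list(day_mean = dm, night_mean = nm, dip_fraction = dip, class = cls)
}

#' Dip classification for a cohort of ambulatory profiles
#'
#' Applies [classify_dip()] per subject and channel of a long-format
#' ambulatory monitoring table.
#'
#' @param abpm Data frame with columns `subject_id`, `channel`, `clock_time`
#'   (HH:MM or decimal hours) and `value`.
#' @param day Day window passed to [classify_dip()].
#' @return Data frame with one row per subject x channel (`day_mean`,
#'   `night_mean`, `dip_fraction`, `class`) and an attribute `fractions`
#'   giving the per-channel class percentages.
#' @export
dip_summary <- function(abpm, day = c(7, 23)) {
  need <- c("subject_id", "channel", "clock_time", "value")
  if (!all(need %in% names(abpm))) {
    stop("abpm table needs columns: ", paste(need, collapse = ", "))
  }
  abpm$clock_time <- parse_clock(abpm$clock_time)
  out <- do.call(rbind, lapply(
    split(abpm, list(abpm$subject_id, abpm$channel), drop = TRUE),
    function(d) {
      r <- classify_dip(d$clock_time, d$value, day = day)
      data.frame(subject_id = d$subject_id[1], channel = d$channel[1],
                 day_mean = r$day_mean, night_mean = r$night_mean,
                 dip_fraction = r$dip_fraction, class = r$class,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  fr <- do.call(rbind, lapply(split(out, out$channel), function(d) {
    data.frame(channel = d$channel[1],
               dipper = 100 * mean(d$class == "dipper"),
               non_dipper = 100 * mean(d$class == "non_dipper"),
               riser = 100 * mean(d$class == "riser"))
  }))
  rownames(fr) <- NULL
  attr(out, "fractions") <- fr
  out
}
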