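# Two-stage pooling of per-subject cosinor estimates.
#
# Stage 1: each subject's (mesor, amplitude, acrophase) with its delta-method
# covariance, on the analysis (possibly log) scale, acrophase centred in a
# 24-h window.  Stage 2: a joint three-outcome random-effects model with the
# stage-1 covariances treated as known ("multiple outcomes" meta-analytic
# model), a group fixed effect per outcome (plus confounders when adjusting),
# unstructured between-subject covariance estimated by REML, Wald inference.

#' Assemble per-subject rhythm estimates for pooling
#'
#' Converts a list of per-subject [fit_cosinor()] results into the stage-1
#' input of [pool_cosinor()]: one `(mesor, amplitude, acrophase)` triple per
#' subject with its delta-method 3x3 covariance, the acrophase centred in a
#' 24-h window, and the per-subject rhythm-significance verdict.
#'
#' Subjects with an undefined acrophase (numerically zero amplitude, or
#' amplitude not distinguishable from zero relative to its standard error)
#' contribute their mesor and amplitude only.
#'
#' @param fits List of `cosinor_fit` objects, one per subject, sharing the
#'   marker and analysis scale.
#' @param center Centre of the acrophase window in clock hours, or `NULL` to
#'   use the circular mean of the individual acrophases (the 24-h midpoint of
#'   the cohort's phases).
#' @param covariates Optional data frame of subject-level confounders with a
#'   `subject_id` column (e.g. age, sex, bmi, egfr, alcohol).
#' @param alpha Significance level for the per-subject zero-amplitude test.
#' @return Object of class `subject_estimates`: list with `table` (data frame
#'   of estimates), `vcov` (list of 3x3 matrices), `center`, `marker`,
#'   `log_scale`, `covariates`.
#' @export
subject_estimates <- function(fits, center = NULL, covariates = NULL,
                              alpha = 0.05) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "cosinor_fit")))
  log_scales <- vapply(fits, function(f) isTRUE(f$log_scale), TRUE)
  if (length(unique(log_scales)) != 1L) {
    stop("all fits must share the analysis scale")
  }
  markers <- unique(vapply(fits, function(f) f$marker %||% NA_character_, ""))
  markers <- markers[!is.na(markers)]
  if (length(markers) > 1L) stop("all fits must share the marker")

  phis <- vapply(fits, function(f) if (isTRUE(f$phi_defined)) f$acrophase else NA_real_, 0)
  if (is.null(center)) center <- circular_mean_hours(phis[!is.na(phis)])

  rows <- lapply(fits, function(f) {
    data.frame(
      subject_id = f$subject_id %||% NA_character_,
      group = f$group %||% NA_character_,
      mesor = f$mesor,
      amplitude = f$amplitude,
      acrophase = if (isTRUE(f$phi_defined) && is.finite(f$se["acrophase"]))
        center_acrophase(f$acrophase, center) else NA_real_,
      significant = is.finite(f$p_value) && f$p_value < alpha,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  vcovs <- lapply(fits, estimate_vcov_map)
  structure(
    list(table = tab, vcov = vcovs, center = center,
         marker = if (length(markers)) markers else NA_character_,
         log_scale = log_scales[1], covariates = covariates),
    class = "subject_estimates"
  )
}

# delta-method map of cov(M, beta, gamma) to cov(M, A, phi_hours)
estimate_vcov_map <- function(fit) {
  V <- fit$vcov
  if (is.null(V)) {
    return(diag(fit$se^2, 3))
  }
  A <- fit$amplitude; b <- fit$beta; g <- fit$gamma; w <- fit$omega
  if (A <= 0 || !isTRUE(fit$phi_defined)) {
    S <- matrix(NA_real_, 3, 3)
    S[1, 1] <- V[1, 1]
    S[2, 2] <- fit$se["amplitude"]^2
    return(S)
  }
  J <- rbind(c(1, 0, 0),
             c(0, b / A, g / A),
             c(0, -g / (A^2 * w), b / (A^2 * w)))
  J %*% V %*% t(J)
}

circular_mean_hours <- function(phi) {
  if (!length(phi)) return(0)
  w <- 2 * pi / 24
  (atan2(mean(sin(w * phi)), mean(cos(w * phi))) / w) %% 24
}

#' Pool per-subject cosinor estimates into a group comparison
#'
#' Fits the stage-2 joint random-effects model over the three rhythm
#' parameters with the stage-1 covariances treated as known, a group fixed
#' effect on every outcome (plus the confounders, held at their sample means,
#' when `adjust = TRUE`), and unstructured between-subject covariance
#' estimated by REML. Group means, case-vs-control contrasts (B
#' coefficients), Wald 95% CIs and p-values are returned; on a log analysis
#' scale the mesor and amplitude (and their B) are back-transformed with
#' [retransform_log()], so that B reads as a multiplication factor; the
#' acrophase is pooled on the centred linear scale and mapped back to clock
#' time, its B being a signed time difference.
#'
#' If the unstructured multivariate fit fails to converge, the function falls
#' back to independent per-outcome random-effects pooling and signals a
#' warning of class `rhythmkit_pooling_fallback`.
#'
#' @param estimates A [subject_estimates()] object.
#' @param adjust Adjust for the confounders supplied in
#'   `estimates$covariates` (all columns except `subject_id`/`group`).
#' @param ref_group Label of the reference group (contrast is
#'   `other - ref_group`); defaults to `"control"`, `"sham"` or `"ctrl"` if
#'   present, else the alphabetically first label.
#' @param conf_level Confidence level for Wald intervals.
#' @return Object of class `group_comparison` with elements `groups` (data
#'   frame of per-group estimates with CIs, retransformed where applicable),
#'   `contrasts` (B with CI and p per parameter), `significance_rate`
#'   (percent of subjects with an individually significant rhythm, per
#'   group), `method`, `between_cov`, `center`, `marker`, `log_scale`.
#' @examples
#' \donttest{
#' cohort <- generate_hormone_cohort(cohort_spec(n_cases = 12, n_controls = 8,
#'                                               seed = 1))
#' fits <- fit_cohort(cohort$measurements, marker = "cortisol",
#'                    log_scale = FALSE)
#' pool_cosinor(subject_estimates(fits))
#' }
#' @export
pool_cosinor <- function(estimates, adjust = FALSE, ref_group = NULL,
                         conf_level = 0.95) {
  stopifnot(inherits(estimates, "subject_estimates"))
  tab <- estimates$table
  groups <- unique(tab$group)
  if (length(groups) != 2L) stop("exactly two groups are required for pooling")
  counts <- table(tab$group)
  if (any(counts < 2L)) {
    stop("each group needs at least 2 subjects (",
         paste(names(counts)[counts < 2], collapse = ", "), ")")
  }
  if (is.null(ref_group)) {
    known <- intersect(c("control", "sham", "ctrl"), groups)
    ref_group <- if (length(known)) known[1] else sort(groups)[1]
  }
  stopifnot(ref_group %in% groups)
  other <- setdiff(groups, ref_group)

  covars <- NULL
  if (adjust) {
    cv <- estimates$covariates
    if (is.null(cv)) stop("adjust = TRUE requires subject covariates")
    idx <- match(tab$subject_id, cv$subject_id)
    if (anyNA(idx)) stop("covariates missing for some subjects")
    covars <- cv[idx, setdiff(names(cv), c("subject_id", "group")), drop = FALSE]
    keep <- stats::complete.cases(covars)
    if (!all(keep)) {
      message(sum(!keep), " subject(s) dropped for missing covariates")
      tab <- tab[keep, , drop = FALSE]
      estimates$vcov <- estimates$vcov[keep]
      covars <- covars[keep, , drop = FALSE]
    }
    covars <- scale(as.matrix(covars), center = TRUE, scale = FALSE)
  }

  Y <- as.matrix(tab[, c("mesor", "amplitude", "acrophase")])
  grp <- as.numeric(tab$group == other)
  n_cov <- if (adjust) ncol(covars) else 0L
  p_per <- 2L + n_cov  # intercept + group (+ confounders) per outcome
  Z <- cbind(1, grp, if (n_cov) covars)
  S <- array(0, dim = c(nrow(tab), 3L, 3L))
  for (i in seq_len(nrow(tab))) {
    Si <- estimates$vcov[[i]]
    Si[!is.finite(Si)] <- 0
    S[i, , ] <- Si
  }

  fit <- tryCatch(mv_reml(Y, S, Z), error = function(e) NULL)
  method <- "multivariate REML"
  if (is.null(fit) || !isTRUE(fit$converged)) {
    warning(structure(
      class = c("rhythmkit_pooling_fallback", "warning", "condition"),
      list(message = paste0("multivariate pooling did not converge for ",
                            estimates$marker %||% "marker",
                            "; falling back to per-outcome pooling"),
           call = sys.call())))
    fit <- mv_reml(Y, S, Z, independent = TRUE)
    method <- "independent per-outcome REML (fallback)"
  }
  p <- 3L * p_per

  theta <- fit$theta; Vth <- fit$vcov
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  params <- c("mesor", "amplitude", "acrophase")

  lincomb <- function(L) {
    est <- drop(L %*% theta)
    se <- sqrt(drop(L %*% Vth %*% t(L)))
    c(est = est, lower = est - zq * se, upper = est + zq * se, se = se)
  }
  groups_df <- NULL; contr_df <- NULL
  for (k in 1:3) {
    base <- (k - 1L) * p_per
    L_ref <- matrix(0, 1, p); L_ref[1, base + 1L] <- 1
    L_oth <- L_ref; L_oth[1, base + 2L] <- 1
    L_B <- matrix(0, 1, p); L_B[1, base + 2L] <- 1
    r <- lincomb(L_ref); o <- lincomb(L_oth); b <- lincomb(L_B)
    pval <- 2 * stats::pnorm(-abs(b["est"] / b["se"]))
    groups_df <- rbind(
      groups_df,
      data.frame(group = c(other, ref_group), parameter = params[k],
                 estimate = c(o["est"], r["est"]),
                 lower = c(o["lower"], r["lower"]),
                 upper = c(o["upper"], r["upper"]), row.names = NULL)
    )
    contr_df <- rbind(
      contr_df,
      data.frame(parameter = params[k], B = unname(b["est"]),
                 lower = unname(b["lower"]), upper = unname(b["upper"]),
                 p = unname(pval), row.names = NULL)
    )
  }
  groups_df$retransformed <- FALSE
  contr_df$type <- "difference"

  if (isTRUE(estimates$log_scale)) {
    sel_g <- groups_df$parameter %in% c("mesor", "amplitude")
    groups_df[sel_g, c("estimate", "lower", "upper")] <-
      exp(groups_df[sel_g, c("estimate", "lower", "upper")])
    groups_df$retransformed[sel_g] <- TRUE
    sel_c <- contr_df$parameter %in% c("mesor", "amplitude")
    contr_df[sel_c, c("B", "lower", "upper")] <-
      exp(contr_df[sel_c, c("B", "lower", "upper")])
    contr_df$type[sel_c] <- "ratio"
  }
  sel_a <- groups_df$parameter == "acrophase"
  groups_df$clock <- NA_character_
  groups_df$clock[sel_a] <- format_clock(groups_df$estimate[sel_a], wrap = TRUE)
  contr_df$type[contr_df$parameter == "acrophase"] <- "time difference"

  sig <- tapply(tab$significant, tab$group, function(z) 100 * mean(z))
  sig <- stats::setNames(as.numeric(sig), names(sig))
  structure(
    list(marker = estimates$marker, log_scale = estimates$log_scale,
         center = estimates$center, groups = groups_df, contrasts = contr_df,
         significance_rate = sig, method = method, adjusted = adjust,
         between_cov = fit$Sigma, conf_level = conf_level,
         n = as.vector(counts)[match(c(other, ref_group), names(counts))],
         ref_group = ref_group, case_group = other),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat("Pooled cosinor comparison:", x$marker %||% "(marker)",
      if (isTRUE(x$adjusted)) "[adjusted]" else "[unadjusted]", "\n")
  cat("  method:", x$method, "\n")
  g <- x$groups
  g[c("estimate", "lower", "upper")] <-
    lapply(g[c("estimate", "lower", "upper")], round, digits)
  print(g, row.names = FALSE)
  ct <- x$contrasts
  ct[c("B", "lower", "upper")] <- lapply(ct[c("B", "lower", "upper")], round, digits)
  ct$p <- signif(ct$p, 3)
  cat(sprintf("  B (%s vs %s):\n", x$case_group, x$ref_group))
  print(ct, row.names = FALSE)
  sr <- x$significance_rate
  cat("  cosinor significance:",
      paste(sprintf("%s %.1f%%", names(sr), sr), collapse = ", "), "\n")
  invisible(x)
}

# REML fit of y_i = (I_d (x) z_i') theta + u_i + e_i over subjects i, with
# u_i ~ N(0, Sigma) (unstructured d x d, or diagonal when independent) and
# e_i ~ N(0, S_i) known from stage 1.  Y is n x d with NA for unobserved
# outcomes; S is n x d x d; Z is the n x p_per per-outcome design.  The
# likelihood is evaluated with subjects batched by missingness pattern and
# closed-form small-matrix inverses, so each REML objective evaluation is a
# handful of vectorized operations.
mv_reml <- function(Y, S, Z, independent = FALSE) {
  d <- ncol(Y)
  n <- nrow(Y)
  p_per <- ncol(Z)
  p <- d * p_per
  obs <- is.finite(Y)
  pattern <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  pat_idx <- split(seq_len(n), pattern)

  build_sigma <- function(par) {
    if (independent) return(diag(exp(par)^2, d))
    L <- matrix(0, d, d)
    diag(L) <- exp(par[seq_len(d)])
    L[lower.tri(L)] <- par[-seq_len(d)]
    L %*% t(L)
  }

  # vectorized symmetric inverse + log-determinant for 1x1/2x2/3x3 batches;
  # V supplied as a matrix with one row per subject, columns the packed
  # upper triangle in column-major order
  sym_inv <- function(V, m) {
    if (m == 1L) {
      det <- V[, 1]
      if (any(det <= 0)) return(NULL)
      list(inv = matrix(1 / det, ncol = 1), ldet = log(det))
    } else if (m == 2L) {
      a <- V[, 1]; b <- V[, 2]; c <- V[, 3]
      det <- a * c - b^2
      if (any(det <= 0) || any(a <= 0)) return(NULL)
      list(inv = cbind(c / det, -b / det, a / det), ldet = log(det))
    } else {
      # column-major packed upper triangle: 11, 12, 22, 13, 23, 33
      a <- V[, 1]; b <- V[, 2]; dd <- V[, 3]
      c <- V[, 4]; e <- V[, 5]; f <- V[, 6]
      # V = [a b c; b d e; c e f]
      A11 <- dd * f - e^2; A12 <- c * e - b * f; A13 <- b * e - c * dd
      det <- a * A11 + b * A12 + c * A13
      if (any(det <= 0) || any(a <= 0)) return(NULL)
      A22 <- a * f - c^2; A23 <- b * c - a * e; A33 <- a * dd - b^2
      list(inv = cbind(A11, A12, A22, A13, A23, A33) / det, ldet = log(det))
    }
  }

  pack_cols <- function(idx_set) {
    # packed upper-triangle (col-major) index pairs for outcomes idx_set
    m <- length(idx_set)
    pairs <- NULL
    for (jj in seq_len(m)) for (ii in seq_len(jj)) {
      pairs <- rbind(pairs, c(idx_set[ii], idx_set[jj]))
    }
    pairs
  }
  pat_info <- lapply(pat_idx, function(I) {
    oset <- which(obs[I[1], ])
    pairs <- pack_cols(oset)
    Spacked <- vapply(seq_len(nrow(pairs)),
                      function(q) S[I, pairs[q, 1], pairs[q, 2]],
                      numeric(length(I)))
    if (length(I) == 1L) Spacked <- matrix(Spacked, nrow = 1)
    list(I = I, oset = oset, pairs = pairs, Spacked = Spacked)
  })

  assemble <- function(Sigma) {
    XtVX <- matrix(0, p, p); XtVy <- numeric(p); yVy <- 0; ldet <- 0
    for (pi in pat_info) {
      m <- length(pi$oset)
      sig_pack <- Sigma[pi$pairs]
      V <- sweep(pi$Spacked, 2, sig_pack, "+")
      si <- sym_inv(V, m)
      if (is.null(si)) return(NULL)
      ldet <- ldet + sum(si$ldet)
      ZI <- Z[pi$I, , drop = FALSE]
      YI <- Y[pi$I, pi$oset, drop = FALSE]
      # full m x m inverse entries from the packed form
      W <- array(0, dim = c(length(pi$I), m, m))
      q <- 0L
      for (jj in seq_len(m)) for (ii in seq_len(jj)) {
        q <- q + 1L
        W[, ii, jj] <- si$inv[, q]
        W[, jj, ii] <- si$inv[, q]
      }
      for (kk in seq_len(m)) {
        gk <- pi$oset[kk]
        rows <- (gk - 1L) * p_per + seq_len(p_per)
        uk <- numeric(length(pi$I))
        for (ll in seq_len(m)) {
          gl <- pi$oset[ll]
          cols <- (gl - 1L) * p_per + seq_len(p_per)
          XtVX[rows, cols] <- XtVX[rows, cols] + crossprod(ZI, ZI * W[, kk, ll])
          uk <- uk + W[, kk, ll] * YI[, ll]
        }
        XtVy[rows] <- XtVy[rows] + drop(crossprod(ZI, uk))
        yVy <- yVy + sum(YI[, kk] * uk)
      }
    }
    list(XtVX = XtVX, XtVy = XtVy, yVy = yVy, ldet = ldet)
  }

  nll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 50)) return(1e10)
    parts <- assemble(build_sigma(par))
    if (is.null(parts)) return(1e10)
    theta <- tryCatch(solve(parts$XtVX, parts$XtVy), error = function(e) NULL)
    if (is.null(theta)) return(1e10)
    quad <- parts$yVy - sum(theta * parts$XtVy)
    ld_fix <- determinant(parts$XtVX, logarithm = TRUE)$modulus
    val <- 0.5 * (parts$ldet + quad + ld_fix)
    if (!is.finite(val)) 1e10 else val
  }

  # moment-based start: marginal residual variance minus the mean known part
  resid0 <- apply(Y, 2, function(col) col - mean(col, na.rm = TRUE))
  v0 <- apply(resid0, 2, stats::var, na.rm = TRUE) -
    vapply(seq_len(d), function(k) mean(S[, k, k][obs[, k]]), 0)
  v0[!is.finite(v0) | v0 < 1e-4] <- 1e-2
  init <- if (independent) 0.5 * log(v0) else c(0.5 * log(v0), rep(0, d * (d - 1L) / 2L))

  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-9))
  if (opt$convergence != 0) {
    opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-9))
  }
  Sigma <- build_sigma(opt$par)
  parts <- assemble(Sigma)
  if (is.null(parts)) stop("REML covariance assembly failed")
  theta <- solve(parts$XtVX, parts$XtVy)
  list(theta = theta, vcov = solve(parts$XtVX), Sigma = Sigma,
       reml = opt$value,
       converged = opt$convergence == 0 && opt$value < 1e9)
}

#' Back-transform log-scale estimates to medians / multiplication factors
#'
#' Exponentiates a log-scale point estimate and its confidence limits. A
#' log-scale group parameter back-transforms to a median with 95% CI; a
#' log-scale contrast back-transforms to a ratio (multiplication factor).
#'
#' @param estimate Point estimate(s) on the log scale.
#' @param lower,upper Optional confidence limits on the log scale.
#' @return If limits are given, a named list `(estimate, lower, upper)`;
#'   otherwise the exponentiated estimate.
#' @examples
#' retransform_log(0, -0.1, 0.1)
#' @export
retransform_log <- function(estimate, lower = NULL, upper = NULL) {
  if (is.null(lower) && is.null(upper)) return(exp(estimate))
  stopifnot(!is.null(lower), !is.null(upper))
  list(estimate = exp(estimate), lower = exp(lower), upper = exp(upper))
}

#' Fraction of subjects with an individually significant rhythm
#'
#' The "cosinor significance" of a cohort: the percentage of subjects whose
#' zero-amplitude test rejects at level `alpha`.
#'
#' @param fits List of `cosinor_fit` objects, or a numeric vector of
#'   zero-amplitude p-values.
#' @param alpha Significance level.
#' @return Percentage in `[0, 100]`.
#' @examples
#' significance_rate(c(0.01, 0.2, 0.03, 0.8))  # 50
#' @export
significance_rate <- function(fits, alpha = 0.05) {
  if (is.list(fits)) {
    fits <- vapply(fits, function(f) f$p_value, 0)
  }
  if (!length(fits)) stop("no fits supplied")
  100 * mean(fits < alpha)
}
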