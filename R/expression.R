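# Animal-model stage: delta-Ct computation, per-group cosinor on delta-Ct,
# and case-control comparison of clock-gene rhythms.  Because each animal is
# sampled terminally, replicates at a zeitgeber time are pooled into a single
# cosinor per group rather than fitted per animal.  Larger delta-Ct means
# lower expression, so a delta-Ct acrophase marks the expression trough.

ZT_GRIDS <- list(
  mouse = c(1, 4, 7.5, 11, 14.5, 18, 21.5),
  zebrafish = c(0, 4, 8, 12, 16, 20)
)

#' Compute normalized expression (delta Ct) from raw qPCR cycle thresholds
#'
#' `delta_ct = ct_target - ct_housekeeping` per observation (housekeeping
#' genes: e.g. *Rplp0* in mouse, *eef1a1* in zebrafish). Rows with a missing
#' target or housekeeping Ct are rejected, counted, and returned in the
#' `rejected` attribute rather than raising an error.
#'
#' @param ct_table Data frame with columns `animal_id`, `species`, `group`,
#'   `organ`, `gene`, `zt`, `ct_target`, `ct_housekeeping`.
#' @return The table with a `delta_ct` column, rejected rows removed;
#'   attributes `rejected` (the removed rows with a `reason` column) and
#'   `n_rejected`.
#' @examples
#' tab <- data.frame(animal_id = 1:2, species = "mouse", group = "HF",
#'                   organ = "heart", gene = "Bmal1", zt = c(1, 4),
#'                   ct_target = c(25, 24), ct_housekeeping = c(20, NA))
#' compute_delta_ct(tab)
#' @export
compute_delta_ct <- function(ct_table) {
  need <- c("animal_id", "species", "group", "organ", "gene", "zt",
            "ct_target", "ct_housekeeping")
  miss <- setdiff(need, names(ct_table))
  if (length(miss)) stop("ct table missing column(s): ", paste(miss, collapse = ", "))
  bad_t <- !is.finite(ct_table$ct_target)
  bad_h <- !is.finite(ct_table$ct_housekeeping)
  bad <- bad_t | bad_h
  rejected <- ct_table[bad, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- ifelse(bad_t[bad] & bad_h[bad], "missing target and housekeeping Ct",
                       ifelse(bad_t[bad], "missing target Ct", "missing housekeeping Ct"))
    message(nrow(rejected), " row(s) rejected: missing Ct values")
  }
  out <- ct_table[!bad, , drop = FALSE]
  if (any(out$zt < 0 | out$zt >= 24)) stop("zeitgeber times must lie in [0, 24)")
  known <- out$species %in% names(ZT_GRIDS)
  off_grid <- known & !mapply(function(sp, z) {
    any(abs(ZT_GRIDS[[sp]] - z) < 1e-9)
  }, out$species, out$zt)
  if (any(off_grid)) {
    warning(sum(off_grid), " observation(s) at zeitgeber times off the usual ",
            "sampling grid for their species")
  }
  out$delta_ct <- out$ct_target - out$ct_housekeeping
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "n_rejected") <- nrow(rejected)
  out
}

#' Fit the group-level cosinor of a clock gene's delta-Ct rhythm
#'
#' Pools all animals of one species/organ/gene/group (each animal contributes
#' one terminal observation) into a single cosinor fit on the delta-Ct scale,
#' and attaches the rhythmicity verdict from the zero-amplitude test.
#'
#' @param samples Data frame of delta-Ct observations (output of
#'   [compute_delta_ct()]) restricted to one species/organ/gene/group.
#' @param period Period in hours.
#' @param alpha Significance level for the rhythmicity verdict.
#' @return A `cosinor_fit` with `species`, `organ`, `gene` labels and a
#'   logical `rhythmic` verdict.
#' @export
fit_group_rhythm <- function(samples, period = 24, alpha = 0.05) {
  for (col in c("species", "organ", "gene", "group")) {
    if (length(unique(samples[[col]])) != 1L) {
      stop("`samples` must contain exactly one ", col)
    }
  }
  if (length(unique(samples$zt)) < 3L) {
    stop("at least 3 distinct zeitgeber times are required")
  }
  ord <- order(samples$zt)
  s <- rhythm_series(samples$zt[ord], samples$delta_ct[ord],
                     subject_id = paste0(samples$species[1], "/", samples$organ[1]),
                     group = samples$group[1], marker = samples$gene[1],
                     strict = FALSE)
  fit <- fit_cosinor(s, period = period)
  fit$species <- samples$species[1]
  fit$organ <- samples$organ[1]
  fit$gene <- samples$gene[1]
  fit$rhythmic <- is.finite(fit$p_value) && fit$p_value < alpha
  fit
}

#' Compare a clock gene's rhythm between case and control animals
#'
#' Mesor and amplitude contrasts are `case - control` with Wald CIs from the
#' combined standard errors `sqrt(se1^2 + se2^2)` and Welch-Satterthwaite t
#' quantiles; the acrophase contrast is the signed circular difference
#' ([circular_diff()]) with a delta-method combined standard error, its
#' confidence limits built from the arcsine-bounded per-group phase
#' uncertainties of classical cosinor interval practice, and capped at 24 h
#' width (and flagged) when the phase is unconstrained - including when
#' either group's rhythm is not detectable. Note that on the delta-Ct scale
#' the acrophase marks the expression trough.
#'
#' @param fit_case,fit_ctrl `cosinor_fit` objects from [fit_group_rhythm()]
#'   for the same species/organ/gene.
#' @param conf_level Confidence level.
#' @param alpha Significance level for the per-group rhythmicity verdicts.
#' @return Object of class `gene_rhythm_comparison`: per-group fits,
#'   a `contrasts` data frame (`B`, `lower`, `upper`, flags), and per-group
#'   rhythmicity verdicts.
#' @examples
#' a <- as_cosinor_fit(6.8, 0.5, parse_clock("03:59"), gene = "Clock")
#' b <- as_cosinor_fit(7.0, 0.1, parse_clock("21:33"), gene = "Clock")
#' compare_groups(a, b)$contrasts
#' @export
compare_groups <- function(fit_case, fit_ctrl, conf_level = 0.95, alpha = 0.05) {
  stopifnot(inherits(fit_case, "cosinor_fit"), inherits(fit_ctrl, "cosinor_fit"))
  for (key in c("species", "organ", "gene")) {
    a <- fit_case[[key]]; b <- fit_ctrl[[key]]
    if (!is.null(a) && !is.null(b) && !identical(a, b)) {
      stop("fits do not refer to the same ", key, " (", a, " vs ", b, ")")
    }
  }
  comb_se <- function(k) sqrt(fit_case$se[k]^2 + fit_ctrl$se[k]^2)
  # Welch-Satterthwaite t quantile; falls back to normal when residual
  # degrees of freedom are unavailable (fits built from published values)
  crit_q <- function(k) {
    df1 <- fit_case$df_residual; df2 <- fit_ctrl$df_residual
    s1 <- fit_case$se[k]^2; s2 <- fit_ctrl$se[k]^2
    a <- 1 - (1 - conf_level) / 2
    if (is.null(df1) || is.null(df2) || is.na(df1) || is.na(df2) ||
        !is.finite(s1) || !is.finite(s2) || s1 + s2 == 0) {
      return(stats::qnorm(a))
    }
    df_eff <- (s1 + s2)^2 / (s1^2 / df1 + s2^2 / df2)
    stats::qt(a, df_eff)
  }

  verdict <- function(f) {
    if (!is.null(f$rhythmic)) f$rhythmic
    else is.finite(f$p_value %||% NA_real_) && f$p_value < alpha
  }
  rows <- list()
  for (k in c("mesor", "amplitude")) {
    est <- fit_case[[k]] - fit_ctrl[[k]]
    se <- unname(comb_se(k))
    q <- crit_q(k)
    rows[[k]] <- data.frame(parameter = k, B = est,
                            lower = est - q * se, upper = est + q * se,
                            se = se, ci_capped = FALSE)
  }
  phi_ok <- isTRUE(fit_case$phi_defined) && isTRUE(fit_ctrl$phi_defined)
  if (phi_ok) {
    est <- circular_diff(fit_case$acrophase, fit_ctrl$acrophase)
    se <- unname(comb_se("acrophase"))
    q <- crit_q("acrophase")
    # per-group phase half-uncertainty in classical cosinor form: the
    # linear (delta-method) term q * se_phi is passed through arcsin, which
    # respects the bounded geometry of a phase around the circle and
    # saturates to half the circle when the tangential uncertainty reaches
    # the amplitude (a group whose phase is unconstrained)
    omega <- 2 * pi / fit_case$period
    half_arc <- function(f) {
      x <- q * f$se[["acrophase"]] * omega
      if (!is.finite(x)) return(Inf)
      if (x >= 1) return(12)
      asin(x) / omega
    }
    h <- sqrt(half_arc(fit_case)^2 + half_arc(fit_ctrl)^2)
    # a group without a detectable rhythm does not constrain its phase: the
    # contrast CI is then the full circle, flagged, as is any interval
    # wider than the period
    capped <- !is.finite(h) || 2 * h > 24 ||
      !verdict(fit_case) || !verdict(fit_ctrl)
    if (capped) h <- 12
    rows$acrophase <- data.frame(parameter = "acrophase", B = est,
                                 lower = est - h, upper = est + h, se = se,
                                 ci_capped = capped)
  } else {
    rows$acrophase <- data.frame(parameter = "acrophase", B = NA_real_,
                                 lower = NA_real_, upper = NA_real_,
                                 se = NA_real_, ci_capped = NA)
  }
  contrasts <- do.call(rbind, rows)
  rownames(contrasts) <- NULL
  structure(
    list(species = fit_case$species, organ = fit_case$organ,
         gene = fit_case$gene, fit_case = fit_case, fit_ctrl = fit_ctrl,
         contrasts = contrasts,
         rhythmic = c(case = verdict(fit_case), control = verdict(fit_ctrl)),
         conf_level = conf_level,
         note = "delta-Ct acrophase marks the expression trough"),
    class = "gene_rhythm_comparison"
  )
}

#' @export
print.gene_rhythm_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("%s %s %s: rhythm comparison (case vs control)\n",
              x$species %||% "", x$organ %||% "", x$gene %||% ""))
  tab <- x$contrasts
  tab[c("B", "lower", "upper", "se")] <-
    lapply(tab[c("B", "lower", "upper", "se")], round, digits)
  print(tab, row.names = FALSE)
  if (!is.na(tab$B[tab$parameter == "acrophase"][1])) {
    cat("  acrophase shift:",
        format_clock(x$contrasts$B[x$contrasts$parameter == "acrophase"]), "h\n")
  }
  cat("  rhythmic (zero-amplitude test):",
      paste(names(x$rhythmic), ifelse(x$rhythmic, "S", "NS"), collapse = ", "),
      "\n  note:", x$note, "\n")
  invisible(x)
}

#' Phase relation between two rhythms
#'
#' Signed circular acrophase offset between two rhythmic fits, classified as
#' in-phase (|offset| at most `in_phase_max` hours), anti-phase (|offset| at
#' least `anti_phase_min` hours) or intermediate. Used for within-organ gene
#' pairs (positive-limb *Bmal1*/*Clock* versus negative-limb *Per*/*Cry*) and
#' for nocturnal-vs-diurnal species contrasts.
#'
#' @param fit1,fit2 Rhythmic `cosinor_fit` objects (zero-amplitude test
#'   significant at `alpha`); non-rhythmic input is an error.
#' @param in_phase_max,anti_phase_min Classification thresholds in hours.
#' @param alpha Significance level for the rhythmicity requirement.
#' @return List with `offset` (hours, in `(-12, 12]`) and `relation`.
#' @examples
#' a <- fit_group_rhythm(transform(expand.grid(animal_id = 1:4,
#'   zt = c(1, 4, 7.5, 11, 14.5, 18, 21.5)), species = "mouse", group = "HF",
#'   organ = "heart", gene = "Bmal1", delta_ct = 9.5 + 1.3 *
#'     cos(2 * pi * (zt - 23) / 24)))
#' b <- fit_group_rhythm(transform(expand.grid(animal_id = 1:4,
#'   zt = c(1, 4, 7.5, 11, 14.5, 18, 21.5)), species = "mouse", group = "HF",
#'   organ = "heart", gene = "Per1", delta_ct = 4 + 1 *
#'     cos(2 * pi * (zt - 11) / 24)))
#' phase_relation(a, b)
#' @export
phase_relation <- function(fit1, fit2, in_phase_max = 4, anti_phase_min = 8,
                           alpha = 0.05) {
  stopifnot(inherits(fit1, "cosinor_fit"), inherits(fit2, "cosinor_fit"))
  rhythmic <- function(f) {
    if (!is.null(f$rhythmic)) return(isTRUE(f$rhythmic))
    is.finite(f$p_value %||% NA_real_) && f$p_value < alpha
  }
  if (!rhythmic(fit1) || !rhythmic(fit2)) {
    stop("phase relations are only defined between rhythmic fits")
  }
  off <- circular_diff(fit1$acrophase, fit2$acrophase)
  rel <- if (abs(off) <= in_phase_max) "in_phase"
         else if (abs(off) >= anti_phase_min) "anti_phase"
         else "intermediate"
  list(offset = off, relation = rel)
}
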