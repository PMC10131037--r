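# Readers, writers and the pipeline drivers chaining the stages into the two
# study arms: human cohort (LOD -> per-subject cosinor -> pooling ->
# variation metrics -> regressions -> dipping) and animal panel (delta-Ct ->
# per-group cosinor -> case-control comparison -> phase relations).

#' Read a long-format hormone measurement CSV
#'
#' Expected columns: `subject_id`, `group`, `marker`, `clock_time` (HH:MM or
#' decimal hours), `value`, and optionally `below_lod` (0/1). Clock times are
#' converted to decimal hours and monotonically unwrapped across midnight per
#' subject x marker (rows must be in sampling order within a series).
#'
#' @param path CSV path, or a data frame already in the same schema.
#' @return Standardised data frame with a decimal-hour `time` column.
#' @export
read_hormone_csv <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "marker", "clock_time", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("hormone table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(df$below_lod)) df$below_lod <- 0L
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad)) {
    stop("non-numeric value(s) at row(s): ", paste(utils::head(bad, 10), collapse = ", "))
  }
  df$value <- as.numeric(df$value)
  clock <- parse_clock(df$clock_time)
  df$time <- NA_real_
  for (key in split(seq_len(nrow(df)), list(df$subject_id, df$marker), drop = TRUE)) {
    df$time[key] <- unwrap_times(clock[key])
  }
  df
}

#' Split a standardised hormone table into per-subject series
#'
#' @param df Output of [read_hormone_csv()].
#' @param marker Marker to extract.
#' @return Named list of [rhythm_series()], one per subject.
#' @export
split_series <- function(df, marker) {
  d <- df[df$marker == marker, , drop = FALSE]
  if (!nrow(d)) stop("no rows for marker '", marker, "'")
  lapply(split(d, d$subject_id, drop = TRUE), function(s) {
    rhythm_series(s$time, s$value, censored = s$below_lod > 0,
                  subject_id = s$subject_id[1], group = s$group[1],
                  marker = marker)
  })
}

#' Read a qPCR Ct CSV
#'
#' @param path CSV path or equivalent data frame with columns `animal_id`,
#'   `species`, `group`, `organ`, `gene`, `zt`, `ct_target`,
#'   `ct_housekeeping`.
#' @return Data frame.
#' @export
read_ct_csv <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "species", "group", "organ", "gene", "zt",
            "ct_target", "ct_housekeeping")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ct table missing column(s): ", paste(miss, collapse = ", "))
  df$zt <- as.numeric(df$zt)
  df
}

#' Fit per-subject cosinors for one marker of a cohort table
#'
#' Applies the marker's detection-limit substitution (when configured),
#' excludes subjects whose samples are all below the limit (they carry no
#' rhythm information), and fits [fit_cosinor()] per subject.
#'
#' @param measurements Hormone table ([read_hormone_csv()] schema or the
#'   `measurements` element of [generate_hormone_cohort()]).
#' @param marker Marker name.
#' @param log_scale Fit on the log scale.
#' @param lod Optional [assay_config()].
#' @param period Period in hours.
#' @return Named list of `cosinor_fit`; attribute `excluded` lists subjects
#'   dropped for all-censored series.
#' @export
fit_cohort <- function(measurements, marker, log_scale = FALSE, lod = NULL,
                       period = 24) {
  df <- read_hormone_csv(measurements)
  series <- split_series(df, marker)
  excluded <- character(0)
  if (!is.null(lod)) {
    series <- lapply(series, apply_lod, config = lod)
    all_cens <- vapply(series, function(s) all(s$censored), TRUE)
    excluded <- names(series)[all_cens]
    series <- series[!all_cens]
    if (length(excluded)) {
      message(length(excluded), " subject(s) excluded for ", marker,
              ": all samples below the detection limit")
    }
  }
  fits <- lapply(series, fit_cosinor, period = period, log_scale = log_scale)
  attr(fits, "excluded") <- excluded
  fits
}

#' Pipeline run configuration
#'
#' @param hormones Hormone measurement table or CSV path (human arm).
#' @param covariates Covariate table or CSV path (`subject_id` + confounder
#'   columns).
#' @param abpm Ambulatory BP/HR table or CSV path, or `NULL`.
#' @param ct qPCR Ct table or CSV path (animal arm), or `NULL`.
#' @param markers Named list of per-marker settings: `scale` (`"log"` or
#'   `"linear"`), optional `lod`/`substitute`, optional acrophase `center`
#'   (clock hours; `NULL` = data-driven circular mean).
#' @param alpha Significance level.
#' @param adjust_for Confounder column names used by the adjusted analyses.
#' @param day_window Day window for dipping classification.
#' @param out_dir Output directory for CSV reports and the run log, or `NULL`
#'   to skip writing.
#' @param seed Seed recorded in the log (the analysis itself is
#'   deterministic).
#' @return Object of class `run_config`.
#' @export
run_config <- function(hormones = NULL, covariates = NULL, abpm = NULL,
                       ct = NULL,
                       markers = list(
                         melatonin = list(scale = "log", lod = 8, substitute = 4),
                         cortisol = list(scale = "linear"),
                         ctnt = list(scale = "log", center = 9)
                       ),
                       alpha = 0.05,
                       adjust_for = c("age", "sex", "bmi", "egfr", "alcohol"),
                       day_window = c(7, 23), out_dir = NULL, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(hormones = hormones, covariates = covariates, abpm = abpm,
                 ct = ct, markers = markers, alpha = alpha,
                 adjust_for = adjust_for, day_window = day_window,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

# run expr collecting warnings/messages into a character log
collect_log <- function(expr, log_env) {
  withCallingHandlers(
    expr,
    warning = function(w) {
      log_env$log <- unique(c(log_env$log, paste("WARN:", conditionMessage(w))))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      log_env$log <- unique(c(log_env$log,
                              paste("NOTE:", trimws(conditionMessage(m)))))
      invokeRestart("muffleMessage")
    }
  )
}

#' Run the human cohort arm
#'
#' Chains detection-limit substitution, per-subject cosinor fits, pooled
#' (unadjusted and confounder-adjusted) group comparisons, min/max/circadian
#' variation summaries with group regressions, the detectable-minimum Firth
#' logistic regression for the censored marker, and dipping classification of
#' the ambulatory profiles when present. Writes `cosinor_report.csv`,
#' `variation.csv`, `variation_regressions.csv`, `dip_summary.csv` and
#' `run_log.txt` to `out_dir` when configured; deterministic given config.
#'
#' @param config A [run_config()] with at least `hormones` and `covariates`.
#' @return List of class `human_arm_report`: `pooled` (per marker:
#'   `unadjusted`/`adjusted` [pool_cosinor()] results), `report` (tidy table
#'   of all pooled rows), `variation`, `variation_regressions`,
#'   `firth` (or `NULL`), `dip` (or `NULL`), `excluded`, `log`.
#' @export
run_human_arm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$hormones)) stop("config$hormones is required")
  le <- new.env(); le$log <- character(0)
  hormones <- read_hormone_csv(config$hormones)
  covariates <- if (is.data.frame(config$covariates)) config$covariates
                else if (!is.null(config$covariates))
                  utils::read.csv(config$covariates, stringsAsFactors = FALSE)
                else NULL

  pooled <- list(); variation <- NULL; var_reg <- NULL
  excluded <- list(); firth <- NULL
  available <- intersect(names(config$markers), unique(hormones$marker))
  skipped <- setdiff(names(config$markers), available)
  if (length(skipped)) {
    le$log <- c(le$log, paste("NOTE: no data for marker(s):",
                              paste(skipped, collapse = ", ")))
  }
  for (nm in available) {
    mcfg <- config$markers[[nm]]
    lod <- if (!is.null(mcfg$lod)) assay_config(mcfg$lod, mcfg$substitute %||% (mcfg$lod / 2))
    log_scale <- identical(mcfg$scale, "log")
    fits <- collect_log(fit_cohort(hormones, nm, log_scale = log_scale, lod = lod),
                        le)
    excluded[[nm]] <- attr(fits, "excluded")
    if (length(excluded[[nm]])) {
      le$log <- c(le$log, paste0("EXCLUDE ", nm, ": ",
                                 paste(excluded[[nm]], collapse = ", "),
                                 " (all samples below LOD)"))
    }
    est <- subject_estimates(fits, center = mcfg$center %||% NULL,
                             covariates = covariates, alpha = config$alpha)
    two_groups <- length(unique(est$table$group)) == 2L
    pooled[[nm]] <- list(
      unadjusted = if (two_groups) collect_log(pool_cosinor(est, adjust = FALSE), le),
      adjusted = if (two_groups && !is.null(covariates))
        collect_log(pool_cosinor_subset(est, config$adjust_for), le),
      estimates = est
    )

    # variation metrics on the substituted series
    series <- split_series(hormones, nm)
    if (!is.null(lod)) series <- lapply(series, apply_lod, config = lod)
    vs <- do.call(rbind, lapply(series, summarize_variation))
    vs$group <- hormones$group[match(vs$subject_id, hormones$subject_id)]
    variation <- rbind(variation, vs)
    usable <- vs[!vs$all_below_lod, , drop = FALSE]
    if (length(unique(usable$group)) == 2L) {
      for (what in c("minimum", "maximum", "circadian_variation")) {
        # skip degenerate outcomes (e.g. minimum pinned at the substitute)
        if (stats::var(usable[[what]]) == 0) next
        reg <- collect_log(variation_regression(usable, what, covariates,
                                                config$adjust_for, log_scale),
                           le)
        var_reg <- rbind(var_reg, cbind(marker = nm, outcome = what, reg))
      }
    }
    if (!is.null(lod) && is.null(firth)) {
      firth <- collect_log(detectable_minimum_firth(vs, lod), le)
      if (!is.null(firth)) {
        le$log <- c(le$log, paste0("FIRTH ", nm,
                                   ": detectable-minimum split ",
                                   firth$n_detectable, " vs ",
                                   firth$n_undetectable, " (Wald CI)"))
      }
    }
  }

  dip <- NULL
  if (!is.null(config$abpm)) {
    abpm <- if (is.data.frame(config$abpm)) config$abpm
            else utils::read.csv(config$abpm, stringsAsFactors = FALSE)
    dip <- dip_summary(abpm, day = config$day_window)
  }

  report <- pooled_report_table(pooled)
  out <- structure(
    list(pooled = pooled, report = report, variation = variation,
         variation_regressions = var_reg, firth = firth, dip = dip,
         excluded = excluded, log = le$log, config = config),
    class = "human_arm_report"
  )
  if (!is.null(config$out_dir)) write_human_reports(out, config$out_dir)
  out
}

# adjusted pooling restricted to the configured confounder columns
pool_cosinor_subset <- function(est, adjust_for) {
  cv <- est$covariates
  keep <- intersect(c("subject_id", adjust_for), names(cv))
  est$covariates <- cv[, keep, drop = FALSE]
  pool_cosinor(est, adjust = TRUE)
}

variation_regression <- function(vs, what, covariates, adjust_for, log_scale) {
  y <- vs[[what]]
  g <- as.numeric(vs$group == setdiff(unique(vs$group), "control")[1])
  conf <- NULL
  if (!is.null(covariates)) {
    idx <- match(vs$subject_id, covariates$subject_id)
    conf <- covariates[idx, intersect(adjust_for, names(covariates)), drop = FALSE]
  }
  transform <- if (log_scale || min(y) > 0 && max(y) / min(y) > 5) "log" else "identity"
  unadj <- adjusted_regression(y, g, NULL, transform = transform)
  adj <- if (!is.null(conf)) adjusted_regression(y, g, conf, transform = transform)
  data.frame(
    transform = transform,
    B = unadj$B, lower = unadj$lower, upper = unadj$upper, p = unadj$p,
    B_adj = if (!is.null(adj)) adj$B else NA_real_,
    lower_adj = if (!is.null(adj)) adj$lower else NA_real_,
    upper_adj = if (!is.null(adj)) adj$upper else NA_real_,
    p_adj = if (!is.null(adj)) adj$p else NA_real_,
    stringsAsFactors = FALSE
  )
}

detectable_minimum_firth <- function(vs, lod) {
  # detectable minimum = subject's lowest sample at or above the limit,
  # i.e. no censored sample in the series
  vs$detectable <- as.numeric(vs$n_below_lod == 0)
  if (length(unique(vs$detectable)) < 2L || length(unique(vs$group)) < 2L) {
    return(NULL)
  }
  d <- data.frame(y = vs$detectable,
                  group = as.numeric(vs$group != "control"))
  fit <- firth_logistic(y ~ group, d)
  fit$n_detectable <- sum(vs$detectable == 1)
  fit$n_undetectable <- sum(vs$detectable == 0)
  fit
}

pooled_report_table <- function(pooled) {
  rows <- NULL
  for (nm in names(pooled)) {
    pc <- pooled[[nm]]$unadjusted
    if (is.null(pc)) next
    pa <- pooled[[nm]]$adjusted
    fmt <- function(e, l, u, clock = FALSE) {
      if (clock) sprintf("%s (%s; %s)", format_clock(e, wrap = TRUE),
                         format_clock(l, wrap = TRUE), format_clock(u, wrap = TRUE))
      else sprintf("%.3g (%.3g; %.3g)", e, l, u)
    }
    for (par in c("mesor", "amplitude", "acrophase")) {
      clock <- par == "acrophase"
      g <- pc$groups[pc$groups$parameter == par, ]
      b <- pc$contrasts[pc$contrasts$parameter == par, ]
      ba <- if (!is.null(pa)) pa$contrasts[pa$contrasts$parameter == par, ]
      bfmt <- function(bb) {
        if (is.null(bb) || !nrow(bb)) return(NA_character_)
        if (clock) sprintf("%s (%s; %s)", format_clock(bb$B),
                           format_clock(bb$lower), format_clock(bb$upper))
        else sprintf("%.3g (%.3g; %.3g)", bb$B, bb$lower, bb$upper)
      }
      rows <- rbind(rows, data.frame(
        marker = nm, parameter = par,
        cases = fmt(g$estimate[1], g$lower[1], g$upper[1], clock),
        controls = fmt(g$estimate[2], g$lower[2], g$upper[2], clock),
        B = bfmt(b), B_adjusted = bfmt(ba),
        stringsAsFactors = FALSE
      ))
    }
    sr <- pc$significance_rate
    rows <- rbind(rows, data.frame(
      marker = nm, parameter = "cosinor_significance",
      cases = sprintf("%.1f%%", sr[[pc$case_group]]),
      controls = sprintf("%.1f%%", sr[[pc$ref_group]]),
      B = NA_character_, B_adjusted = NA_character_, stringsAsFactors = FALSE
    ))
  }
  rows
}

write_human_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$report, file.path(out_dir, "cosinor_report.csv"),
                   row.names = FALSE)
  utils::write.csv(res$variation, file.path(out_dir, "variation.csv"),
                   row.names = FALSE)
  if (!is.null(res$variation_regressions)) {
    utils::write.csv(res$variation_regressions,
                     file.path(out_dir, "variation_regressions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$dip)) {
    utils::write.csv(res$dip, file.path(out_dir, "dip_summary.csv"),
                     row.names = FALSE)
  }
  writeLines(c(paste("rhythmkit", as.character(utils::packageVersion("rhythmkit"))),
               paste("seed:", res$config$seed), res$log),
             file.path(out_dir, "run_log.txt"))
  invisible(res)
}

#' Run the animal panel arm
#'
#' Computes delta-Ct, fits the per-group cosinor for every species x organ x
#' gene, compares the groups, and summarises phase relations between all
#' rhythmic gene pairs within each organ (and, when both species are present,
#' between species for shared organs). Writes `gene_rhythms.csv`,
#' `phase_relations.csv` and `run_log.txt` to `out_dir` when configured.
#'
#' @param config A [run_config()] with `ct` set.
#' @return List of class `animal_arm_report`: `comparisons` (named list of
#'   [compare_groups()] results), `report` (tidy per-gene table),
#'   `phase_relations` (data frame), `log`.
#' @export
run_animal_arm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$ct)) stop("config$ct is required for the animal arm")
  le <- new.env(); le$log <- character(0)
  ct <- read_ct_csv(config$ct)
  if (!nrow(ct)) stop("empty Ct table")
  samples <- collect_log(compute_delta_ct(ct), le)
  if (attr(samples, "n_rejected") > 0) {
    le$log <- c(le$log, paste("REJECT:", attr(samples, "n_rejected"),
                              "Ct row(s) with missing values"))
  }

  keys <- unique(samples[c("species", "organ", "gene")])
  if (!nrow(keys)) stop("validation error: no genes present in the Ct table")
  comparisons <- list(); report <- NULL
  fits_by_key <- list()
  for (r in seq_len(nrow(keys))) {
    k <- keys[r, ]
    sub <- samples[samples$species == k$species & samples$organ == k$organ &
                     samples$gene == k$gene, ]
    groups <- unique(sub$group)
    if (length(groups) != 2L) {
      le$log <- c(le$log, paste("SKIP:", k$species, k$organ, k$gene,
                                "- needs exactly 2 groups"))
      next
    }
    ref <- intersect(c("sham", "control", "ctrl"), groups)
    ref <- if (length(ref)) ref[1] else sort(groups)[1]
    case <- setdiff(groups, ref)
    f_case <- fit_group_rhythm(sub[sub$group == case, ], alpha = config$alpha)
    f_ctrl <- fit_group_rhythm(sub[sub$group == ref, ], alpha = config$alpha)
    cmp <- compare_groups(f_case, f_ctrl, alpha = config$alpha)
    key <- paste(k$species, k$organ, k$gene, sep = "/")
    comparisons[[key]] <- cmp
    fits_by_key[[key]] <- list(case = f_case, ctrl = f_ctrl)
    for (par in c("mesor", "amplitude", "acrophase")) {
      b <- cmp$contrasts[cmp$contrasts$parameter == par, ]
      grp_fmt <- function(f) {
        if (par == "acrophase") {
          if (isTRUE(f$phi_defined)) format_clock(f$acrophase, wrap = TRUE) else NA
        } else sprintf("%.2f", f[[par]])
      }
      report <- rbind(report, data.frame(
        species = k$species, organ = k$organ, gene = k$gene, parameter = par,
        case = grp_fmt(f_case), control = grp_fmt(f_ctrl),
        B = if (par == "acrophase" && !is.na(b$B)) format_clock(b$B)
            else sprintf("%.2f", b$B),
        lower = b$lower, upper = b$upper, ci_capped = b$ci_capped,
        rhythmic_case = ifelse(cmp$rhythmic["case"], "S", "NS"),
        rhythmic_control = ifelse(cmp$rhythmic["control"], "S", "NS"),
        stringsAsFactors = FALSE
      ))
    }
  }

  phase <- animal_phase_relations(fits_by_key, le)
  out <- structure(list(comparisons = comparisons, report = report,
                        phase_relations = phase, log = le$log,
                        config = config),
                   class = "animal_arm_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(config$out_dir, "gene_rhythms.csv"),
                     row.names = FALSE)
    if (!is.null(phase)) {
      utils::write.csv(phase, file.path(config$out_dir, "phase_relations.csv"),
                       row.names = FALSE)
    }
    writeLines(c(paste("rhythmkit", as.character(utils::packageVersion("rhythmkit"))),
                 paste("seed:", config$seed), le$log),
               file.path(config$out_dir, "run_log.txt"))
  }
  out
}

animal_phase_relations <- function(fits_by_key, le) {
  keys <- names(fits_by_key)
  if (length(keys) < 2L) return(NULL)
  info <- do.call(rbind, strsplit(keys, "/", fixed = TRUE))
  rows <- NULL
  add_pair <- function(k1, k2, kind) {
    f1 <- fits_by_key[[k1]]$ctrl; f2 <- fits_by_key[[k2]]$ctrl
    if (!isTRUE(f1$rhythmic) || !isTRUE(f2$rhythmic)) {
      le$log <- c(le$log, paste("PHASE SKIP:", k1, "vs", k2,
                                "- non-rhythmic control fit"))
      return(NULL)
    }
    pr <- phase_relation(f1, f2)
    data.frame(pair = paste(k1, "vs", k2), kind = kind,
               offset_h = pr$offset, relation = pr$relation,
               stringsAsFactors = FALSE)
  }
  # gene pairs within each species x organ
  for (so in unique(paste(info[, 1], info[, 2]))) {
    idx <- which(paste(info[, 1], info[, 2]) == so)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) rows <- rbind(rows, add_pair(keys[idx[a]], keys[idx[b]],
                                              "within-organ gene pair"))
    }
  }
  # species pairs for the same organ (positive-limb genes line up ~12 h apart
  # between nocturnal and diurnal species)
  organs <- intersect(info[info[, 1] == "mouse", 2], info[info[, 1] == "zebrafish", 2])
  for (org in unique(organs)) {
    m_keys <- keys[info[, 1] == "mouse" & info[, 2] == org]
    z_keys <- keys[info[, 1] == "zebrafish" & info[, 2] == org]
    for (mk in m_keys) for (zk in z_keys) {
      rows <- rbind(rows, add_pair(mk, zk, "mouse vs zebrafish"))
    }
  }
  rows
}
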