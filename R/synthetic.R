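# Seeded generators for every input the pipeline consumes: a two-group
# hormone cohort sampled at the 7-draw 24-h protocol, terminal-sampling qPCR
# panels on species-specific zeitgeber grids, and ambulatory BP/HR profiles
# with known dipping classes.  One user seed drives all draws through
# deterministic per-stream sub-seeds (see derive_seed()).

#' Specification of a synthetic two-group hormone cohort
#'
#' Defaults emulate a heart-failure case-control design: 46 cases and 24
#' controls sampled at 09:00, 13:00, 17:00, 21:00, 01:00, 05:00 and 09:00
#' (decimal hours 9, 13, ..., 33), with three markers:
#'
#' * `melatonin` (pmol/L, log-normal): nocturnal peak (acrophase ~03:41
#'   controls, ~03:55 cases), case amplitude damped to about 0.6 of the
#'   control multiplication factor, mesor ratio about 1.1, left-censored at
#'   8 pmol/L with half-LOD substitution at 4 pmol/L. The latent (log-scale)
#'   group parameters are pre-calibrated by simulation so that the pipeline's
#'   post-substitution pooled estimates match the target medians (21.9 vs
#'   19.7 pmol/L mesor; amplitude factors 5.2 vs 8.8) - see the methods
#'   vignette.
#' * `cortisol` (nmol/L, additive Gaussian): morning peak (~09:55 controls,
#'   ~10:06 cases), mesor shifted +56.8 nmol/L in cases, equal amplitudes.
#' * `ctnt` (cardiac troponin T, log-normal): small-amplitude morning-peak
#'   rhythm (amplitude factor ~1.107), no group effect.
#'
#' For log-scale markers the `control`/`case` mesor and amplitude entries are
#' on the log scale and the residual noise is multiplicative log-normal; for
#' linear markers they are in measurement units with additive Gaussian noise.
#' Between-subject variation is Gaussian on each parameter (acrophase SD
#' default 1.5 h).
#'
#' @param n_cases,n_controls Group sizes.
#' @param times Sampling times in decimal hours since first-sample midnight.
#' @param markers Named list of marker specifications (see
#'   [default_marker_specs()]).
#' @param covariates Covariate-distribution specification (see
#'   [default_covariate_spec()]).
#' @param seed Integer seed controlling all draws.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 46, n_controls = 24,
                        times = c(9, 13, 17, 21, 25, 29, 33),
                        markers = default_marker_specs(),
                        covariates = default_covariate_spec(),
                        seed = 1L) {
  spec <- structure(
    list(n_cases = n_cases, n_controls = n_controls, times = times,
         markers = markers, covariates = covariates, seed = seed),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' Default per-marker generating parameters for the synthetic cohort
#'
#' @return Named list of marker specifications; each holds `scale`
#'   (`"log"`/`"linear"`), optional `lod`/`substitute`, optional `floor`
#'   (assay lower bound for additive markers), per-group parameter vectors
#'   `control`/`case` (`mesor`, `amplitude`, `acrophase`), between-subject
#'   SDs `sd`, and residual SD `resid_sd`.
#' @export
default_marker_specs <- function() {
  list(
    melatonin = list(
      scale = "log", lod = 8, substitute = 4, floor = NULL,
      # latent log-scale parameters; calibrated so the post-substitution
      # pipeline recovers mesor medians 21.9/19.7 and amplitude factors
      # 5.2/8.8 (multiplication factors relative to the mesor)
      control = c(mesor = 2.6238, amplitude = 2.8191, acrophase = 3.6833),
      case = c(mesor = 3.0843, amplitude = 1.6709, acrophase = 3.9167),
      sd = c(mesor = 0.50, amplitude = 0.35, acrophase = 1.5),
      resid_sd = 0.35
    ),
    cortisol = list(
      scale = "linear", lod = NULL, substitute = NULL, floor = 1,
      control = c(mesor = 275.1, amplitude = 165.7, acrophase = 9.9167),
      case = c(mesor = 331.9, amplitude = 165.5, acrophase = 10.1),
      sd = c(mesor = 40, amplitude = 25, acrophase = 1.5),
      resid_sd = 30
    ),
    ctnt = list(
      scale = "log", lod = NULL, substitute = NULL, floor = NULL,
      control = c(mesor = log(0.026), amplitude = log(1.107), acrophase = 4.9333),
      case = c(mesor = log(0.026), amplitude = log(1.107), acrophase = 4.9333),
      sd = c(mesor = 0.40, amplitude = 0.05, acrophase = 1.5),
      resid_sd = 0.08
    )
  )
}

#' Default covariate distributions for the synthetic cohort
#'
#' Age (years), sex (1 = male), BMI (kg/m^2), eGFR (mL/min/1.73 m^2) and
#' alcohol consumption (IU/week), with mild group offsets typical of a
#' heart-failure case-control sample.
#'
#' @return List with `case` and `control` sub-lists of distribution
#'   parameters.
#' @export
default_covariate_spec <- function() {
  list(
    case = list(age = c(mean = 60, sd = 10), sex_p_male = 0.72,
                bmi = c(mean = 25.5, sd = 4.6), egfr = c(mean = 70.2, sd = 23.8),
                alcohol_mean = 2),
    control = list(age = c(mean = 56, sd = 10), sex_p_male = 0.71,
                   bmi = c(mean = 24.9, sd = 3.5), egfr = c(mean = 77.4, sd = 21.7),
                   alcohol_mean = 7)
  )
}

validate_cohort_spec <- function(spec) {
  problems <- character(0)
  if (!isTRUE(spec$n_cases > 0)) problems <- c(problems, "n_cases must be > 0")
  if (!isTRUE(spec$n_controls > 0)) problems <- c(problems, "n_controls must be > 0")
  if (length(spec$times) < 4 || any(diff(spec$times) <= 0)) {
    problems <- c(problems, "times must be >= 4 strictly increasing values")
  }
  if (!length(spec$markers)) problems <- c(problems, "at least one marker is required")
  for (nm in names(spec$markers)) {
    m <- spec$markers[[nm]]
    if (!m$scale %in% c("log", "linear")) {
      problems <- c(problems, paste0(nm, ": scale must be 'log' or 'linear'"))
    }
    for (g in c("control", "case")) {
      pars <- m[[g]]
      if (is.null(pars) || !all(c("mesor", "amplitude", "acrophase") %in% names(pars))) {
        problems <- c(problems, paste0(nm, ": ", g, " parameters incomplete"))
      }
    }
    if (any(m$sd < 0) || m$resid_sd < 0) {
      problems <- c(problems, paste0(nm, ": SDs must be nonnegative"))
    }
    if (!is.null(m$lod) && !(m$substitute > 0 && m$substitute < m$lod)) {
      problems <- c(problems, paste0(nm, ": need 0 < substitute < lod"))
    }
  }
  if (length(problems)) {
    stop("invalid cohort spec:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(spec)
}

#' Generate a synthetic hormone cohort
#'
#' Draws per-subject rhythm parameters from the group-level distributions of
#' a [cohort_spec()], evaluates each subject's cosine trajectory at the
#' sampling times, and adds noise (multiplicative log-normal for log-scale
#' markers, additive Gaussian for linear ones). Values below a marker's
#' detection limit are flagged; substitution is left to [apply_lod()] in the
#' analysis arm, mirroring how assay exports carry a below-LOD flag.
#' Deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `measurements` (long table: `subject_id`, `group`,
#'   `marker`, `clock_time` in HH:MM, `value`, `below_lod`), `covariates`
#'   (one row per subject) and `truth` (the drawn per-subject rhythm
#'   parameters on the analysis scale, for recovery studies).
#' @examples
#' cohort <- generate_hormone_cohort(cohort_spec(n_cases = 5, n_controls = 4,
#'                                               seed = 7))
#' head(cohort$measurements)
#' @export
generate_hormone_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_cases + spec$n_controls
  subject_id <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
                  sprintf("ctrl_%03d", seq_len(spec$n_controls)))
  group <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  tt <- spec$times
  omega <- 2 * pi / 24

  meas <- vector("list", length(spec$markers))
  truth <- vector("list", length(spec$markers))
  for (j in seq_along(spec$markers)) {
    nm <- names(spec$markers)[j]
    m <- spec$markers[[j]]
    set.seed(derive_seed(spec$seed, j))
    rows <- vector("list", n)
    drawn <- matrix(NA_real_, n, 3,
                    dimnames = list(NULL, c("mesor", "amplitude", "acrophase")))
    for (i in seq_len(n)) {
      pars <- m[[group[i]]]
      mes <- stats::rnorm(1, pars["mesor"], m$sd["mesor"])
      amp <- abs(stats::rnorm(1, pars["amplitude"], m$sd["amplitude"]))
      phi <- stats::rnorm(1, pars["acrophase"], m$sd["acrophase"])
      drawn[i, ] <- c(mes, amp, phi)
      mu <- mes + amp * cos(omega * (tt - phi))
      eps <- stats::rnorm(length(tt), 0, m$resid_sd)
      value <- if (m$scale == "log") exp(mu + eps) else mu + eps
      if (!is.null(m$floor)) value <- pmax(value, m$floor)
      rows[[i]] <- data.frame(
        subject_id = subject_id[i], group = group[i], marker = nm,
        clock_time = format_clock(tt, wrap = TRUE), value = value,
        below_lod = if (!is.null(m$lod)) as.integer(value < m$lod) else 0L,
        stringsAsFactors = FALSE
      )
    }
    meas[[j]] <- do.call(rbind, rows)
    truth[[j]] <- data.frame(subject_id = subject_id, group = group,
                             marker = nm, drawn, stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, meas)
  rownames(measurements) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  set.seed(derive_seed(spec$seed, 1000L))
  cv <- spec$covariates
  covariates <- do.call(rbind, lapply(seq_len(n), function(i) {
    cs <- cv[[group[i]]]
    data.frame(
      subject_id = subject_id[i], group = group[i],
      age = round(stats::rnorm(1, cs$age["mean"], cs$age["sd"])),
      sex = stats::rbinom(1, 1, cs$sex_p_male),
      bmi = round(stats::rnorm(1, cs$bmi["mean"], cs$bmi["sd"]), 1),
      egfr = round(stats::rnorm(1, cs$egfr["mean"], cs$egfr["sd"]), 1),
      alcohol = round(stats::rexp(1, 1 / cs$alcohol_mean)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(covariates) <- NULL
  list(measurements = measurements, covariates = covariates, truth = truth)
}

#' Reference clock-gene generating parameters for animal panels
#'
#' Per-organ, per-gene, per-group (HF vs control) mesor, amplitude and
#' acrophase of the delta-Ct rhythm used as generator defaults: core-clock
#' panels for a nocturnal mouse heart-failure model (heart, kidney, liver;
#' *Per1*, *Bmal1*, *Clock*, *Cry2*) and a diurnal zebrafish anaemia model
#' (heart, kidney; *per3*, *arntl1b*, *clocka*, *cry1ba*), with positive-limb
#' genes (*Bmal1*/*arntl1b*, *Clock*/*clocka*) roughly in anti-phase to the
#' negative limb (*Per*, *Cry*) and the two species about 12 h apart.
#'
#' @param species `"mouse"` or `"zebrafish"`.
#' @return Data frame with columns `organ`, `gene`, `group`, `mesor`,
#'   `amplitude`, `acrophase` (hours).
#' @export
clock_gene_params <- function(species = c("mouse", "zebrafish")) {
  species <- match.arg(species)
  g <- function(organ, gene, group, mesor, amplitude, acrophase) {
    data.frame(organ = organ, gene = gene, group = group, mesor = mesor,
               amplitude = amplitude, acrophase = parse_clock(acrophase),
               stringsAsFactors = FALSE)
  }
  tab <- if (species == "mouse") rbind(
    g("heart", "Per1", "HF", 3.9, 1.3, "01:32"),
    g("heart", "Per1", "sham", 4.0, 1.0, "01:36"),
    g("heart", "Bmal1", "HF", 9.6, 1.3, "22:53"),
    g("heart", "Bmal1", "sham", 9.5, 1.3, "22:59"),
    g("heart", "Clock", "HF", 6.8, 0.5, "03:59"),
    g("heart", "Clock", "sham", 7.0, 0.1, "21:33"),
    g("heart", "Cry2", "HF", 4.9, 0.5, "19:58"),
    g("heart", "Cry2", "sham", 4.8, 0.3, "22:19"),
    g("kidney", "Per1", "HF", 4.0, 0.8, "23:13"),
    g("kidney", "Per1", "sham", 3.9, 0.6, "00:02"),
    g("kidney", "Bmal1", "HF", 6.0, 1.6, "01:00"),
    g("kidney", "Bmal1", "sham", 6.2, 1.8, "00:58"),
    g("liver", "Per1", "HF", 12.6, 14.7, "02:43"),
    g("liver", "Per1", "sham", 4.6, 1.2, "22:48"),
    g("liver", "Bmal1", "HF", 7.7, 2.8, "00:08"),
    g("liver", "Bmal1", "sham", 8.0, 2.5, "00:51")
  ) else rbind(
    g("heart", "per3", "HF", 10.1, 2.5, "20:08"),
    g("heart", "per3", "control", 9.2, 2.5, "19:35"),
    g("heart", "arntl1b", "HF", 9.7, 1.6, "23:00"),
    g("heart", "arntl1b", "control", 9.8, 2.2, "23:05"),
    g("heart", "clocka", "HF", 10.4, 1.4, "21:13"),
    g("heart", "clocka", "control", 10.4, 1.7, "21:17"),
    g("heart", "cry1ba", "HF", 7.7, 1.7, "01:45"),
    g("heart", "cry1ba", "control", 8.0, 1.5, "00:28"),
    g("kidney", "per3", "HF", 9.2, 1.8, "20:15"),
    g("kidney", "per3", "control", 8.8, 2.0, "20:39"),
    g("kidney", "arntl1b", "HF", 9.4, 0.7, "23:13"),
    g("kidney", "arntl1b", "control", 9.4, 1.1, "22:09")
  )
  rownames(tab) <- NULL
  tab
}

#' Specification of a synthetic qPCR animal panel
#'
#' @param species `"mouse"` (zeitgeber grid 1, 4, 7.5, 11, 14.5, 18, 21.5;
#'   default 4 animals per group per ZT) or `"zebrafish"` (grid 0, 4, 8, 12,
#'   16, 20; default 3 pooled samples per group per ZT).
#' @param genes Data frame of generating parameters as returned by
#'   [clock_gene_params()].
#' @param n_per_zt Replicates per group per zeitgeber time.
#' @param ct_noise_sd Additive Gaussian noise SD on the Ct scale.
#' @param housekeeping_mean,housekeeping_sd Housekeeping-gene Ct level; kept
#'   flat with small noise so the delta-Ct carries the rhythm.
#' @param seed Integer seed.
#' @return Object of class `animal_spec`.
#' @export
animal_spec <- function(species = c("mouse", "zebrafish"),
                        genes = clock_gene_params(species),
                        n_per_zt = if (species == "mouse") 4L else 3L,
                        ct_noise_sd = if (species == "mouse") 0.7 else 0.5,
                        housekeeping_mean = 20, housekeeping_sd = 0.1,
                        seed = 1L) {
  species <- match.arg(species)
  force(genes); force(n_per_zt); force(ct_noise_sd)
  if (!nrow(genes)) stop("invalid animal spec: empty gene list")
  need <- c("organ", "gene", "group", "mesor", "amplitude", "acrophase")
  if (!all(need %in% names(genes))) {
    stop("invalid animal spec: gene table needs columns ",
         paste(need, collapse = ", "))
  }
  if (n_per_zt < 1) stop("invalid animal spec: n_per_zt must be >= 1")
  if (ct_noise_sd < 0 || housekeeping_sd < 0) {
    stop("invalid animal spec: noise SDs must be nonnegative")
  }
  structure(list(species = species, genes = genes, zt = ZT_GRIDS[[species]],
                 n_per_zt = as.integer(n_per_zt), ct_noise_sd = ct_noise_sd,
                 housekeeping_mean = housekeeping_mean,
                 housekeeping_sd = housekeeping_sd, seed = seed),
            class = "animal_spec")
}

#' Generate a synthetic qPCR Ct table
#'
#' For every organ/gene/group/zeitgeber-time cell, draws `n_per_zt` terminal
#' animals: the housekeeping Ct is flat with small noise and the target Ct is
#' housekeeping + the generating delta-Ct cosine + Gaussian noise, so that
#' the delta-Ct (target - housekeeping) carries the rhythm. Deterministic
#' given the spec seed.
#'
#' @param spec An [animal_spec()].
#' @return Data frame with columns `animal_id`, `species`, `group`, `organ`,
#'   `gene`, `zt`, `ct_target`, `ct_housekeeping` (the input schema of
#'   [compute_delta_ct()]).
#' @examples
#' panel <- generate_animal_panel(animal_spec("mouse", seed = 3))
#' head(panel)
#' @export
generate_animal_panel <- function(spec) {
  stopifnot(inherits(spec, "animal_spec"))
  set.seed(derive_seed(spec$seed, 2000L))
  omega <- 2 * pi / 24
  cells <- merge(spec$genes, data.frame(zt = spec$zt))
  # radix = C-locale ordering, so the RNG-to-cell assignment does not depend
  # on the session locale
  cells <- cells[order(cells$organ, cells$gene, cells$group, cells$zt,
                       method = "radix"), ]
  out <- vector("list", nrow(cells))
  counter <- 0L
  for (r in seq_len(nrow(cells))) {
    cl <- cells[r, ]
    dct_true <- cl$mesor + cl$amplitude * cos(omega * (cl$zt - cl$acrophase))
    hk <- stats::rnorm(spec$n_per_zt, spec$housekeeping_mean, spec$housekeeping_sd)
    dct <- dct_true + stats::rnorm(spec$n_per_zt, 0, spec$ct_noise_sd)
    ids <- sprintf("%s_%s_%04d", substr(spec$species, 1, 2), cl$group,
                   counter + seq_len(spec$n_per_zt))
    counter <- counter + spec$n_per_zt
    out[[r]] <- data.frame(
      animal_id = ids, species = spec$species, group = cl$group,
      organ = cl$organ, gene = cl$gene, zt = cl$zt,
      ct_target = hk + dct, ct_housekeeping = hk, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate synthetic ambulatory BP/HR profiles with known dipping classes
#'
#' Assigns each subject a dipping class by exact (largest-remainder) rounding
#' of the requested class fractions, draws a class-consistent dip fraction
#' (dipper: 10-25% fall; non-dipper: 0 to <10%; riser: nocturnal rise up to
#' 10%), and builds hourly systolic/diastolic/heart-rate series whose day and
#' night window means hit the subject's targets exactly, so that
#' [classify_dip()] recovers the assigned class for every subject.
#'
#' @param n Number of subjects.
#' @param fractions Length-3 numeric `(dipper, non_dipper, riser)` summing
#'   to 1; defaults to 8/36, 21/36, 7/36.
#' @param seed Integer seed.
#' @param day Day window in clock hours.
#' @param day_means Named day-window means for channels `sbp`, `dbp`, `hr`.
#' @return Long data frame (`subject_id`, `channel`, `clock_time`, `value`)
#'   with attribute `truth` (assigned class and dip fraction per subject).
#' @examples
#' abpm <- generate_abpm(n = 12, seed = 5)
#' table(attr(abpm, "truth")$class)
#' @export
generate_abpm <- function(n = 36, fractions = c(8, 21, 7) / 36, seed = 1L,
                          day = c(7, 23),
                          day_means = c(sbp = 104, dbp = 65, hr = 70)) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three class proportions summing to 1")
  }
  set.seed(derive_seed(seed, 3000L))
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    counts[order(raw - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(raw - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  classes <- rep(c("dipper", "non_dipper", "riser"), counts)
  dip <- numeric(n)
  dip[classes == "dipper"] <- stats::runif(counts[1], 0.10, 0.25)
  dip[classes == "non_dipper"] <- stats::runif(counts[2], 0, 0.0995)
  dip[classes == "riser"] <- stats::runif(counts[3], -0.10, -0.005)

  hours <- 0:23
  in_day <- hours >= day[1] & hours < day[2]
  sd_channel <- c(sbp = 8, dbp = 6, hr = 8)
  noise_sd <- 4
  out <- vector("list", n * 3L)
  k <- 0L
  for (i in seq_len(n)) {
    for (ch in names(day_means)) {
      dm <- stats::rnorm(1, day_means[[ch]], sd_channel[[ch]])
      nm <- dm * (1 - dip[i])
      target <- ifelse(in_day, dm, nm)
      v <- target + stats::rnorm(24, 0, noise_sd)
      # recentre each window so the window means equal the targets exactly
      v[in_day] <- v[in_day] - mean(v[in_day]) + dm
      v[!in_day] <- v[!in_day] - mean(v[!in_day]) + nm
      k <- k + 1L
      out[[k]] <- data.frame(
        subject_id = sprintf("abpm_%03d", i), channel = ch,
        clock_time = format_clock(hours), value = v,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- data.frame(
    subject_id = sprintf("abpm_%03d", seq_len(n)), class = classes,
    dip_fraction = dip, stringsAsFactors = FALSE
  )
  res
}
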