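test_that("cohort generation is deterministic given the seed", {
  spec <- cohort_spec(n_cases = 8, n_controls = 5, seed = 123)
  a <- generate_hormone_cohort(spec)
  b <- generate_hormone_cohort(spec)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$covariates, b$covariates)
  c2 <- generate_hormone_cohort(cohort_spec(n_cases = 8, n_controls = 5,
                                            seed = 124))
  expect_false(identical(a$measurements$value, c2$measurements$value))
})

test_that("a zero-noise spec produces the exact population cosine", {
  spec <- cohort_spec(n_cases = 2, n_controls = 2, seed = 1)
  for (nm in names(spec$markers)) {
    spec$markers[[nm]]$sd[] <- 0
    spec$markers[[nm]]$resid_sd <- 0
  }
  cohort <- generate_hormone_cohort(spec)
  m <- spec$markers$cortisol
  d <- cohort$measurements
  vals <- d$value[d$marker == "cortisol" & d$subject_id == "ctrl_001"]
  expect_equal(vals, make_cosine(spec$times, m$control["mesor"],
                                 m$control["amplitude"],
                                 m$control["acrophase"]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # and every subject in a group is identical
  vals2 <- d$value[d$marker == "cortisol" & d$subject_id == "ctrl_002"]
  expect_equal(vals, vals2)
})

test_that("generated tables validate against the reader schemas", {
  cohort <- generate_hormone_cohort(cohort_spec(n_cases = 4, n_controls = 3,
                                                seed = 2))
  expect_no_warning(df <- read_hormone_csv(cohort$measurements))
  expect_true(all(c("subject_id", "group", "marker", "time", "value") %in% names(df)))
  # unwrapped sampling times reproduce the 7-draw design
  one <- df[df$subject_id == "case_001" & df$marker == "melatonin", ]
  expect_equal(one$time, hormone_times)

  panel <- generate_animal_panel(animal_spec("zebrafish", seed = 2))
  expect_no_warning(s <- compute_delta_ct(read_ct_csv(panel)))
  expect_identical(attr(s, "n_rejected"), 0L)
  expect_true(all(s$zt %in% c(0, 4, 8, 12, 16, 20)))
})

test_that("the melatonin censoring fraction rises as the mesor falls", {
  frac_below <- vapply(c(0.8, 0, -0.8), function(shift) {
    spec <- cohort_spec(n_cases = 30, n_controls = 20, seed = 5)
    spec$markers$melatonin$control["mesor"] <-
      spec$markers$melatonin$control["mesor"] + shift
    spec$markers$melatonin$case["mesor"] <-
      spec$markers$melatonin$case["mesor"] + shift
    d <- generate_hormone_cohort(spec)$measurements
    mean(d$below_lod[d$marker == "melatonin"])
  }, 0)
  expect_true(all(diff(frac_below) > 0))
})

test_that("a zero-noise animal spec is recovered exactly by the rhythm fit", {
  spec <- animal_spec("mouse", seed = 11, ct_noise_sd = 0,
                      housekeeping_sd = 0)
  panel <- generate_animal_panel(spec)
  s <- compute_delta_ct(panel)
  truth <- spec$genes[spec$genes$organ == "liver" & spec$genes$gene == "Bmal1" &
                        spec$genes$group == "HF", ]
  f <- fit_group_rhythm(s[s$organ == "liver" & s$gene == "Bmal1" &
                            s$group == "HF", ])
  expect_equal(f$mesor, truth$mesor, tolerance = 1e-9)
  expect_equal(f$amplitude, truth$amplitude, tolerance = 1e-9)
  expect_equal(circular_diff(f$acrophase, truth$acrophase), 0, tolerance = 1e-7)
})

test_that("animal amplitude estimates are unbiased over replicates", {
  # heart Bmal1-style truth: mesor 9.5, amplitude 1.3, nocturnal acrophase
  spec <- animal_spec("mouse", genes = data.frame(
    organ = "heart", gene = "Bmal1", group = "HF", mesor = 9.5,
    amplitude = 1.3, acrophase = 22.9), seed = 1)
  amps <- vapply(1:200, function(r) {
    spec$seed <- 5000 + r
    s <- compute_delta_ct(generate_animal_panel(spec))
    fit_group_rhythm(s)$amplitude
  }, 0)
  mc_se <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - 1.3), 2 * mc_se + 0.01)
})

test_that("a diurnal spec phase-shifted 12 h reads as anti-phase", {
  base <- data.frame(organ = "heart", gene = "Bmal1", group = "HF",
                     mesor = 9.5, amplitude = 1.3, acrophase = 23)
  nocturnal <- animal_spec("mouse", genes = base, seed = 3, ct_noise_sd = 0.2)
  shifted <- base; shifted$acrophase <- (23 + 12) %% 24
  diurnal <- animal_spec("mouse", genes = shifted, seed = 4, ct_noise_sd = 0.2)
  f1 <- fit_group_rhythm(compute_delta_ct(generate_animal_panel(nocturnal)))
  f2 <- fit_group_rhythm(compute_delta_ct(generate_animal_panel(diurnal)))
  expect_equal(phase_relation(f1, f2)$relation, "anti_phase")
})

test_that("ambulatory profiles round-trip their assigned dipping classes", {
  abpm <- generate_abpm(n = 36, fractions = c(8, 21, 7) / 36, seed = 9)
  truth <- attr(abpm, "truth")
  expect_equal(unname(table(truth$class)[c("dipper", "non_dipper", "riser")]),
               c(8L, 21L, 7L), ignore_attr = TRUE)
  ds <- dip_summary(abpm)
  sbp <- ds[ds$channel == "sbp", ]
  expect_equal(sbp$class[match(truth$subject_id, sbp$subject_id)], truth$class)
  # all-dipper spec
  all_dip <- dip_summary(generate_abpm(n = 10, fractions = c(1, 0, 0), seed = 2))
  expect_true(all(all_dip$class == "dipper"))
  expect_error(generate_abpm(10, fractions = c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("generated day/night systolic means match the generator settings", {
  abpm <- generate_abpm(n = 200, seed = 31)
  ds <- dip_summary(abpm)
  sbp <- ds[ds$channel == "sbp", ]
  expect_equal(mean(sbp$day_mean), 104, tolerance = 0.02)
  # mean dip fraction under the default class mix is ~5.8%, night mean ~98
  expect_equal(mean(sbp$night_mean), 98, tolerance = 0.02)
})

test_that("damped case rhythms show lower circadian variation than controls", {
  lodc <- assay_config(8, 4)
  lower <- vapply(1:200, function(r) {
    d <- generate_hormone_cohort(cohort_spec(seed = 30000 + r))$measurements
    series <- lapply(split_series(read_hormone_csv(d), "melatonin"),
                     apply_lod, config = lodc)
    vs <- do.call(rbind, lapply(series, summarize_variation))
    vs <- vs[!vs$all_below_lod, ]
    grp <- substr(vs$subject_id, 1, 4)
    median(vs$circadian_variation[grp == "case"]) <
      median(vs$circadian_variation[grp == "ctrl"])
  }, TRUE)
  expect_gte(mean(lower), 0.95)
})

test_that("invalid specs are rejected with the offending fields listed", {
  expect_error(cohort_spec(n_cases = 0), "n_cases")
  spec <- cohort_spec(n_cases = 4, n_controls = 4)
  spec$markers$melatonin$substitute <- 12
  expect_error(validate <- generate_hormone_cohort(spec), "substitute")
  expect_error(animal_spec("mouse", genes = clock_gene_params("mouse")[0, ]),
               "empty gene list")
})
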