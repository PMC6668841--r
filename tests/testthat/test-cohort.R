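test_that("severity process: degenerate, reproducible, ordered by location", {
  cfg <- cohort_config(n_admissions = 1)
  # zero noise, zero drift, start at stationary = baseline exactly
  cfg0 <- cfg
  cfg0$severity$noise_sd <- 0
  cfg0$severity$baseline_sd <- 0
  cfg0$severity$drift_sd <- 0
  tr <- simulate_severity(cfg0, "icu", 48, seed = 1)
  expect_equal(as.numeric(tr), rep(cfg0$severity$baseline[["icu"]], 48))

  a <- simulate_severity(cfg, "ward", 60, n = 3, seed = 42)
  b <- simulate_severity(cfg, "ward", 60, n = 3, seed = 42)
  expect_identical(a, b)
  expect_error(simulate_severity(cfg, "ward", 24), ">= 48")

  # Monte-Carlo check of the baseline ordering icu > ward > other
  icu <- simulate_severity(cfg, "icu", 48, n = 10000, seed = 9)
  ward <- simulate_severity(cfg, "ward", 48, n = 10000, seed = 10)
  oth <- simulate_severity(cfg, "other", 48, n = 10000, seed = 11)
  expect_gt(mean(icu), mean(ward))
  expect_gt(mean(ward), mean(oth))
})

test_that("emission: degenerate links, direction sign, clipping, errors", {
  cfg <- cohort_config(n_admissions = 1)
  cat <- cfg$catalogue
  # zero link and zero noise -> every continuous value at the normal midpoint
  cfg0 <- cfg
  cfg0$emission$link <- 0
  cfg0$emission$noise_sd <- 0
  tr <- rep(1, 48)
  obs <- emit_observations(tr, cat, cfg0, seed = 3)
  cont <- cat$name[cat$kind == "continuous" &
                     !cat$group %in% c("clinical_characteristics", "location")]
  lin <- obs[obs$variable %in% setdiff(cont, c("avpu", "gcs")), ]
  expect_equal(lin$value, cat$normal[match(lin$variable, cat$name)])

  # higher_abnormal variable: high-severity mean exceeds zero-severity mean
  hi <- emit_observations(rep(2, 48), cat, cfg, seed = 5)
  lo <- emit_observations(rep(0, 48), cat, cfg, seed = 5)
  mean_of <- function(o, v) mean(o$value[o$variable == v])
  expect_gt(mean_of(hi, "lactate"), mean_of(lo, "lactate"))
  expect_lt(mean_of(hi, "systolic_bp"), mean_of(lo, "systolic_bp"))

  # clipping: extreme severity stays inside the plausible range
  ext <- emit_observations(rep(50, 48), cat, cfg, seed = 6)
  rng <- cat[match(ext$variable, cat$name), ]
  expect_true(all(ext$value >= rng$low | rng$kind == "binary"))
  expect_true(all(ext$value <= rng$high | rng$kind == "binary"))

  # every vital has an observation in the first hour
  first <- aggregate(time_h ~ variable, data = obs, FUN = min)
  vit <- first$time_h[first$variable %in% cat$name[cat$group == "vitals"]]
  expect_true(all(vit < 1))

  cfg_bad <- cfg
  cfg_bad$emission <- cfg$emission[cfg$emission$variable != "lactate", ]
  expect_error(emit_observations(tr, cat, cfg_bad, seed = 1),
               "without emission parameters")
})

test_that("generate_cohort: preconditions, reproducibility, intercept-only rate", {
  expect_error(cohort_config(n_admissions = 0), "n_admissions")
  expect_error(cohort_config(location_probs = c(ward = 1, ed = 0.2,
                                                icu = 0, other = 0)),
               "location_probs")
  expect_error(cohort_config(female_p = 1.4), "female_p")

  c1 <- generate_cohort(cohort_config(n_admissions = 50, seed = 123))
  c2 <- generate_cohort(cohort_config(n_admissions = 50, seed = 123))
  expect_identical(c1$admissions, c2$admissions)
  expect_identical(c1$observations, c2$observations)
  expect_true(all(c1$admissions$los_days >= 2))

  # beta_* = 0 with intercept = logit(p) -> empirical rate ~ Binomial(n, p)
  cfg <- cohort_config(n_admissions = 20000, seed = 11)
  cfg$outcome$beta_severity <- 0
  cfg$outcome$beta_trend <- 0
  cfg$outcome$beta_age <- 0
  cfg$outcome$beta_female <- 0
  cfg$outcome$intercept <- qlogis(0.025)
  cfg$emission$rate_per_hour <- 0      # marginals only, keep it fast
  coh <- generate_cohort(cfg)
  rate <- mean(coh$admissions$outcome == "died")
  expect_lt(abs(rate - 0.025), 4 * sqrt(0.025 * 0.975 / 20000))
})

test_that("death rate increases strictly with the severity coefficient", {
  rates <- vapply(c(1.5, 3.2, 5.0), function(b) {
    cfg <- cohort_config(n_admissions = 6000, seed = 77)
    cfg$outcome$beta_severity <- b
    cfg$emission$rate_per_hour <- 0
    mean(generate_cohort(cfg)$admissions$outcome == "died")
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("cohort CSV round trip is lossless and malformed input is rejected", {
  coh <- generate_cohort(cohort_config(n_admissions = 30, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort_csv(coh, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$admissions$id, coh$admissions$id)
  expect_equal(back$admissions$los_days, coh$admissions$los_days,
               tolerance = 1e-12)
  expect_equal(back$observations$value, coh$observations$value,
               tolerance = 1e-12)
  expect_equal(back$catalogue$name, coh$catalogue$name)

  # determinism: regenerating writes byte-identical CSVs
  dir2 <- withr::local_tempdir()
  write_cohort_csv(generate_cohort(cohort_config(n_admissions = 30, seed = 2)),
                   dir2)
  expect_identical(readLines(file.path(dir, "observations.csv")),
                   readLines(file.path(dir2, "observations.csv")))

  # negative time is rejected with the row number
  bad <- coh
  bad$observations$time_h[5] <- -1
  dir3 <- withr::local_tempdir()
  write_cohort_csv(bad, dir3)
  expect_error(read_cohort_csv(dir3), "row 5.*negative|negative")

  # an admission with no observations is allowed (imputed later)
  empty <- coh
  keep1 <- empty$observations$id != empty$admissions$id[1]
  empty$observations <- empty$observations[keep1, ]
  dir4 <- withr::local_tempdir()
  write_cohort_csv(empty, dir4)
  expect_silent(read_cohort_csv(dir4))
})

test_that("admission_record extracts a consistent single admission", {
  coh <- small_cohort()
  rec <- admission_record(coh, coh$admissions$id[3])
  expect_equal(rec$id, coh$admissions$id[3])
  expect_true(all(rec$observations$variable %in% coh$catalogue$name))
  expect_length(rec$latent_trace, 48)
  expect_error(admission_record(coh, "zzz"), "unknown admission id")
})
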