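test_that("MEWS hits its published worked examples and bounds", {
  expect_equal(mews_at_hour(list(systolic_bp = 120, heart_rate = 80,
                                 resp_rate = 14, temperature = 37,
                                 avpu = 0)), 0L)
  # unresponsive with otherwise normal vitals scores exactly 3
  expect_equal(mews_at_hour(list(systolic_bp = 120, heart_rate = 80,
                                 resp_rate = 14, temperature = 37,
                                 avpu = "unresponsive")), 3L)
  # worst band on every component
  expect_equal(mews_at_hour(list(systolic_bp = 60, heart_rate = 150,
                                 resp_rate = 40, temperature = 34,
                                 avpu = 3)), 14L)
  expect_error(mews_at_hour(list(systolic_bp = 120, heart_rate = 80,
                                 resp_rate = 14, temperature = 37,
                                 avpu = NA)), "avpu")
})

test_that("SOFA hits its published worked examples and bounds", {
  normal <- list(pao2_fio2_ratio = 450, platelets = 250, bilirubin = 0.7,
                 mean_arterial_pressure = 85, vasopressor = 0, gcs = 15,
                 creatinine = 0.9)
  expect_equal(sofa_at_hour(normal), 0L)
  low_plt <- normal; low_plt$platelets <- 45
  expect_equal(sofa_at_hour(low_plt), 3L)       # coagulation band [20,50)
  worst <- list(pao2_fio2_ratio = 80, platelets = 10, bilirubin = 15,
                mean_arterial_pressure = 50, vasopressor = 1, gcs = 3,
                creatinine = 7)
  expect_equal(sofa_at_hour(worst), 24L)
  bad_gcs <- normal; bad_gcs$gcs <- 17
  expect_error(sofa_at_hour(bad_gcs), "gcs out of range")
  # urine variant worsens the renal component only when lower
  oliguric <- normal; oliguric$urine_output_24h <- 150
  expect_equal(sofa_at_hour(oliguric), 4L)
})

test_that("vectorized scorers equal the scalar lookup oracles on random panels", {
  set.seed(99)
  n <- 10000
  sbp <- runif(n, 40, 260); hr <- runif(n, 20, 220); rr <- runif(n, 4, 60)
  temp <- runif(n, 32, 42); avpu <- sample(0:3, n, TRUE)
  mews_vec <- mews_at_hour(list(systolic_bp = sbp, heart_rate = hr,
                                resp_rate = rr, temperature = temp,
                                avpu = avpu))
  mews_ref <- mapply(mews_oracle, sbp, hr, rr, temp, avpu)
  expect_identical(mews_vec, as.integer(mews_ref))
  expect_true(all(mews_vec >= 0 & mews_vec <= 14))

  pf <- runif(n, 40, 600); plt <- runif(n, 5, 1000); bili <- runif(n, 0.1, 30)
  map <- runif(n, 30, 180); vaso <- sample(0:1, n, TRUE)
  gcs <- sample(3:15, n, TRUE); cr <- runif(n, 0.2, 15)
  sofa_vec <- sofa_at_hour(list(pao2_fio2_ratio = pf, platelets = plt,
                                bilirubin = bili,
                                mean_arterial_pressure = map,
                                vasopressor = vaso, gcs = gcs,
                                creatinine = cr))
  sofa_ref <- mapply(sofa_oracle, pf, plt, bili, map, vaso, gcs, cr)
  expect_identical(sofa_vec, as.integer(sofa_ref))
  expect_true(all(sofa_vec >= 0 & sofa_vec <= 24))
})

test_that("worsening any single input never decreases the score", {
  base_m <- list(systolic_bp = 120, heart_rate = 80, resp_rate = 14,
                 temperature = 37, avpu = 0)
  worsen <- list(systolic_bp = seq(120, 40, by = -5),
                 heart_rate = seq(80, 220, by = 10),
                 resp_rate = seq(14, 60, by = 4),
                 temperature = seq(37, 42, by = 0.5),
                 avpu = 0:3)
  for (f in names(worsen)) {
    p <- base_m
    scores <- vapply(worsen[[f]], function(v) {
      p[[f]] <- v; mews_at_hour(p)
    }, integer(1))
    expect_true(all(diff(scores) >= 0), info = paste("MEWS", f))
  }
  base_s <- list(pao2_fio2_ratio = 450, platelets = 250, bilirubin = 0.7,
                 mean_arterial_pressure = 85, vasopressor = 0, gcs = 15,
                 creatinine = 0.9)
  worsen_s <- list(pao2_fio2_ratio = seq(450, 40, by = -25),
                   platelets = seq(250, 5, by = -15),
                   bilirubin = seq(0.7, 30, by = 2),
                   mean_arterial_pressure = seq(85, 30, by = -5),
                   vasopressor = 0:1, gcs = 15:3,
                   creatinine = seq(0.9, 15, by = 1))
  for (f in names(worsen_s)) {
    p <- base_s
    scores <- vapply(worsen_s[[f]], function(v) {
      p[[f]] <- v; sofa_at_hour(p)
    }, integer(1))
    expect_true(all(diff(scores) >= 0), info = paste("SOFA", f))
  }
})

test_that("max_score_48h equals the max over hourly scores", {
  coh <- small_cohort()
  st <- small_stats()
  rec <- admission_record(coh, coh$admissions$id[5])
  for (w in c("mews", "sofa")) {
    r <- max_score_48h(rec, w, st, coh$catalogue)
    expect_length(r$hourly, 48)
    expect_equal(r$max48, max(r$hourly))
  }
  # a constant normal record scores 0 throughout
  normal_obs <- obs_df(
    c("systolic_bp", "heart_rate", "resp_rate", "temperature", "avpu"),
    rep(0.5, 5), c(120, 80, 14, 37, 0))
  # imputation stats from a normal-only cohort so imputed cells are benign
  rec0 <- toy_admission(normal_obs)
  st0 <- st
  st0$median_by_location[] <- NA
  st0$global_median[] <- NA
  st0$global_median[c("systolic_bp", "heart_rate", "resp_rate",
                      "temperature", "avpu")] <- c(120, 80, 14, 37, 0)
  r0 <- max_score_48h(rec0, "mews", st0, coh$catalogue)
  expect_equal(r0$max48, 0L)
  # a single tachycardic hour sets the maximum
  tach <- toy_admission(rbind(normal_obs,
                              obs_df(c("heart_rate", "heart_rate"),
                                     c(10.2, 11.1), c(135, 80))))
  r1 <- max_score_48h(tach, "mews", st0, coh$catalogue)
  expect_equal(r1$max48, 3L)
  expect_equal(r1$hourly[11], 3L)
})

test_that("batch scoring equals per-admission scoring", {
  coh <- small_cohort()
  st <- small_stats()
  ids <- coh$admissions$id[1:10]
  sc <- score_cohort(coh, ids, st)
  for (k in c(1, 5, 10)) {
    rec <- admission_record(coh, ids[k])
    expect_equal(sc$mews_max48[k], max_score_48h(rec, "mews", st,
                                                 coh$catalogue)$max48)
    expect_equal(sc$sofa_max48[k], max_score_48h(rec, "sofa", st,
                                                 coh$catalogue)$max48)
  }
})
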