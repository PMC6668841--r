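cat40 <- default_catalogue("demo")

test_that("hourly blocking follows the LOCF definition and tie rules", {
  adm <- toy_admission(obs_df(c("heart_rate", "heart_rate"),
                              c(0.5, 2.2), c(80, 120)))
  g <- block_hourly(adm$observations, cat40)
  hr <- g$values["heart_rate", ]
  expect_equal(hr[1:2], c(80, 80))
  expect_equal(hr[3:48], rep(120, 46))

  # two observations in the same hour: later timestamp wins
  g2 <- block_hourly(obs_df(c("lactate", "lactate"), c(3.1, 3.7), c(2, 5)),
                     cat40)
  expect_equal(unname(g2$values["lactate", 4]), 5)
  # identical timestamps: later input row wins
  g3 <- block_hourly(obs_df(c("lactate", "lactate"), c(3.5, 3.5), c(2, 5)),
                     cat40)
  expect_equal(unname(g3$values["lactate", 4]), 5)

  # a variable never observed stays entirely missing
  expect_true(all(is.na(g$values["bilirubin", ])))

  # observations at/after the window are dropped with a warning
  expect_warning(g4 <- block_hourly(obs_df("lactate", 48.5, 3), cat40),
                 "dropped")
  expect_equal(g4$n_dropped, 1L)
  expect_error(block_hourly(obs_df("lactate", -0.1, 3), cat40), "negative")
  expect_error(block_hourly(obs_df("not_a_var", 1, 3), cat40),
               "not in catalogue")
})

test_that("blocking + LOCF agrees with a scalar brute-force reference", {
  set.seed(501)
  for (rep in 1:1000) {
    k <- sample(0:6, 1)
    times <- round(runif(k, 0, 48), 3)
    vals <- round(runif(k, 1, 9), 2)
    g <- block_hourly(obs_df(rep("lactate", k), times, vals), cat40)
    expect_identical(unname(g$values["lactate", ]),
                     locf_reference(times, vals))
  }
})

test_that("imputation stats implement the stated fallback chain", {
  coh <- small_cohort()
  # hand-made cohort: lactate observed only at icu with values 1,2,3
  mini <- coh
  mini$admissions <- data.frame(
    id = c("x1", "x2", "x3"), age = 50, female = 0, race_black = 0,
    admission_location = c("icu", "icu", "ward"), outcome = "alive",
    los_days = 3, stringsAsFactors = FALSE)
  mini$observations <- obs_df(rep("lactate", 3), c(1, 2, 3), c(1, 2, 3))
  mini$observations$id <- c("x1", "x2", "x1")
  st <- fit_imputation_stats(mini)
  expect_equal(unname(st$median_by_location["lactate", "icu"]), 2)
  # global fallback for a location never observed
  fill_ward <- vistl:::imputation_fill_values(st, cat40, "ward")
  expect_equal(fill_ward[match("lactate", cat40$name)], 2)
  # plausible-range midpoint for a variable never observed anywhere
  expect_equal(fill_ward[match("bilirubin", cat40$name)],
               mean(c(0.1, 30)))
  # binary variables impute 0
  expect_equal(fill_ward[match("med_vasopressor", cat40$name)], 0)
  expect_error(fit_imputation_stats(list(admissions = data.frame())),
               "empty")
})

test_that("impute_missing fills only missing cells, LOCF applied first", {
  st <- small_stats()
  adm <- toy_admission(obs_df("heart_rate", 1.5, 95), location = "icu")
  g <- impute_missing(block_hourly(adm$observations, cat40,
                                   admission_location = "icu"), st)
  expect_false(anyNA(g$values))
  # hour 0 (before the first observation) = icu median; later hours carried
  icu_med <- st$median_by_location["heart_rate", "icu"]
  expect_equal(unname(g$values["heart_rate", 1]), unname(icu_med))
  expect_equal(unname(g$values["heart_rate", 2:48]), rep(95, 47))
  # fully observed grid passes through unchanged
  full <- block_hourly(obs_df("heart_rate", 0.1, 80), cat40)
  full$values[] <- 70
  expect_equal(impute_missing(full, st)$values, full$values)
})

test_that("normalizer bounds are training percentiles with range fallback", {
  set.seed(11)
  V <- nrow(cat40)
  # uniform training values on the plausible range -> bounds near endpoints
  n_img <- 60
  A <- array(NA_real_, c(V, 48, n_img))
  for (v in seq_len(V)) {
    lo <- cat40$low[v]; hi <- cat40$high[v]
    if (cat40$kind[v] == "binary") { lo <- 0; hi <- 1 }
    A[v, , ] <- runif(48 * n_img, lo, hi)
  }
  norm <- fit_normalizer(A, "min_max", cat40)
  cont <- cat40$kind == "continuous"
  span <- cat40$high[cont] - cat40$low[cont]
  expect_true(all(abs(norm$table$low[cont] -
                        (cat40$low[cont] + 0.01 * span)) < 0.05 * span))
  expect_true(all(abs(norm$table$high[cont] -
                        (cat40$high[cont] - 0.01 * span)) < 0.05 * span))
  # constant variable falls back to the plausible range with a warning
  B <- A
  B[1, , ] <- 5
  expect_warning(nc <- fit_normalizer(B, "min_max", cat40), "widened")
  expect_equal(nc$table$low[1], cat40$low[1])
  expect_equal(nc$table$high[1], cat40$high[1])
  # refit on identical data is identical
  expect_equal(fit_normalizer(A, "min_max", cat40),
               fit_normalizer(A, "min_max", cat40))
})

test_that("normalization formulas hit their stated endpoints", {
  tb <- data.frame(name = c("up", "down", "both", "bin"),
                   low = c(0, 0, 40, 0), high = c(10, 10, 120, 1),
                   mean = c(NA, NA, 70, NA),
                   direction = c("higher_abnormal", "lower_abnormal",
                                 "bidirectional", "none"),
                   binary = c(FALSE, FALSE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  for (scheme in c("min_max", "custom")) {
    nz <- structure(list(table = tb, scheme = scheme, fitted_on = "t"),
                    class = "vistl_normalizer")
    m <- matrix(c(0, 10,      # up: low, high
                  0, 10,      # down
                  70, 120,    # both: mean, high bound
                  0, 1), 4, 2, byrow = TRUE)
    img <- apply_normalizer(m, nz)
    if (scheme == "min_max") {
      expect_equal(img$pixels[1, ], c(0, 1))
      expect_equal(img$pixels[2, ], c(0, 1))
    } else {
      expect_equal(img$pixels[1, ], c(0, 1))
      expect_equal(img$pixels[2, ], c(1, 0))   # inverted: low value abnormal
      expect_equal(img$pixels[3, ], c(0, 1))   # at mean 0, at bound 1
    }
    expect_equal(img$pixels[4, ], c(0, 1))     # binary passthrough
  }
  # at the low bound a bidirectional row is also 1 under custom
  nz <- structure(list(table = tb, scheme = "custom", fitted_on = "t"),
                  class = "vistl_normalizer")
  m2 <- matrix(c(5, 5, 40, 0), 4, 1)
  expect_equal(apply_normalizer(m2, nz)$pixels[3, 1], 1)
})

test_that("orderings are permutations; clustering places duplicates together", {
  imgs <- array(runif(nrow(cat40) * 48 * 4), c(nrow(cat40), 48, 4))
  for (scheme in c("standard", "within_group", "across_group")) {
    o <- fit_ordering(imgs, scheme, cat40)
    expect_setequal(o$perm, seq_len(nrow(cat40)))
    if (scheme == "within_group") {
      # group blocks survive exactly
      expect_equal(cat40$group[o$perm], cat40$group)
    }
  }
  expect_equal(fit_ordering(imgs, "standard", cat40)$perm,
               seq_len(nrow(cat40)))
  expect_error(fit_ordering(imgs[, , 1, drop = FALSE], "within_group", cat40),
               "at least 2")

  # two perfectly correlated rows in one group end up adjacent
  set.seed(21)
  A <- array(runif(nrow(cat40) * 48 * 6), c(nrow(cat40), 48, 6))
  vit <- which(cat40$group == "vitals")
  A[vit[4], , ] <- A[vit[1], , ]          # duplicate within the block
  o <- fit_ordering(A, "within_group", cat40)
  pos <- match(c(vit[1], vit[4]), o$perm)
  expect_equal(abs(diff(pos)), 1L)
})

test_that("encode_admission composes the stages; full preset is 156 x 48", {
  coh <- small_cohort()
  st <- small_stats()
  nat <- encode_cohort(coh, small_split()$train_ids, st)
  norm <- fit_normalizer(nat$pixels, "min_max", cat40)
  rec <- admission_record(coh, small_split()$validation_ids[1])
  img <- encode_admission(rec, cat40, st, norm)
  expect_equal(dim(img$pixels), c(nrow(cat40), 48))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  # static rows are constant across all hours
  age_row <- img$pixels[match("age_years", img$row_labels), ]
  expect_equal(length(unique(age_row)), 1L)
  loc_row <- img$pixels[match(paste0("loc_", rec$admission_location),
                              img$row_labels), ]
  expect_equal(unname(loc_row), rep(1, 48))

  # permuting the observation rows leaves the image unchanged
  rec2 <- rec
  set.seed(3)
  rec2$observations <- rec2$observations[sample(nrow(rec2$observations)), ]
  expect_equal(encode_admission(rec2, cat40, st, norm)$pixels, img$pixels)

  # full preset yields the published matrix shape
  full <- default_catalogue("full")
  cfg_full <- cohort_config(n_admissions = 20, seed = 3, catalogue = full)
  coh_full <- generate_cohort(cfg_full)
  st_full <- fit_imputation_stats(coh_full)
  nat_full <- encode_cohort(coh_full, coh_full$admissions$id, st_full)
  norm_full <- fit_normalizer(nat_full$pixels, "min_max", full)
  img_full <- encode_admission(admission_record(coh_full, "a000001"),
                               full, st_full, norm_full)
  expect_equal(dim(img_full$pixels), c(156L, 48L))
})

test_that("batch encoding equals per-admission encoding", {
  coh <- small_cohort()
  st <- small_stats()
  ids <- small_split()$validation_ids[1:12]
  nat <- encode_cohort(coh, small_split()$train_ids, st)
  for (scheme in c("min_max", "custom")) {
    norm <- fit_normalizer(nat$pixels, scheme, cat40)
    stack <- encode_cohort(coh, ids, st, norm)
    for (k in c(1, 7, 12)) {
      img <- encode_admission(admission_record(coh, ids[k]), cat40, st, norm)
      expect_equal(stack$pixels[, , k], unname(img$pixels), tolerance = 1e-12)
    }
  }
})

test_that("PNG round trip: orientation, endpoints, quantization bound", {
  px <- matrix(runif(40 * 48), 40, 48)
  px[1, 1] <- 0; px[2, 1] <- 1
  path <- withr::local_tempfile(fileext = ".png")
  write_png(px, path)
  back <- read_png(path)
  expect_equal(dim(back$pixels), c(40, 48))       # V tall x 48 wide
  expect_equal(back$pixels[1, 1], 0)
  expect_equal(back$pixels[2, 1], 1)
  expect_lte(max(abs(back$pixels - px)), 1 / 510 + 1e-12)
  expect_error(write_png(px * 2, path), "\\[0,1\\]")
  expect_error(read_png(file.path(tempdir(), "absent.png")), "cannot read")
})
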