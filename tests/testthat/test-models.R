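test_that("split proportions, determinism, disjointness", {
  ids <- sprintf("p%03d", 1:100)
  sp <- make_split(ids, seed = 4)
  expect_length(sp$validation_ids, 30)
  expect_length(sp$derivation_ids, 70)
  expect_length(sp$tune_ids, 14)
  expect_length(sp$train_ids, 56)
  expect_identical(sp, make_split(ids, seed = 4))
  expect_false(identical(sp$validation_ids, make_split(ids, 5)$validation_ids))
  all4 <- c(sp$validation_ids, sp$train_ids, sp$tune_ids)
  expect_equal(anyDuplicated(all4), 0L)
  expect_setequal(all4, ids)
  expect_setequal(c(sp$train_ids, sp$tune_ids), sp$derivation_ids)
  expect_error(make_split(ids[1:5]), "at least 10")
})

test_that("build_model: seeded init, shape validation, prediction contract", {
  cfg <- model_config("cnn_rl", seed = 9)
  m1 <- build_model(cfg, c(40, 48))
  m2 <- build_model(cfg, c(40, 48))
  expect_identical(m1$params, m2$params)
  expect_error(build_model(cfg, c(42, 48)), "incompatible with pooling")
  expect_error(build_model(model_config("standard_cnn"), c(40, 50)),
               "incompatible with pooling")

  X <- array(runif(40 * 48 * 7), c(40, 48, 7))
  p <- predict_proba(m1, X)
  expect_length(p, 7)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_proba(m1, X))          # inference determinism
  # batch order: single-image predictions match their batch positions
  p_single <- vapply(1:7, function(i)
    predict_proba(m1, X[, , i, drop = FALSE]), numeric(1))
  expect_equal(p, p_single, tolerance = 1e-12)
  expect_error(predict_proba(m1, array(0, c(20, 48, 2))), "does not match")
})

test_that("cnn_rl hands exactly 48 time steps to the recurrent layer", {
  m <- build_model(model_config("cnn_rl", seed = 1), c(40, 48))
  X <- array(runif(40 * 48 * 2), c(40, 48, 2))
  r <- vistl:::.nn_run("cnn_rl", m$params, X, NULL, NULL, NULL, FALSE, TRUE)
  # the final conv feature maps preserve all 48 columns
  expect_equal(dim(r$A)[2], 48L)
  # and the GRU input width equals pooled-variables x filters
  expect_equal(ncol(m$params$Wz), (40 %/% 4) * m$config$filters[2])
})

make_planted_stack <- function(n = 300, seed = 1, reversed_signal = FALSE) {
  # one row equals the label (plus tiny noise): perfectly separable
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- array(runif(16 * 48 * n, 0, 0.2), c(16, 48, n))
  for (i in seq_len(n)) X[5, , i] <- y[i] * 0.9 + 0.05
  list(X = X, y = y)
}

test_that("training recovers a planted separable signal; shuffled labels do not", {
  d <- make_planted_stack(300)
  ids <- sprintf("s%03d", seq_len(300))
  sp <- make_split(ids, 1)
  for (arch in c("standard_cnn", "cnn_rl", "rnn")) {
    cfg <- model_config(arch, epochs = 20, patience = 20, augment_sd = 0,
                        dropout = 0, seed = 3)
    mod <- build_model(cfg, c(16, 48))
    stack <- structure(list(pixels = d$X, ids = ids,
                            outcome = ifelse(d$y == 1, "died", "alive"),
                            row_labels = NULL), class = "vistl_image_stack")
    mod <- train_model(mod, stack, split = sp)
    expect_lte(nrow(mod$history), cfg$epochs)
    expect_gte(max(mod$history$tune_auc), 0.99)
    vi <- match(sp$validation_ids, ids)
    expect_gte(roc_auc(d$y[vi], predict_proba(mod, d$X[, , vi])), 0.99)
  }
  # permuted labels: tune AUC stays near chance
  set.seed(8)
  y_perm <- sample(d$y)
  stack_perm <- structure(list(pixels = d$X, ids = ids,
                               outcome = ifelse(y_perm == 1, "died", "alive"),
                               row_labels = NULL), class = "vistl_image_stack")
  cfg <- model_config("standard_cnn", epochs = 6, patience = 6,
                      augment_sd = 0, seed = 3)
  mod <- train_model(build_model(cfg, c(16, 48)), stack_perm, split = sp)
  vi <- match(sp$validation_ids, ids)
  auc_null <- roc_auc(y_perm[vi], predict_proba(mod, d$X[, , vi]))
  expect_lt(abs(auc_null - 0.5), 0.12)
})

test_that("training rejects single-class labels and validation leakage", {
  d <- make_planted_stack(60)
  ids <- sprintf("s%03d", seq_len(60))
  sp <- make_split(ids, 1)
  stack <- structure(list(pixels = d$X, ids = ids,
                          outcome = rep("alive", 60), row_labels = NULL),
                     class = "vistl_image_stack")
  cfg <- model_config("standard_cnn", epochs = 1, seed = 1)
  expect_error(train_model(build_model(cfg, c(16, 48)), stack, split = sp),
               "single-class")
  # leakage assertion on stats provenance
  coh <- small_cohort()
  sp2 <- small_split()
  st_all <- fit_imputation_stats(coh, "everything")
  expect_error(assert_no_leakage(st_all, sp2$validation_ids), "leakage")
  st_ok <- small_stats()
  expect_true(assert_no_leakage(st_ok, sp2$validation_ids))
})

test_that("reversing the time axis changes CNN-RL predictions", {
  # time-ordered planted pattern: rising vs falling ramp decides the label
  set.seed(12)
  n <- 240
  y <- rep(c(0, 1), length.out = n)
  ramp <- seq(0.1, 0.9, length.out = 48)
  X <- array(runif(16 * 48 * n, 0, 0.15), c(16, 48, n))
  for (i in seq_len(n)) X[6, , i] <- if (y[i] == 1) ramp else rev(ramp)
  ids <- sprintf("r%03d", seq_len(n))
  sp <- make_split(ids, 2)
  stack <- structure(list(pixels = X, ids = ids,
                          outcome = ifelse(y == 1, "died", "alive"),
                          row_labels = NULL), class = "vistl_image_stack")
  cfg <- model_config("cnn_rl", epochs = 15, patience = 15, augment_sd = 0,
                      dropout = 0, seed = 5)
  mod <- train_model(build_model(cfg, c(16, 48)), stack, split = sp)
  vi <- match(sp$validation_ids, ids)
  p_fwd <- predict_proba(mod, X[, , vi])
  p_rev <- predict_proba(mod, X[, 48:1, vi])
  expect_gt(mean(abs(p_fwd - p_rev)), 0)
  # the planted pattern is ordering-only, so a good fit must flip with time
  expect_gt(roc_auc(y[vi], p_fwd), 0.9)
})
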