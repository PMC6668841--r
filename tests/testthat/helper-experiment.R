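# The default desk-scale experiment shared by the heavier acceptance checks:
# one synthetic cohort of 8,000 admissions per seed, 70/30 + 80/20 split,
# min-max normalization, standard ordering, CNN-RL and Standard-CNN trained
# with the package-default model configuration, MEWS/SOFA comparators.
# Memoised so several test blocks can reuse the same runs.
default_experiment_run <- function(seed) {
  memo(paste0("exp_", seed), {
    coh <- generate_cohort(cohort_config(n_admissions = 8000, seed = seed))
    split <- make_split(coh$admissions$id, seed)
    stats <- fit_imputation_stats(split_cohort(coh, split$train_ids), "train")
    nat <- encode_cohort(coh, split$train_ids, stats)
    norm <- fit_normalizer(nat$pixels, "min_max", coh$catalogue,
                           fitted_on = "train")
    allimg <- encode_cohort(coh, coh$admissions$id, stats, norm)
    ids <- coh$admissions$id
    y <- as.numeric(coh$admissions$outcome == "died")
    vi <- match(split$validation_ids, ids)
    sc <- score_cohort(coh, split$validation_ids, stats)
    val_stack <- structure(list(
      pixels = allimg$pixels[, , vi, drop = FALSE],
      ids = split$validation_ids,
      outcome = coh$admissions$outcome[vi],
      row_labels = allimg$row_labels,
      norm_scheme = "min_max", order_scheme = "standard"),
      class = "vistl_image_stack")
    aucs <- c(sofa = roc_auc(y[vi], sc$sofa_max48),
              mews = roc_auc(y[vi], sc$mews_max48))
    models <- list()
    for (arch in c("cnn_rl", "standard_cnn")) {
      mod <- build_model(model_config(arch, seed = seed),
                         dim(allimg$pixels)[1:2])
      mod <- train_model(mod, allimg, split = split)
      models[[arch]] <- mod
      aucs[arch] <- roc_auc(y[vi], predict_proba(mod, val_stack$pixels))
    }
    list(aucs = aucs, models = models, val_stack = val_stack,
         y_val = y[vi], signal_rows = signal_variables(coh$config),
         catalogue = coh$catalogue)
  })
}

# Localization cohorts for the Grad-CAM check: no demographic or location
# risk, equal severity baselines, and severity links kept on only a
# designated subset of channels, so the outcome signal is confined to known
# rows. Smaller than the discrimination experiment; only the CNN-RL is
# trained.
localization_cohort_config <- function(seed, n = 4000) {
  # dynamic channels only: the static demographic/location rows play no role
  # in this design (their outcome coefficients are zero) and would otherwise
  # sit as constant-bright rows in the image
  cat_dyn <- default_catalogue("demo")
  cat_dyn <- cat_dyn[!cat_dyn$group %in% c("clinical_characteristics",
                                           "location"), ]
  class(cat_dyn) <- c("vistl_catalogue", "data.frame")
  cfg <- cohort_config(n_admissions = n, seed = seed, catalogue = cat_dyn)
  cfg$severity$baseline[] <- 0.7
  cfg$severity$baseline_sd <- 0.45
  cfg$outcome$beta_age <- 0
  cfg$outcome$beta_female <- 0
  cfg$outcome$intercept <- -7
  # signal confined to the contiguous labs block; links strengthened so the
  # block is clearly informative relative to its sampling noise
  keep <- cfg$catalogue$name[cfg$catalogue$group == "labs"]
  em <- cfg$emission
  drop <- !em$variable %in% keep
  em$link[drop] <- 0
  em$bin_link[drop] <- 0
  em$rate_sev[drop] <- 0
  strong <- c(pao2_fio2_ratio = 100, platelets = 60, bilirubin = 1.5,
              creatinine = 0.8, lactate = 3, wbc = 6, hemoglobin = 2,
              sodium = 4, potassium = 0.8, bicarbonate = 6)
  em$link[match(names(strong), em$variable)] <- strong
  em$rate_per_hour[em$variable %in% keep] <- 1 / 3
  cfg$emission <- em
  cfg
}

localization_experiment_run <- function(seed) {
  memo(paste0("locexp_", seed), {
    cfg <- localization_cohort_config(seed)
    coh <- generate_cohort(cfg)
    split <- make_split(coh$admissions$id, seed)
    stats <- fit_imputation_stats(split_cohort(coh, split$train_ids), "train")
    nat <- encode_cohort(coh, split$train_ids, stats)
    norm <- suppressWarnings(fit_normalizer(nat$pixels, "custom",
                                            coh$catalogue,
                                            fitted_on = "train"))
    allimg <- encode_cohort(coh, coh$admissions$id, stats, norm)
    y <- as.numeric(coh$admissions$outcome == "died")
    vi <- match(split$validation_ids, coh$admissions$id)
    mod <- build_model(model_config("cnn_rl", seed = seed),
                       dim(allimg$pixels)[1:2])
    mod <- train_model(mod, allimg, split = split)
    val_stack <- structure(list(
      pixels = allimg$pixels[, , vi, drop = FALSE],
      ids = split$validation_ids,
      outcome = coh$admissions$outcome[vi],
      row_labels = allimg$row_labels,
      norm_scheme = "custom", order_scheme = "standard"),
      class = "vistl_image_stack")
    list(model = mod, val_stack = val_stack, y_val = y[vi],
         signal_rows = signal_variables(cfg), catalogue = coh$catalogue)
  })
}
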