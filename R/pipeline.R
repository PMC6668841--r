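#' Configuration of an end-to-end experiment
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort (or an
#'   already generated `vistl_cohort`).
#' @param schemes data.frame with columns `norm` (min_max/custom) and
#'   `order` (standard/within_group/across_group); one evaluation per row.
#' @param architectures model architectures to train.
#' @param model a [model_config()] used for every architecture (its
#'   `architecture` field is overridden per run).
#' @param split_seed admission-level split seed.
#' @param gradcam_n how many validation deaths/survivors to render in the
#'   Grad-CAM gallery.
#' @return list of class `vistl_experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              schemes = data.frame(norm = "min_max",
                                                   order = "standard"),
                              architectures = c("cnn_rl", "standard_cnn"),
                              model = model_config(),
                              split_seed = 1L,
                              gradcam_n = 3L) {
  stopifnot(nrow(schemes) >= 1,
            all(schemes$norm %in% c("min_max", "custom")),
            all(schemes$order %in% c("standard", "within_group", "across_group")),
            all(architectures %in% c("standard_cnn", "rnn", "cnn_rl")))
  structure(list(cohort = cohort, schemes = schemes,
                 architectures = architectures, model = model,
                 split_seed = as.integer(split_seed),
                 gradcam_n = as.integer(gradcam_n)),
            class = "vistl_experiment_config")
}

#' Run the full experiment: simulate, encode, score, train, evaluate, explain
#'
#' Reproduces the study protocol at desk scale: a 70/30 derivation /
#' validation split (80/20 train/tune inside derivation), imputation and
#' normalization statistics fitted on the training split only, one model per
#' (scheme, architecture) pair, MEWS / SOFA 48-hour-maximum comparators,
#' paired DeLong comparisons against the CNN-RL, admission-location
#' stratified AUCs, the cohort differential image, and a Grad-CAM gallery.
#' Every random step derives from seeds in the config, so a rerun produces
#' an identical report.
#'
#' @param config a [experiment_config()].
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `table2.csv`, `s3_grid.csv`, `s4_strata.csv` and `figures/`.
#' @return list of class `vistl_experiment_report`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cohort <- if (inherits(config$cohort, "vistl_cohort")) config$cohort else
    generate_cohort(config$cohort)
  split <- make_split(cohort$admissions$id, config$split_seed)
  train_cohort <- split_cohort(cohort, split$train_ids)
  stats <- fit_imputation_stats(train_cohort, fitted_on = "train")
  assert_no_leakage(stats, split$validation_ids)

  val_adm <- cohort$admissions[match(split$validation_ids,
                                     cohort$admissions$id), ]
  y_val <- as.numeric(val_adm$outcome == "died")

  sc <- score_cohort(cohort, split$validation_ids, stats)
  scores <- list(MEWS = sc$mews_max48, SOFA = sc$sofa_max48)

  native_train <- encode_cohort(cohort, split$train_ids, stats,
                                normalizer = NULL)
  grid <- config$schemes
  s3 <- NULL
  model_scores <- list()
  primary <- list()
  for (si in seq_len(nrow(grid))) {
    norm <- fit_normalizer(native_train$pixels, grid$norm[si],
                           cohort$catalogue, fitted_on = "train")
    train_img <- encode_cohort(cohort, split$train_ids, stats, norm)
    ord <- fit_ordering(train_img, grid$order[si], cohort$catalogue)
    for (arch in config$architectures) {
      mcfg <- config$model
      mcfg$architecture <- arch
      all_img <- encode_cohort(cohort,
                               c(split$derivation_ids, split$validation_ids),
                               stats, norm, ord)
      model <- build_model(mcfg, dim(all_img$pixels)[1:2])
      model <- train_model(model, all_img, split = split)
      val_idx <- match(split$validation_ids, all_img$ids)
      p <- predict_proba(model, all_img$pixels[, , val_idx, drop = FALSE])
      rep1 <- eval_report(y_val, p)
      s3 <- rbind(s3, data.frame(
        norm = grid$norm[si], order = grid$order[si], model = arch,
        auc = rep1$auc, auc_lo = rep1$auc_ci_95[1], auc_hi = rep1$auc_ci_95[2],
        aupr = rep1$aupr, stringsAsFactors = FALSE))
      if (si == 1L) {
        model_scores[[arch]] <- p
        if (arch == "cnn_rl") {
          primary <- list(model = model, images = all_img,
                          val_idx = val_idx, norm = norm, ord = ord)
        }
      }
    }
  }

  # Table-2-shaped comparison on the primary scheme, against CNN-RL
  ref_name <- if ("cnn_rl" %in% names(model_scores)) "cnn_rl" else
    names(model_scores)[1]
  ref <- model_scores[[ref_name]]
  rows <- c(scores, model_scores)
  table2 <- do.call(rbind, lapply(names(rows), function(nm) {
    r <- eval_report(y_val, rows[[nm]])
    p <- if (nm == ref_name) NA_real_ else
      compare_auc(y_val, ref, rows[[nm]])$p
    data.frame(model = nm, auc = r$auc, auc_lo = r$auc_ci_95[1],
               auc_hi = r$auc_ci_95[2], aupr = r$aupr,
               p_vs_ref = p, stringsAsFactors = FALSE)
  }))

  # location-stratified validation AUC of the reference model
  strata <- do.call(rbind, lapply(admission_locations(), function(l) {
    sel <- val_adm$admission_location == l
    if (sum(y_val[sel]) < 2 || sum(1 - y_val[sel]) < 2) return(NULL)
    data.frame(location = l, n = sum(sel),
               auc = roc_auc(y_val[sel], ref[sel]), stringsAsFactors = FALSE)
  }))

  report <- list(
    n_admissions = nrow(cohort$admissions),
    mortality = mean(cohort$admissions$outcome == "died"),
    split_seed = config$split_seed,
    s3_grid = s3, table2 = table2, strata = strata)

  if (length(primary)) {
    val_px <- primary$images$pixels[, , primary$val_idx, drop = FALSE]
    di <- differential_image(val_px, y_val)
    report$diff_image <- di$display
    pick <- c(utils::head(which(y_val == 1), config$gradcam_n),
              utils::head(which(y_val == 0), config$gradcam_n))
    if (length(pick)) {
      cams <- grad_cam(primary$model, val_px[, , pick, drop = FALSE])
      report$gradcam <- list(ids = split$validation_ids[pick],
                             attention = cams,
                             images = val_px[, , pick, drop = FALSE],
                             row_labels = primary$images$row_labels)
    }
  }
  class(report) <- "vistl_experiment_report"

  if (!is.null(out_dir)) write_experiment_report(report, out_dir)
  report
}

write_experiment_report <- function(report, out_dir) {
  dir.create(file.path(out_dir, "figures"), showWarnings = FALSE,
             recursive = TRUE)
  utils::write.csv(report$table2, file.path(out_dir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(report$s3_grid, file.path(out_dir, "s3_grid.csv"),
                   row.names = FALSE)
  strata <- report$strata %||% data.frame(location = character(),
                                          n = integer(), auc = numeric())
  utils::write.csv(strata, file.path(out_dir, "s4_strata.csv"),
                   row.names = FALSE)
  json <- report[c("n_admissions", "mortality", "split_seed")]
  json$s3_grid <- report$s3_grid
  json$table2 <- report$table2
  json$strata <- report$strata
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  if (!is.null(report$diff_image)) {
    write_png(report$diff_image, file.path(out_dir, "figures",
                                           "differential_image.png"))
  }
  if (!is.null(report$gradcam)) {
    g <- report$gradcam
    for (k in seq_along(g$ids)) {
      base <- g$images[, , k]
      att <- g$attention[, , k]
      write_png(base, file.path(out_dir, "figures",
                                paste0(g$ids[k], "_timeline.png")))
      png::writePNG(overlay_heatmap(base, att),
                    file.path(out_dir, "figures",
                              paste0(g$ids[k], "_gradcam.png")))
    }
    jsonlite::write_json(list(row_labels = g$row_labels),
                         file.path(out_dir, "figures", "row_labels.json"))
  }
  invisible(out_dir)
}

#' @export
print.vistl_experiment_report <- function(x, ...) {
  cat("<vistl_experiment_report> n=", x$n_admissions, ", mortality ",
      round(100 * x$mortality, 2), "%\n", sep = "")
  print(x$table2)
  invisible(x)
}
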