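#' Admission-level data split
#'
#' Random 70/30 split into derivation and independent validation, then
#' 80/20 inside derivation into training and tuning (hyperparameter /
#' early-stopping) sets, all at the admission level. The smaller set of
#' each split is rounded down.
#'
#' @param ids admission ids (>= 10).
#' @param seed split seed.
#' @return A `vistl_split`: list with `derivation_ids`, `validation_ids`,
#'   `train_ids`, `tune_ids`, `seed`.
#' @export
make_split <- function(ids, seed = 1L) {
  n <- length(ids)
  if (n < 10) stop("need at least 10 ids to split")
  with_seed(seed, {
    shuffled <- sample(ids)
    n_val <- floor(0.30 * n)
    validation <- shuffled[seq_len(n_val)]
    derivation <- shuffled[-seq_len(n_val)]
    n_tune <- floor(0.20 * length(derivation))
    tune <- derivation[seq_len(n_tune)]
    train <- derivation[-seq_len(n_tune)]
    structure(list(derivation_ids = derivation, validation_ids = validation,
                   train_ids = train, tune_ids = tune, seed = seed),
              class = "vistl_split")
  })
}

#' Restrict a cohort to a set of admissions
#' @param cohort a `vistl_cohort`.
#' @param ids admission ids to keep.
#' @return the restricted `vistl_cohort`.
#' @export
split_cohort <- function(cohort, ids) {
  keep <- cohort$admissions$id %in% ids
  structure(list(
    admissions = cohort$admissions[keep, , drop = FALSE],
    observations = cohort$observations[cohort$observations$id %in% ids, ,
                                       drop = FALSE],
    severity = if (!is.null(cohort$severity))
      cohort$severity[keep, , drop = FALSE] else NULL,
    catalogue = cohort$catalogue, config = cohort$config),
    class = "vistl_cohort")
}

# Fail loudly if stats fitted on admissions that overlap the validation set.
assert_no_leakage <- function(stats, validation_ids) {
  leak <- intersect(stats$fitted_ids %||% character(), validation_ids)
  if (length(leak)) {
    stop("leakage: ", length(leak),
         " validation admission(s) were used to fit training statistics")
  }
  invisible(TRUE)
}

#' Model configuration
#'
#' @param architecture `"standard_cnn"` (MNIST-style: two 3x3 conv blocks
#'   with 2x2 pooling, dense, sigmoid), `"rnn"` (GRU over the 48 hourly
#'   column vectors), or `"cnn_rl"` (two 3x3 conv blocks pooling only the
#'   variable axis so all 48 time steps survive, per-time-step feature
#'   vectors into a GRU, sigmoid).
#' @param filters conv filters per block.
#' @param recurrent_width GRU hidden width.
#' @param dense_width dense layer width (standard_cnn).
#' @param dropout dropout rate on the penultimate feature vector.
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled L2 weight decay per step.
#' @param augment_sd s.d. of Gaussian pixel noise added to training batches
#'   (augmentation against memorising the few positive admissions).
#' @param batch_size minibatch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience on tuning-split AUC.
#' @param class_weight inverse-prevalence class weights (the cohort is ~2.5%
#'   positive).
#' @param seed seed for initialization, shuffling and dropout.
#' @return list of class `vistl_model_config`.
#' @export
model_config <- function(architecture = c("cnn_rl", "standard_cnn", "rnn"),
                         filters = c(8L, 16L), recurrent_width = 32L,
                         dense_width = 32L, dropout = 0.3,
                         learning_rate = 1e-3, weight_decay = 1e-4,
                         augment_sd = 0.05, batch_size = 128L,
                         epochs = 16L, patience = 5L, class_weight = TRUE,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(all(filters >= 1), recurrent_width >= 1, dense_width >= 1,
            dropout >= 0, dropout < 1, learning_rate > 0, batch_size >= 1,
            epochs >= 1, patience >= 0, weight_decay >= 0, augment_sd >= 0)
  structure(list(architecture = architecture, filters = as.integer(filters),
                 recurrent_width = as.integer(recurrent_width),
                 dense_width = as.integer(dense_width), dropout = dropout,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 augment_sd = augment_sd,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 class_weight = isTRUE(class_weight), seed = as.integer(seed)),
            class = "vistl_model_config")
}

#' Build an untrained model for a given image shape
#'
#' Initializes all parameters (He-scaled for the conv and dense layers,
#' Glorot-scaled for the recurrent matrices) under the config seed, so two
#' builds with the same config are identical.
#'
#' @param config a [model_config()].
#' @param image_shape `c(V, H)` of the timeline images.
#' @return A `vistl_model` (untrained).
#' @export
build_model <- function(config, image_shape) {
  V <- as.integer(image_shape[1]); H <- as.integer(image_shape[2])
  arch <- config$architecture
  F1 <- config$filters[1]; F2 <- config$filters[2]
  if (arch != "rnn") {
    pw <- if (arch == "standard_cnn") c(4L, 4L) else c(4L, 1L)
    if (V %% pw[1] != 0 || H %% pw[2] != 0) {
      stop("image shape ", V, "x", H, " incompatible with pooling: after two ",
           if (arch == "standard_cnn") "2x2" else "2x1",
           " pools it would be ", V / pw[1], "x", H / pw[2],
           " (need V divisible by 4",
           if (arch == "standard_cnn") " and H divisible by 4", ")")
    }
  }
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  glorot <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
  params <- with_seed(config$seed, {
    p <- list()
    if (arch != "rnn") {
      p$W1 <- he(F1, 9); p$b1 <- numeric(F1)
      p$W2 <- he(F2, 9 * F1); p$b2 <- numeric(F2)
    }
    d <- switch(arch,
      standard_cnn = {
        flat <- (V %/% 4) * (H %/% 4) * F2
        p$Wd <- he(config$dense_width, flat); p$bd <- numeric(config$dense_width)
        config$dense_width
      },
      rnn = {
        Hd <- config$recurrent_width
        p$Wz <- glorot(Hd, V); p$Uz <- glorot(Hd, Hd); p$bz <- numeric(Hd)
        p$Wr <- glorot(Hd, V); p$Ur <- glorot(Hd, Hd); p$br <- numeric(Hd)
        p$Wh <- glorot(Hd, V); p$Uh <- glorot(Hd, Hd); p$bh <- numeric(Hd)
        Hd
      },
      cnn_rl = {
        D <- (V %/% 4) * F2
        Hd <- config$recurrent_width
        p$Wz <- glorot(Hd, D); p$Uz <- glorot(Hd, Hd); p$bz <- numeric(Hd)
        p$Wr <- glorot(Hd, D); p$Ur <- glorot(Hd, Hd); p$br <- numeric(Hd)
        p$Wh <- glorot(Hd, D); p$Uh <- glorot(Hd, Hd); p$bh <- numeric(Hd)
        Hd
      })
    p$Wo <- glorot(1, d); p$bo <- 0
    p
  })
  structure(list(architecture = arch, config = config, params = params,
                 image_shape = c(V, H), trained = FALSE, history = NULL),
            class = "vistl_model")
}

#' @export
print.vistl_model <- function(x, ...) {
  cat("<vistl_model> ", x$architecture, " on ", x$image_shape[1], "x",
      x$image_shape[2], if (x$trained) " (trained)" else " (untrained)",
      "\n", sep = "")
  invisible(x)
}

stack_pixels <- function(images) {
  if (inherits(images, "vistl_image_stack")) return(images$pixels)
  if (is.array(images) && length(dim(images)) == 3L) return(images)
  if (inherits(images, "vistl_timeline_image")) {
    return(array(images$pixels, c(dim(images$pixels), 1L)))
  }
  stop("images must be a vistl_image_stack, a V x H x N array, or a single image")
}

#' Train a model on timeline images
#'
#' Minimizes class-weighted binary cross-entropy with Adam, early-stopping
#' on tuning-split AUC, and returns the parameters of the best tuning
#' epoch. Validation admissions are never touched: the function asserts
#' that no validation id appears in any training or tuning batch.
#'
#' @param model a [build_model()] result.
#' @param images a `vistl_image_stack` covering at least the derivation ids.
#' @param labels numeric 0/1 per image (default: `outcome == "died"` from
#'   the stack).
#' @param split a [make_split()].
#' @return the trained `vistl_model` with a `history` data.frame
#'   (epoch, train_loss, tune_auc).
#' @export
train_model <- function(model, images, labels = NULL, split) {
  cfg <- model$config
  px <- stack_pixels(images)
  ids <- if (inherits(images, "vistl_image_stack")) images$ids else
    seq_len(dim(px)[3])
  if (is.null(labels)) {
    if (!inherits(images, "vistl_image_stack"))
      stop("labels required when images is a bare array")
    labels <- as.numeric(images$outcome == "died")
  }
  stopifnot(length(labels) == dim(px)[3], all(labels %in% c(0, 1)))
  if (!all(dim(px)[1:2] == model$image_shape))
    stop("image shape ", dim(px)[1], "x", dim(px)[2],
         " does not match model shape ",
         paste(model$image_shape, collapse = "x"))

  tr_idx <- match(split$train_ids, ids)
  tu_idx <- match(split$tune_ids, ids)
  if (anyNA(tr_idx) || anyNA(tu_idx))
    stop("images do not cover all derivation admissions")
  # data hygiene: no validation admission may enter a batch
  if (length(intersect(ids[c(tr_idx, tu_idx)], split$validation_ids)))
    stop("leakage: validation id present in training/tuning data")

  y_tr <- labels[tr_idx]
  if (length(unique(y_tr)) < 2L)
    stop("training labels are single-class; cannot fit")
  w_class <- if (cfg$class_weight) {
    n <- length(y_tr)
    c(n / (2 * sum(y_tr == 0)), n / (2 * sum(y_tr == 1)))
  } else c(1, 1)

  params <- model$params
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  d_feat <- if (cfg$architecture == "standard_cnn") cfg$dense_width else
    cfg$recurrent_width

  best <- list(auc = -Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        tune_auc = numeric())
  y_tu <- labels[tu_idx]

  with_seed(cfg$seed + 1L, {
    wait <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      losses <- c()
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
        yb <- labels[bi]
        wb <- w_class[yb + 1]
        mask <- NULL
        if (cfg$dropout > 0) {
          mask <- matrix((stats::runif(d_feat * length(bi)) >= cfg$dropout) /
                           (1 - cfg$dropout), d_feat, length(bi))
        }
        xb <- px[, , bi, drop = FALSE]
        if (cfg$augment_sd > 0) {
          xb <- xb + stats::rnorm(length(xb), 0, cfg$augment_sd)
        }
        res <- .nn_run(cfg$architecture, params, xb, yb, wb, mask,
                       want_grads = TRUE, want_gradcam = FALSE)
        losses <- c(losses, res$loss)
        step <- step + 1L
        g <- res$grads
        wd <- 1 - cfg$learning_rate * cfg$weight_decay
        for (nm in names(params)) {
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g[[nm]]
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - b1^step)
          vhat <- adam_v[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] * wd - cfg$learning_rate * mhat /
            (sqrt(vhat) + eps)
        }
      }
      p_tu <- predict_proba_params(cfg$architecture, params,
                                   px[, , tu_idx, drop = FALSE])
      auc_tu <- roc_auc(y_tu, p_tu)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = mean(losses),
                                  tune_auc = auc_tu))
      if (auc_tu > best$auc + 1e-6) {
        best <- list(auc = auc_tu, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  model$params <- best$params
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

predict_proba_params <- function(arch, params, px, chunk = 512L) {
  N <- dim(px)[3]
  out <- numeric(N)
  for (b0 in seq(1, N, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1, N)
    out[bi] <- .nn_run(arch, params, px[, , bi, drop = FALSE],
                       NULL, NULL, NULL, FALSE, FALSE)$probs
  }
  out
}

#' Predict per-admission death probability
#'
#' Deterministic at inference (no dropout); probabilities are returned in
#' input order.
#'
#' @param model a trained `vistl_model`.
#' @param images a `vistl_image_stack`, V x H x N array, or single image.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, images) {
  px <- stack_pixels(images)
  if (!all(dim(px)[1:2] == model$image_shape))
    stop("image shape ", dim(px)[1], "x", dim(px)[2],
         " does not match model shape ",
         paste(model$image_shape, collapse = "x"))
  predict_proba_params(model$architecture, model$params, px)
}
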