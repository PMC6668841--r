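#' Area under the ROC curve
#'
#' Mann-Whitney formulation via mid-ranks: ties between a positive and a
#' negative score count one half.
#'
#' @param labels 0/1 (or "died"/"alive") outcome per subject.
#' @param scores numeric risk scores, higher = more likely positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.numeric(as.character(labels) == "died")
  } else as.numeric(labels)
}

#' DeLong 95% confidence interval for an AUC
#'
#' Placement-value (DeLong) variance with a normal approximation, clipped
#' to `[0, 1]`.
#'
#' @inheritParams roc_auc
#' @return numeric `c(low, high)`.
#' @export
delong_ci <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (sum(y == 1) < 10 || sum(y == 0) < 10)
    stop("DeLong CI needs at least 10 subjects per class")
  r <- pROC::roc(y, scores, quiet = TRUE, direction = "<")
  ci <- tryCatch(suppressWarnings(pROC::ci.auc(r, method = "delong")),
                 error = function(e) NULL)
  if (is.null(ci) || anyNA(ci)) {
    warning("degenerate DeLong variance; returning the widest interval")
    return(c(0, 1))
  }
  c(max(0, ci[1]), min(1, ci[3]))
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both score vectors must be computed on the same subjects. Returns the
#' AUC difference (a minus b) and the two-sided p-value of the paired
#' DeLong test.
#'
#' @inheritParams roc_auc
#' @param scores_a,scores_b two risk scores on the same subjects.
#' @return list with `delta`, `p`, `auc_a`, `auc_b`.
#' @export
compare_auc <- function(labels, scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("labels, scores_a and scores_b must have equal length")
  y <- as_binary_labels(labels)
  auc_a <- roc_auc(y, scores_a)
  auc_b <- roc_auc(y, scores_b)
  delta <- auc_a - auc_b
  ra <- pROC::roc(y, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, scores_b, quiet = TRUE, direction = "<")
  p <- tryCatch(
    suppressWarnings(pROC::roc.test(ra, rb, method = "delong",
                                    paired = TRUE)$p.value),
    error = function(e) NA_real_)
  if (is.na(p)) {
    # identical or perfectly concordant scores: no evidence of a difference
    p <- if (abs(delta) < 1e-12) 1 else NA_real_
  }
  list(delta = delta, p = p, auc_a = auc_a, auc_b = auc_b)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum over distinct score thresholds of
#' the recall increment times the precision at that threshold. The no-skill
#' baseline equals the outcome prevalence.
#'
#' @inheritParams roc_auc
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(labels, scores) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores))
  P <- sum(y == 1)
  if (P == 0 || all(y == 1)) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE)   # threshold group boundaries
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Discrimination report for one model
#'
#' @inheritParams roc_auc
#' @param comparisons named list of competing score vectors on the same
#'   subjects; each is compared to `scores` with the paired DeLong test.
#' @return A `vistl_eval_report`: list with `auc`, `auc_ci_95`, `aupr`,
#'   `n`, and a `comparisons` data.frame (model, auc, delta_auc, p_value).
#' @export
eval_report <- function(labels, scores, comparisons = list()) {
  y <- as_binary_labels(labels)
  cmp <- NULL
  if (length(comparisons)) {
    cmp <- do.call(rbind, lapply(names(comparisons), function(nm) {
      cc <- compare_auc(y, scores, comparisons[[nm]])
      data.frame(model = nm, auc = cc$auc_b, delta_auc = cc$delta,
                 p_value = cc$p, stringsAsFactors = FALSE)
    }))
  }
  ci <- tryCatch(delong_ci(y, scores), error = function(e) c(NA_real_, NA_real_))
  structure(list(auc = roc_auc(y, scores), auc_ci_95 = ci,
                 aupr = average_precision(y, scores), n = length(y),
                 comparisons = cmp),
            class = "vistl_eval_report")
}

#' @export
print.vistl_eval_report <- function(x, ...) {
  cat(sprintf("<vistl_eval_report> n=%d AUC %.3f (%.3f-%.3f), AUPR %.3f\n",
              x$n, x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$aupr))
  if (!is.null(x$comparisons)) print(x$comparisons)
  invisible(x)
}

#' Single-pixel perturbation robustness check
#'
#' Zeroes one uniformly random pixel in every image, recomputes the AUC,
#' and returns both values. Replicates the robustness probe of the source
#' framework: a robust model's discrimination should be essentially
#' unchanged.
#'
#' @param model a trained `vistl_model`.
#' @param images a `vistl_image_stack` (validation set).
#' @param labels 0/1 outcome per image (default from the stack).
#' @param seed seed for the pixel choice.
#' @return list with `auc_before`, `auc_after`, `delta`.
#' @export
pixel_perturbation_test <- function(model, images, labels = NULL, seed = 1L) {
  px <- stack_pixels(images)
  if (is.null(labels)) labels <- as.numeric(images$outcome == "died")
  d <- dim(px)
  px2 <- px
  with_seed(seed, {
    rows <- sample.int(d[1], d[3], replace = TRUE)
    cols <- sample.int(d[2], d[3], replace = TRUE)
    px2[cbind(rows, cols, seq_len(d[3]))] <- 0
  })
  p_before <- predict_proba(model, px)
  p_after <- predict_proba(model, px2)
  list(auc_before = roc_auc(labels, p_before),
       auc_after = roc_auc(labels, p_after),
       delta = roc_auc(labels, p_after) - roc_auc(labels, p_before))
}
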