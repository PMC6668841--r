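#' Encode one admission into a visual timeline image
#'
#' Full composition: hourly blocking with carry-forward, location-median
#' imputation, rendering of static rows, normalization, and row reordering.
#' All fitted artifacts (imputation stats, normalizer, ordering) must come
#' from the training split; the image records their provenance.
#'
#' @param admission an admission record ([admission_record()]), i.e. a list
#'   with `observations`, `admission_location`, demographics and outcome.
#' @param catalogue the variable catalogue.
#' @param imputation_stats from [fit_imputation_stats()].
#' @param normalizer from [fit_normalizer()].
#' @param ordering from [fit_ordering()]; `NULL` keeps the standard order.
#' @param n_hours timeline width in hours.
#' @return A `vistl_timeline_image` with pixels in `[0, 1]`.
#' @export
encode_admission <- function(admission, catalogue, imputation_stats,
                             normalizer, ordering = NULL, n_hours = 48L) {
  grid <- native_grid(admission, catalogue, imputation_stats, n_hours)
  img <- apply_normalizer(grid, normalizer)
  img$id <- admission$id %||% NA_character_
  img$outcome <- admission$outcome %||% NA_character_
  attr(img, "stats_fitted_on") <- imputation_stats$fitted_on
  if (!is.null(ordering)) img <- apply_ordering(img, ordering)
  img
}

#' Encode many admissions into an image stack
#'
#' Vectorized batch version of [encode_admission()]: blocking, carry-forward
#' and imputation run on a V x hours x N array at once, which is what the
#' model-training pipeline uses. Single-admission and batch encodings agree
#' exactly.
#'
#' @param cohort a `vistl_cohort`.
#' @param ids admissions to encode (default all), in this order.
#' @param imputation_stats,normalizer,ordering fitted artifacts; `normalizer`
#'   `NULL` returns native units (used when fitting the normalizer itself,
#'   and by the clinical scorers).
#' @param n_hours timeline width.
#' @return A `vistl_image_stack`: list with `pixels` (V x n_hours x N array),
#'   `row_labels`, `ids`, `outcome`, `norm_scheme`, `order_scheme`.
#' @export
encode_cohort <- function(cohort, ids = cohort$admissions$id,
                          imputation_stats, normalizer = NULL,
                          ordering = NULL, n_hours = 48L) {
  cat <- cohort$catalogue
  V <- nrow(cat)
  adm <- cohort$admissions[match(ids, cohort$admissions$id), , drop = FALSE]
  if (anyNA(adm$id)) stop("unknown admission id(s) in `ids`")
  N <- length(ids)

  obs <- data.table::as.data.table(cohort$observations)
  obs <- obs[obs$id %in% ids & obs$time_h < n_hours]
  obs$vi <- catalogue_index(cat, obs$variable)
  obs$ni <- match(obs$id, ids)
  obs$hour <- as.integer(floor(obs$time_h))
  data.table::setorder(obs, ni, vi, hour, time_h)
  last <- !duplicated(obs[, c("ni", "vi", "hour")], fromLast = TRUE)

  A <- array(NA_real_, c(V, n_hours, N))
  A[cbind(obs$vi[last], obs$hour[last] + 1L, obs$ni[last])] <- obs$value[last]
  for (h in seq_len(n_hours)[-1]) {              # carry forward
    sl <- A[, h, , drop = FALSE]
    na <- is.na(sl)
    sl[na] <- A[, h - 1L, , drop = FALSE][na]
    A[, h, ] <- sl
  }
  # impute per admission location, then render static rows
  for (loc in unique(adm$admission_location)) {
    sel <- which(adm$admission_location == loc)
    fill <- imputation_fill_values(imputation_stats, cat, loc)
    sub <- A[, , sel, drop = FALSE]
    na <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(na)) {
      sub[na] <- fill[na[, 1L]]
      A[, , sel] <- sub
    }
  }
  static_vals <- vapply(seq_len(N), function(i)
    static_row_values(cat, as.list(adm[i, , drop = FALSE])), numeric(V))
  srows <- which(!is.na(static_vals[, 1L]))
  for (v in srows) A[v, , ] <- matrix(static_vals[v, ], n_hours, N, byrow = TRUE)

  norm_scheme <- "native"
  if (!is.null(normalizer)) {
    tb <- normalizer$table
    flat <- matrix(A, nrow = V)
    flat <- normalize_matrix(flat, tb, normalizer$scheme, tb$direction,
                             tb$binary)
    A <- array(flat, c(V, n_hours, N))
    norm_scheme <- normalizer$scheme
  }
  labels <- cat$name
  order_scheme <- "standard"
  if (!is.null(ordering)) {
    A <- A[ordering$perm, , , drop = FALSE]
    labels <- labels[ordering$perm]
    order_scheme <- ordering$scheme
  }
  structure(list(pixels = A, row_labels = labels, ids = ids,
                 outcome = adm$outcome, norm_scheme = norm_scheme,
                 order_scheme = order_scheme,
                 stats_fitted_on = imputation_stats$fitted_on),
            class = "vistl_image_stack")
}

#' @export
print.vistl_image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<vistl_image_stack> ", d[3], " images of ", d[1], " x ", d[2],
      " (", x$norm_scheme, " / ", x$order_scheme, ")\n", sep = "")
  invisible(x)
}

#' Write / read a timeline image as an 8-bit grayscale PNG
#'
#' Pixel byte = `round(255 * value)`: value 0 is black, value 1 white. Row 1
#' of the matrix is the top row of the PNG and column 1 is hour 0 at the
#' left, so a V-variable timeline becomes a PNG 48 px wide and V px tall.
#' The round trip is exact to within 1/510 (8-bit quantization).
#'
#' @param image a `vistl_timeline_image` (or plain matrix in `[0,1]`).
#' @param path file path.
#' @param row_labels optional labels reattached on read.
#' @return `read_png` returns a `vistl_timeline_image`.
#' @export
write_png <- function(image, path) {
  px <- if (inherits(image, "vistl_timeline_image")) image$pixels else image
  if (anyNA(px) || min(px) < 0 || max(px) > 1) {
    stop("image pixels must be in [0,1]")
  }
  png::writePNG(px, path)
  invisible(path)
}

#' @rdname write_png
#' @export
read_png <- function(path, row_labels = NULL) {
  if (!file.exists(path)) stop("cannot read PNG: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  structure(list(pixels = px,
                 row_labels = row_labels %||% rownames(px),
                 norm_scheme = NA_character_, order_scheme = NA_character_,
                 id = NA_character_, outcome = NA_character_),
            class = "vistl_timeline_image")
}
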