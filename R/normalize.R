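#' Fit normalization statistics on training grids
#'
#' Per-variable value bounds are the 1st/99th percentiles of all training
#' cells (pooled over admissions and hours), clipped to the plausible range;
#' `raw_minmax = TRUE` uses the raw training min/max instead, at the price of
#' making the grayscale hostage to single outliers. Bidirectional variables
#' additionally get their training mean, the reference point of the custom
#' scheme. A variable constant in training (low = high) falls back to its
#' plausible range with a warning.
#'
#' @param grids training data: a list of complete `vistl_hourly_grid`s, a
#'   list of native-unit matrices, or a V x H x N array.
#' @param scheme `"min_max"` (black = low, white = high) or `"custom"`
#'   (black = clinically normal, white = abnormal, direction-aware).
#' @param catalogue the variable catalogue.
#' @param probs percentile bounds (default 1st/99th).
#' @param raw_minmax use raw extremes instead of percentiles.
#' @param fitted_on split id recorded for leakage auditing.
#' @return A `vistl_normalizer`: data.frame of per-variable `low`, `high`,
#'   `mean` plus scheme metadata.
#' @export
fit_normalizer <- function(grids, scheme = c("min_max", "custom"), catalogue,
                           probs = c(0.01, 0.99), raw_minmax = FALSE,
                           fitted_on = "training") {
  scheme <- match.arg(scheme)
  X <- grids_to_array(grids, catalogue)     # V x (H*N)
  V <- nrow(catalogue)
  if (raw_minmax) {
    lo <- apply(X, 1, min); hi <- apply(X, 1, max)
  } else {
    qs <- apply(X, 1, stats::quantile, probs = probs, names = FALSE)
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  lo <- pmax(lo, ifelse(is.na(catalogue$low), -Inf, catalogue$low))
  hi <- pmin(hi, ifelse(is.na(catalogue$high), Inf, catalogue$high))
  binary <- catalogue$kind == "binary"
  lo[binary] <- 0; hi[binary] <- 1
  flat <- which(!binary & lo >= hi)
  if (length(flat)) {
    warning("constant training values for ",
            paste(catalogue$name[flat], collapse = ", "),
            "; bounds widened to the plausible range")
    lo[flat] <- catalogue$low[flat]
    hi[flat] <- catalogue$high[flat]
  }
  mu <- rowMeans(X)
  mu[catalogue$direction != "bidirectional"] <- NA_real_
  structure(list(table = data.frame(name = catalogue$name, low = lo,
                                    high = hi, mean = mu,
                                    direction = catalogue$direction,
                                    binary = binary,
                                    stringsAsFactors = FALSE),
                 scheme = scheme, fitted_on = fitted_on),
            class = "vistl_normalizer")
}

# Accept a list of grids/matrices or a 3D array; return V x (cells) matrix
grids_to_array <- function(grids, catalogue) {
  V <- nrow(catalogue)
  if (is.array(grids) && length(dim(grids)) == 3L) {
    stopifnot(dim(grids)[1] == V)
    return(matrix(grids, nrow = V))
  }
  if (inherits(grids, "vistl_hourly_grid")) grids <- list(grids)
  mats <- lapply(grids, function(g) {
    m <- if (inherits(g, "vistl_hourly_grid")) g$values else g
    if (anyNA(m)) stop("normalizer must be fitted on complete (imputed) grids")
    stopifnot(nrow(m) == V)
    m
  })
  do.call(cbind, mats)
}

#' Normalize a complete grid into a timeline image
#'
#' Min-max: `clip((x - low) / (high - low), 0, 1)`; binary rows pass through
#' (0 absence, 1 presence). Custom: higher-abnormal rows as min-max;
#' lower-abnormal rows inverted, `clip((high - x) / (high - low), 0, 1)`, so
#' that e.g. a low urine output maps towards one; bidirectional rows map the
#' magnitude of the departure from the training mean, scaled per side
#' (`(x - mean)/(high - mean)` above, `(mean - x)/(mean - low)` below), so
#' either bound maps to one.
#'
#' @param grid a complete `vistl_hourly_grid` (or native V x H matrix).
#' @param normalizer a `vistl_normalizer`.
#' @return A `vistl_timeline_image`: list with `pixels` (V x H in `[0,1]`),
#'   `row_labels`, `norm_scheme`, `order_scheme` (`"standard"` until
#'   reordered), `id`, `outcome`.
#' @export
apply_normalizer <- function(grid, normalizer) {
  if (!inherits(normalizer, "vistl_normalizer") || is.null(normalizer$scheme)) {
    stop("normalizer scheme not set; fit with fit_normalizer()")
  }
  m <- if (inherits(grid, "vistl_hourly_grid")) grid$values else grid
  if (anyNA(m)) stop("grid has missing cells; impute before normalizing")
  tb <- normalizer$table
  stopifnot(nrow(m) == nrow(tb))
  px <- normalize_matrix(m, tb, normalizer$scheme,
                         direction = tb$direction, binary = tb$binary)
  structure(list(pixels = px, row_labels = tb$name,
                 norm_scheme = normalizer$scheme, order_scheme = "standard",
                 id = NA_character_, outcome = NA_character_),
            class = "vistl_timeline_image")
}

normalize_matrix <- function(m, tb, scheme, direction, binary) {
  span <- tb$high - tb$low
  px <- (m - tb$low) / span
  if (scheme == "custom") {
    lower <- which(direction == "lower_abnormal" & !binary)
    if (length(lower)) px[lower, ] <- (tb$high[lower] - m[lower, , drop = FALSE]) /
        span[lower]
    bidir <- which(direction == "bidirectional" & !binary)
    if (length(bidir)) {
      dev <- m[bidir, , drop = FALSE] - tb$mean[bidir]
      up <- pmax(tb$high[bidir] - tb$mean[bidir], 1e-12)
      dn <- pmax(tb$mean[bidir] - tb$low[bidir], 1e-12)
      # departure from the mean, scaled per side so either bound maps to 1
      px[bidir, ] <- ifelse(dev >= 0, dev / up, -dev / dn)
    }
  }
  if (any(binary)) px[binary, ] <- m[binary, , drop = FALSE]
  pmin(pmax(px, 0), 1)
}

#' @export
print.vistl_timeline_image <- function(x, ...) {
  cat("<vistl_timeline_image> ", nrow(x$pixels), " x ", ncol(x$pixels),
      " (", x$norm_scheme, " / ", x$order_scheme, ")",
      if (!is.na(x$id)) paste0(" id=", x$id), "\n", sep = "")
  invisible(x)
}
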