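#' Grad-CAM attention heatmap
#'
#' Gradient-weighted class-activation mapping on the final convolutional
#' layer: channel weights are the spatial means of the death-logit gradient
#' with respect to each feature map, the map is the ReLU of the weighted sum
#' of feature maps, bilinearly upsampled to the image size and divided by
#' its maximum (an all-zero map stays zero). For the CNN-RL the final conv
#' layer sits before the recurrent layer and the gradients flow back
#' through it.
#'
#' @param model a trained `vistl_model` (`standard_cnn` or `cnn_rl`; the
#'   `rnn` has no convolutional layer and is rejected).
#' @param images a `vistl_image_stack`, V x H x N array, or single image.
#' @return For a single image a `vistl_heatmap` (list with `attention`
#'   V x H in `[0,1]`, `id`, `model`); for a batch, a V x H x N array of
#'   attention maps.
#' @export
grad_cam <- function(model, images) {
  if (model$architecture == "rnn") {
    stop("Grad-CAM needs a convolutional layer; the rnn architecture has none")
  }
  px <- stack_pixels(images)
  d <- dim(px)
  maps <- array(0, d)
  chunk <- 256L
  for (b0 in seq(1, d[3], by = chunk)) {
    bi <- b0:min(b0 + chunk - 1, d[3])
    res <- .nn_run(model$architecture, model$params,
                   px[, , bi, drop = FALSE], NULL, NULL, NULL,
                   FALSE, TRUE)
    cam <- res$cam                      # coarse maps, Vc x Hc x n
    for (k in seq_along(bi)) {
      up <- bilinear_upsample(cam[, , k], d[1], d[2])
      m <- max(up)
      maps[, , bi[k]] <- if (m > 0) up / m else up
    }
  }
  if (inherits(images, "vistl_timeline_image") ||
      (length(d) == 3L && d[3] == 1L && !inherits(images, "vistl_image_stack"))) {
    return(structure(list(attention = maps[, , 1],
                          id = if (inherits(images, "vistl_timeline_image"))
                            images$id else NA_character_,
                          model = model$architecture),
                     class = "vistl_heatmap"))
  }
  maps
}

# Bilinear upsampling of a matrix to (V, H), pixel-center aligned
bilinear_upsample <- function(m, V, H) {
  interp_weights <- function(n_out, n_in) {
    if (n_in == 1L) return(matrix(1, n_out, 1))
    pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
    pos <- pmin(pmax(pos, 0), n_in - 1)
    lo <- floor(pos)
    frac <- pos - lo
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
    hi <- pmin(lo + 2, n_in)
    W[cbind(seq_len(n_out), hi)] <- W[cbind(seq_len(n_out), hi)] + frac
    W
  }
  Wr <- interp_weights(V, nrow(m))
  Wc <- interp_weights(H, ncol(m))
  Wr %*% m %*% t(Wc)
}

#' Blend a timeline image with its attention heatmap
#'
#' The grayscale base is blended towards a blue-to-red attention palette:
#' attention 0 leaves the pixel untouched, attention 1 renders it pure red.
#' Output bytes are a deterministic function of the inputs. Row labels are
#' not rasterised into the pixels; write them from `image$row_labels`
#' (e.g. as a JSON sidecar) when exporting galleries.
#'
#' @param image a `vistl_timeline_image` (or matrix in `[0,1]`).
#' @param heatmap a `vistl_heatmap` (or matrix in `[0,1]`).
#' @return V x H x 3 RGB array in `[0,1]`.
#' @export
overlay_heatmap <- function(image, heatmap) {
  base <- if (inherits(image, "vistl_timeline_image")) image$pixels else image
  att <- if (inherits(heatmap, "vistl_heatmap")) heatmap$attention else heatmap
  if (!all(dim(base) == dim(att))) {
    stop("image and heatmap shapes differ: ",
         paste(dim(base), collapse = "x"), " vs ",
         paste(dim(att), collapse = "x"))
  }
  rgb <- array(0, c(dim(base), 3L))
  rgb[, , 1] <- (1 - att) * base + att * att          # red channel
  rgb[, , 2] <- (1 - att) * base
  rgb[, , 3] <- (1 - att) * base + att * (1 - att)    # blue fades out
  rgb
}

#' Cohort differential image
#'
#' Subtracts the mean timeline of admissions that died from the mean
#' timeline of admissions discharged alive. The display image is the
#' absolute difference scaled by its maximum: white marks the variables and
#' hours of maximum difference between the classes, black marks similarity.
#'
#' @param images a `vistl_image_stack` or list of `vistl_timeline_image`s
#'   sharing one normalization/ordering scheme.
#' @param labels outcome per image (default from the stack).
#' @return list with `signed` (mean alive minus mean died, V x H) and
#'   `display` (abs-normalized V x H in `[0,1]`).
#' @export
differential_image <- function(images, labels = NULL) {
  if (is.list(images) && !inherits(images, "vistl_image_stack") &&
      all(vapply(images, inherits, logical(1), "vistl_timeline_image"))) {
    schemes <- unique(vapply(images, function(i)
      paste(i$norm_scheme, i$order_scheme), character(1)))
    if (length(schemes) > 1) stop("images mix schemes: ",
                                  paste(schemes, collapse = " | "))
    if (is.null(labels)) labels <- vapply(images, `[[`, character(1), "outcome")
    px <- array(unlist(lapply(images, `[[`, "pixels")),
                c(dim(images[[1]]$pixels), length(images)))
  } else {
    px <- stack_pixels(images)
    if (is.null(labels)) labels <- images$outcome
  }
  y <- as_binary_labels(labels)
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  mean_alive <- apply(px[, , y == 0, drop = FALSE], c(1, 2), mean)
  mean_died <- apply(px[, , y == 1, drop = FALSE], c(1, 2), mean)
  signed <- mean_alive - mean_died
  m <- max(abs(signed))
  list(signed = signed,
       display = if (m > 0) abs(signed) / m else abs(signed))
}
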