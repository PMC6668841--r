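#' Fit a variable ordering for timeline display
#'
#' `standard` keeps the catalogue order (variables grouped by type).
#' The cluster schemes compute Pearson correlations between variable rows,
#' pooling cells over training admissions and hours, take distance `1 - r`,
#' run agglomerative clustering with complete linkage, and use the
#' dendrogram leaf order as the display order — inside each group block for
#' `within_group`, globally for `across_group`. Zero-variance rows are
#' assigned correlation 0 to every other row.
#'
#' @param images training images: list of `vistl_timeline_image`s, a
#'   V x H x N array, or a `vistl_image_stack`.
#' @param scheme `"standard"`, `"within_group"`, or `"across_group"`.
#' @param catalogue the variable catalogue.
#' @return A `vistl_ordering`: list with `perm` (display order as catalogue
#'   row indices) and `scheme`.
#' @export
fit_ordering <- function(images, scheme = c("standard", "within_group",
                                            "across_group"), catalogue) {
  scheme <- match.arg(scheme)
  V <- nrow(catalogue)
  if (scheme == "standard") {
    return(structure(list(perm = seq_len(V), scheme = scheme),
                     class = "vistl_ordering"))
  }
  X <- images_to_matrix(images, V)          # V x pooled cells
  if (ncol(X) < 2 * 48 || n_images(images) < 2) {
    stop("cluster orderings need at least 2 training images")
  }
  R <- suppressWarnings(stats::cor(t(X)))
  R[!is.finite(R)] <- 0                      # zero-variance rows
  diag(R) <- 1
  leaf_order <- function(idx) {
    if (length(idx) <= 2L) return(idx)
    d <- stats::as.dist(1 - R[idx, idx])
    idx[stats::hclust(d, method = "complete")$order]
  }
  perm <- if (scheme == "across_group") {
    leaf_order(seq_len(V))
  } else {
    unlist(lapply(unique(catalogue$group), function(g) {
      leaf_order(which(catalogue$group == g))
    }), use.names = FALSE)
  }
  structure(list(perm = perm, scheme = scheme), class = "vistl_ordering")
}

images_to_matrix <- function(images, V) {
  if (inherits(images, "vistl_image_stack")) images <- images$pixels
  if (is.array(images) && length(dim(images)) == 3L) {
    stopifnot(dim(images)[1] == V)
    return(matrix(images, nrow = V))
  }
  do.call(cbind, lapply(images, function(im) {
    if (inherits(im, "vistl_timeline_image")) im$pixels else im
  }))
}

n_images <- function(images) {
  if (inherits(images, "vistl_image_stack")) return(dim(images$pixels)[3])
  if (is.array(images) && length(dim(images)) == 3L) return(dim(images)[3])
  length(images)
}

#' Apply a fitted ordering to a timeline image
#' @param image a `vistl_timeline_image`.
#' @param ordering a `vistl_ordering`.
#' @return The image with rows permuted into display order.
#' @export
apply_ordering <- function(image, ordering) {
  stopifnot(inherits(ordering, "vistl_ordering"))
  image$pixels <- image$pixels[ordering$perm, , drop = FALSE]
  image$row_labels <- image$row_labels[ordering$perm]
  image$order_scheme <- ordering$scheme
  image
}
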