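#' Segmentation configuration
#'
#' Parameters of the reproducible cell detector: Gaussian smoothing, Otsu (or
#' fixed) thresholding, hole filling, connected-component labelling, then
#' area and circularity filters. Circularity is measured as the ratio of the
#' component's area to the area of the circumscribed circle around its
#' centroid (1 for a disk, small for elongated or ragged shapes).
#'
#' @param smoothing_sigma Gaussian smoothing sd in pixels before thresholding.
#' @param threshold `"otsu"` (computed on the min-max normalized image, hence
#'   invariant to positive affine intensity transforms) or `"fixed"`.
#' @param fixed_threshold Intensity threshold when `threshold = "fixed"`.
#' @param min_area,max_area Component area bounds in pixels.
#' @param min_circularity Minimum circularity in `[0, 1]`.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(smoothing_sigma = 2,
                                threshold = c("otsu", "fixed"),
                                fixed_threshold = NA_real_,
                                min_area = 50,
                                max_area = 5000,
                                min_circularity = 0.6) {
  threshold <- match.arg(threshold)
  stopifnot(smoothing_sigma >= 0, min_area < max_area,
            min_circularity >= 0, min_circularity <= 1)
  if (threshold == "fixed" && !is.finite(fixed_threshold)) {
    stop("`fixed_threshold` must be set when threshold = 'fixed'",
         call. = FALSE)
  }
  structure(list(smoothing_sigma = smoothing_sigma, threshold = threshold,
                 fixed_threshold = fixed_threshold, min_area = min_area,
                 max_area = max_area, min_circularity = min_circularity),
            class = "segmentation_config")
}

new_cell_roi <- function(cell_id, pixels, source_channel) {
  centroid <- colMeans(pixels)
  structure(list(cell_id = cell_id,
                 pixels = pixels,
                 centroid = unname(centroid),
                 area = nrow(pixels),
                 source_channel = source_channel),
            class = "cell_roi")
}

#' @export
print.cell_roi <- function(x, ...) {
  cat(sprintf("<cell_roi> id %d, area %d px, centroid (%.1f, %.1f)\n",
              x$cell_id, x$area, x$centroid[1L], x$centroid[2L]))
  invisible(x)
}

roi_circularity <- function(pixels, centroid) {
  r2 <- (pixels[, 1L] - centroid[1L])^2 + (pixels[, 2L] - centroid[2L])^2
  # +0.5 px accounts for the half-pixel extent of boundary pixel centers
  rmax <- sqrt(max(r2)) + 0.5
  min(nrow(pixels) / (pi * rmax^2), 1)
}

#' Detect cells in a field image
#'
#' One ROI per detected cell on the chosen channel. Components are filtered
#' by area and circularity and ordered deterministically by centroid (row,
#' then column). A uniform (blank or everywhere-saturated) channel yields
#' zero ROIs with a warning, not an error.
#'
#' @param image A [field_image()].
#' @param channel_name Channel to segment (membrane/lineage by default in
#'   this package's simulations; Bodipy also works for aggregate-rich cells).
#' @param config A [segmentation_config()].
#' @return List of `cell_roi` objects (possibly empty), ids `1..n`.
#' @export
detect_cells <- function(image, channel_name = "membrane",
                         config = segmentation_config()) {
  stopifnot(inherits(image, "field_image"),
            inherits(config, "segmentation_config"))
  x <- channel(image, channel_name)
  xs <- if (config$smoothing_sigma > 0) {
    gaussian_blur(x, config$smoothing_sigma)
  } else {
    x
  }
  rng <- range(xs)
  if (rng[2L] - rng[1L] < .Machine$double.eps * max(1, abs(rng[2L]))) {
    warning("channel has no contrast; returning zero ROIs")
    return(list())
  }
  mask <- if (config$threshold == "otsu") {
    xn <- (xs - rng[1L]) / (rng[2L] - rng[1L])
    thr <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
    xn > thr
  } else {
    xs > config$fixed_threshold
  }
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::imageData(EBImage::bwlabel(mask))
  n_comp <- max(labels)
  if (n_comp == 0L) {
    return(list())
  }
  rois <- list()
  for (i in seq_len(n_comp)) {
    px <- which(labels == i, arr.ind = TRUE)
    dimnames(px) <- NULL
    area <- nrow(px)
    if (area < config$min_area || area > config$max_area) next
    centroid <- colMeans(px)
    if (roi_circularity(px, centroid) < config$min_circularity) next
    rois[[length(rois) + 1L]] <- new_cell_roi(0L, px, channel_name)
  }
  order_rois(rois)
}

order_rois <- function(rois) {
  if (length(rois) == 0L) {
    return(list())
  }
  cen <- t(vapply(rois, function(r) r$centroid, numeric(2)))
  ord <- order(cen[, 1L], cen[, 2L])
  rois <- rois[ord]
  for (i in seq_along(rois)) rois[[i]]$cell_id <- i
  rois
}

#' Build ROIs from an external label mask
#'
#' Supports manually drawn ROIs (label-mask image, one positive integer per
#' cell) or a simulator's ground-truth mask, bypassing [detect_cells()].
#'
#' @param label_mask Integer matrix; 0 = background, k > 0 = cell k.
#' @param source_channel Channel name recorded on the ROIs.
#' @return List of `cell_roi` objects ordered by centroid.
#' @export
rois_from_mask <- function(label_mask, source_channel = "manual") {
  stopifnot(is.matrix(label_mask))
  ids <- sort(unique(label_mask[label_mask > 0]))
  rois <- lapply(ids, function(i) {
    px <- which(label_mask == i, arr.ind = TRUE)
    dimnames(px) <- NULL
    new_cell_roi(0L, px, source_channel)
  })
  order_rois(rois)
}

#' Paired pixel coordinates and intensities of an ROI
#'
#' @param roi A `cell_roi`.
#' @param image A [field_image()].
#' @param channel_name Channel to sample.
#' @return List with `coords` (`(row, col)` matrix, the ROI's pixel order)
#'   and `intensities` (numeric vector in matching order, length = area).
#' @export
roi_pixels <- function(roi, image, channel_name) {
  stopifnot(inherits(roi, "cell_roi"), inherits(image, "field_image"))
  m <- channel(image, channel_name)
  px <- roi$pixels
  if (any(px < 1L) || any(px[, 1L] > nrow(m)) || any(px[, 2L] > ncol(m))) {
    stop("ROI pixels fall outside the image bounds", call. = FALSE)
  }
  list(coords = px, intensities = m[px])
}

#' ROI summary table
#'
#' @param rois List of `cell_roi` objects.
#' @return Data frame with `cell_id`, `centroid_row`, `centroid_col`, `area`,
#'   `source_channel`, suitable for CSV export.
#' @export
roi_table <- function(rois) {
  data.frame(cell_id = vapply(rois, `[[`, integer(1), "cell_id"),
             centroid_row = vapply(rois, function(r) r$centroid[1L],
                                   numeric(1)),
             centroid_col = vapply(rois, function(r) r$centroid[2L],
                                   numeric(1)),
             area = vapply(rois, `[[`, integer(1), "area"),
             source_channel = vapply(rois, `[[`, character(1),
                                     "source_channel"))
}
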