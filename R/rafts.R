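#' Per-cell CT-B raft metrics
#'
#' Mean and maximal cholera-toxin-B fluorescence over the whole-cell ROI:
#' the mean reflects total raft abundance, the maximum reflects raft
#' clustering. `"max"` (default) is the single brightest pixel; the
#' `"top_percent"` alternative averages the brightest `top_fraction` of
#' pixels and is robust to hot pixels.
#'
#' @param roi A `cell_roi`.
#' @param image A [field_image()].
#' @param ctb_channel CT-B channel name.
#' @param max_method `"max"` or `"top_percent"`.
#' @param top_fraction Fraction of brightest pixels averaged when
#'   `max_method = "top_percent"`.
#' @return One-row data frame: `cell_id`, `mean_ctb`, `max_ctb`
#'   (`max_ctb >= mean_ctb` always holds).
#' @export
cell_ctb_metrics <- function(roi, image, ctb_channel = "ctb",
                             max_method = c("max", "top_percent"),
                             top_fraction = 0.01) {
  max_method <- match.arg(max_method)
  px <- roi_pixels(roi, image, ctb_channel)
  v <- px$intensities
  if (length(v) == 0L) {
    stop("empty ROI", call. = FALSE)
  }
  mx <- if (max_method == "max") {
    max(v)
  } else {
    k <- max(1L, ceiling(top_fraction * length(v)))
    mean(sort(v, decreasing = TRUE)[seq_len(k)])
  }
  data.frame(cell_id = roi$cell_id, mean_ctb = mean(v), max_ctb = mx)
}

#' Raft metrics for every cell of a field
#'
#' @param rois List of `cell_roi` objects.
#' @inheritParams cell_ctb_metrics
#' @return Data frame with one row per cell.
#' @export
raft_metrics <- function(rois, image, ctb_channel = "ctb",
                         max_method = c("max", "top_percent"),
                         top_fraction = 0.01) {
  max_method <- match.arg(max_method)
  out <- do.call(rbind, lapply(rois, cell_ctb_metrics, image = image,
                               ctb_channel = ctb_channel,
                               max_method = max_method,
                               top_fraction = top_fraction))
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), mean_ctb = numeric(0),
                      max_ctb = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Field-level raft summary
#'
#' One observation per field: the arithmetic mean of the per-cell means and
#' of the per-cell maxima over all T cells in the field.
#'
#' @param metrics Data frame from [raft_metrics()] (>= 1 cell).
#' @param field_id Field identifier.
#' @return One-row data frame: `field_id`, `n_cells`, `mean_of_means`,
#'   `mean_of_maxima`.
#' @export
field_average <- function(metrics, field_id = NA_character_) {
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics) == 0L) {
    stop("no cells to average", call. = FALSE)
  }
  data.frame(field_id = field_id, n_cells = nrow(metrics),
             mean_of_means = mean(metrics$mean_ctb),
             mean_of_maxima = mean(metrics$max_ctb))
}
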