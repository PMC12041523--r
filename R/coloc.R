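#' Co-localization classifier configuration
#'
#' Per-cell classification takes the `k` brightest reference-channel pixels
#' of the ROI and regresses the second channel on the first by ordinary
#' least squares; the cell is called positive when the slope is positive and
#' significant at `alpha`. `"two_sided_positive_slope"` (default) uses the
#' two-sided slope t-test p with a positive-slope requirement, matching how
#' standard regression software reports p values; `"one_sided_positive"`
#' uses the upper-tail p directly.
#'
#' @param k Number of top reference pixels per cell (default 50).
#' @param alpha Significance level (default 0.05).
#' @param sidedness Test convention, see Details.
#' @param min_pixels Minimum ROI size to attempt classification.
#' @return A list of class `coloc_config`.
#' @export
coloc_config <- function(k = 50L,
                         alpha = 0.05,
                         sidedness = c("two_sided_positive_slope",
                                       "one_sided_positive"),
                         min_pixels = 10L) {
  sidedness <- match.arg(sidedness)
  stopifnot(k >= 3, alpha > 0, alpha < 1, min_pixels >= 3)
  structure(list(k = as.integer(k), alpha = alpha, sidedness = sidedness,
                 min_pixels = as.integer(min_pixels)),
            class = "coloc_config")
}

#' Brightest-pixel subset of an ROI
#'
#' Returns the `min(k, area)` ROI pixels with the largest reference-channel
#' intensity. Ties at the cutoff are broken by raster order (row, then
#' column) so the subset is deterministic.
#'
#' @param roi A `cell_roi`.
#' @param image A [field_image()].
#' @param ref_channel Reference channel name (Bodipy in the lipid-droplet
#'   assay).
#' @param k Number of pixels requested.
#' @return List with `coords` (`(row, col)` matrix, brightest first),
#'   `intensities` (matching reference intensities) and `undersized`
#'   (`TRUE` when the ROI has fewer than `k` pixels).
#' @export
top_pixels <- function(roi, image, ref_channel, k = 50L) {
  px <- roi_pixels(roi, image, ref_channel)
  if (nrow(px$coords) == 0L) {
    stop("empty ROI", call. = FALSE)
  }
  ord <- order(-px$intensities, px$coords[, 1L], px$coords[, 2L])
  take <- seq_len(min(k, length(ord)))
  list(coords = px$coords[ord[take], , drop = FALSE],
       intensities = px$intensities[ord[take]],
       undersized = nrow(px$coords) < k)
}

# OLS of y on x with the slope t-test; returns NA-free degenerate results
# for constant x (positive = FALSE, p = 1) and constant y (slope 0).
slope_test <- function(x, y, sidedness) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  if (sxx <= 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r = 0,
                p = 1, degenerate = TRUE))
  }
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  r <- if (syy > 0) sxy / sqrt(sxx * syy) else 0
  rss <- max(syy - slope * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  t_stat <- if (se > 0) slope / se else sign(slope) * Inf
  p <- switch(sidedness,
              two_sided_positive_slope = 2 * stats::pt(-abs(t_stat),
                                                       df = n - 2),
              one_sided_positive = stats::pt(t_stat, df = n - 2,
                                             lower.tail = FALSE))
  if (syy <= 0) p <- 1  # constant y: nothing to explain
  list(slope = slope, intercept = intercept, r = r, p = p, degenerate = FALSE)
}

#' Classify one cell as PLIN2-co-localizing or not
#'
#' Ordinary least-squares regression of the `y_channel` intensity on the
#' `x_channel` intensity over a pixel subset (normally from [top_pixels()]),
#' with the slope t-test on `n - 2` degrees of freedom. The cell is positive
#' when the slope is positive and the p value (per the configured sidedness)
#' is below `alpha`. The call is invariant to positive affine transforms of
#' either channel since the slope t statistic is.
#'
#' @param pixels Pixel subset from [top_pixels()] (list with `coords` and
#'   `undersized`), or a bare `(row, col)` coordinate matrix.
#' @param image A [field_image()].
#' @param x_channel,y_channel Channel names (reference and probe).
#' @param config A [coloc_config()].
#' @param cell_id Id recorded in the result.
#' @return One-row data frame of class `coloc_cell_result`: `cell_id`,
#'   `n_pixels`, `slope`, `intercept`, `r`, `p`, `positive`, `undersized`.
#' @export
classify_cell <- function(pixels, image, x_channel = "bodipy",
                          y_channel = "plin2", config = coloc_config(),
                          cell_id = NA_integer_) {
  stopifnot(inherits(config, "coloc_config"))
  if (is.matrix(pixels)) {
    pixels <- list(coords = pixels, undersized = FALSE)
  }
  coords <- pixels$coords
  n <- nrow(coords)
  if (n < config$min_pixels) {
    stop(sprintf("only %d pixels; min_pixels is %d", n, config$min_pixels),
         call. = FALSE)
  }
  x <- channel(image, x_channel)[coords]
  y <- channel(image, y_channel)[coords]
  fit <- slope_test(x, y, config$sidedness)
  positive <- !fit$degenerate && !is.na(fit$slope) &&
    fit$slope > 0 && fit$p < config$alpha
  out <- data.frame(cell_id = cell_id, n_pixels = n,
                    slope = fit$slope, intercept = fit$intercept,
                    r = fit$r, p = fit$p, positive = positive,
                    undersized = isTRUE(pixels$undersized))
  class(out) <- c("coloc_cell_result", class(out))
  out
}

#' Classify every cell of a field
#'
#' Convenience wrapper: [top_pixels()] then [classify_cell()] per ROI.
#' Cells smaller than `k` are classified on all their pixels and flagged
#' `undersized`; cells below `min_pixels` are skipped with a warning.
#'
#' @param rois List of `cell_roi` objects.
#' @inheritParams classify_cell
#' @param ref_channel Channel used for top-pixel selection.
#' @return Data frame with one row per classified cell.
#' @export
classify_cells <- function(rois, image, ref_channel = "bodipy",
                           x_channel = "bodipy", y_channel = "plin2",
                           config = coloc_config()) {
  res <- lapply(rois, function(roi) {
    if (roi$area < config$min_pixels) {
      warning(sprintf("cell %d skipped: %d px < min_pixels", roi$cell_id,
                      roi$area))
      return(NULL)
    }
    px <- top_pixels(roi, image, ref_channel, config$k)
    classify_cell(px, image, x_channel, y_channel, config,
                  cell_id = roi$cell_id)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), n_pixels = integer(0),
                      slope = numeric(0), intercept = numeric(0),
                      r = numeric(0), p = numeric(0), positive = logical(0),
                      undersized = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Population co-localization summary
#'
#' Percentage of cells with a significant positive Bodipy-PLIN2 regression,
#' reported to one decimal.
#'
#' @param results Data frame from [classify_cells()].
#' @param condition Condition label carried into the summary.
#' @param include_undersized Include cells flagged `undersized` (default
#'   drops them).
#' @return One-row data frame: `condition`, `n_cells`, `n_positive`,
#'   `percent_positive`.
#' @export
summarize_coloc <- function(results, condition = NA_character_,
                            include_undersized = FALSE) {
  stopifnot(is.data.frame(results))
  if (!include_undersized) {
    results <- results[!results$undersized, , drop = FALSE]
  }
  if (nrow(results) == 0L) {
    stop("no classified cells to summarize", call. = FALSE)
  }
  n <- nrow(results)
  np <- sum(results$positive)
  data.frame(condition = condition, n_cells = n, n_positive = np,
             percent_positive = round(100 * np / n, 1))
}

#' Cross-sectional intensity profile
#'
#' Gray-value traces of one or more channels along a line between two pixel
#' endpoints, sampled at nearest pixels -- the spatial-plot diagnostic used
#' to inspect Bodipy/PLIN2 co-occurrence across a cell. All channels are
#' sampled at the same positions, so traces have equal length.
#'
#' @param image A [field_image()].
#' @param from,to Endpoints as `(row, col)` pairs (within bounds).
#' @param channels Channel names; default all.
#' @return Data frame with `step`, `row`, `col` and one column per channel.
#' @export
intensity_profile <- function(image, from, to, channels = NULL) {
  stopifnot(inherits(image, "field_image"),
            length(from) == 2L, length(to) == 2L)
  d <- dim(image)
  if (any(c(from, to) < 1) || from[1L] > d[1L] || to[1L] > d[1L] ||
      from[2L] > d[2L] || to[2L] > d[2L]) {
    stop("profile endpoints outside the image", call. = FALSE)
  }
  if (all(from == to)) {
    stop("zero-length profile line", call. = FALSE)
  }
  if (is.null(channels)) channels <- names(image$channels)
  n <- max(abs(to - from)) + 1L
  tt <- seq(0, 1, length.out = n)
  rows <- round(from[1L] + tt * (to[1L] - from[1L]))
  cols <- round(from[2L] + tt * (to[2L] - from[2L]))
  out <- data.frame(step = seq_len(n) - 1L, row = rows, col = cols)
  for (ch in channels) {
    out[[ch]] <- channel(image, ch)[cbind(rows, cols)]
  }
  out
}
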