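#' Multi-channel microscopy field
#'
#' A `field_image` holds one confocal field as a named list of 2-D intensity
#' rasters sharing a common shape. Pixel coordinates are 1-based `(row, col)`
#' matrix indices throughout the package; intensities are non-negative and,
#' for generated fields, integer-valued on a 16-bit scale.
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions and non-negative entries. Typical channel names are
#'   `"membrane"`, `"bodipy"`, `"plin2"` and `"ctb"`.
#' @param pixel_size Optional pixel edge length in micrometers (informational).
#'
#' @return An object of class `field_image`.
#' @examples
#' img <- field_image(list(dapi = matrix(0, 8, 8)))
#' dim(img)
#' @export
field_image <- function(channels, pixel_size = NULL) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of matrices", call. = FALSE)
  }
  dims <- vapply(channels, function(m) {
    if (!is.matrix(m) || !is.numeric(m)) {
      stop("every channel must be a numeric matrix", call. = FALSE)
    }
    dim(m)
  }, integer(2))
  if (!all(dims == dims[, 1L])) {
    stop("all channels must share one shape", call. = FALSE)
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "field_image")
}

#' @export
dim.field_image <- function(x) dim(x$channels[[1L]])

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<field_image> %d x %d px, channels: %s\n",
              d[1L], d[2L], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract one channel of a field image
#'
#' @param image A [field_image()].
#' @param name Channel name.
#' @return The channel's intensity matrix.
#' @export
channel <- function(image, name) {
  stopifnot(inherits(image, "field_image"))
  if (!name %in% names(image$channels)) {
    stop(sprintf("channel '%s' not found (available: %s)", name,
                 paste(names(image$channels), collapse = ", ")), call. = FALSE)
  }
  image$channels[[name]]
}

#' Gaussian point-spread blur
#'
#' Separable Gaussian convolution used as the isotropic PSF model of the
#' synthetic-field generators. The kernel is truncated at `4 * sigma` pixels
#' and renormalized to unit sum; borders use replicate padding, so a constant
#' image is exactly invariant and total intensity away from borders is
#' preserved.
#'
#' @param x Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `0` returns `x`
#'   unchanged.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) {
    return(x)
  }
  r <- as.integer(ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  conv_cols <- function(m) {
    # convolve down each column with replicate padding
    mp <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[seq_len(nrow(m)) + (j - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(x))))
}

# Shared camera model: Poisson shot noise on the expected signal, additive
# Gaussian read noise, 16-bit quantization with saturation clipping.
apply_camera_noise <- function(signal, shot_noise, read_noise_sd) {
  out <- signal
  if (shot_noise) {
    out <- matrix(stats::rpois(length(out), lambda = pmax(out, 0)),
                  nrow(out), ncol(out))
  }
  if (read_noise_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), sd = read_noise_sd),
                        nrow(out), ncol(out))
  }
  matrix(pmin(pmax(round(out), 0), 65535), nrow(out), ncol(out))
}

#' Write / read a field image as multi-page TIFF
#'
#' Channels are written as 16-bit pages in the order of `names(image$channels)`;
#' channel names are stored in a plain-text sidecar (`<path>.channels.txt`) so
#' the round trip preserves them.
#'
#' @param image A [field_image()].
#' @param path Output TIFF path.
#' @return `write_field_image()` returns `path` invisibly; `read_field_image()`
#'   returns a [field_image()].
#' @export
write_field_image <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  }
  pages <- lapply(image$channels, function(m) pmin(pmax(m, 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  writeLines(names(image$channels), paste0(path, ".channels.txt"))
  invisible(path)
}

#' @rdname write_field_image
#' @export
read_field_image <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF import", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".channels.txt")
  nms <- if (file.exists(sidecar)) readLines(sidecar) else
    paste0("channel", seq_along(pages))
  channels <- lapply(pages, function(p) round(p * 65535))
  names(channels) <- nms
  field_image(channels)
}
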