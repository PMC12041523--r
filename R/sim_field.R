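# Shared geometry helpers for the synthetic-field generators.

# Non-overlapping disk placement by rejection sampling, bounded retries per
# cell; cells keep a 2 px clearance from each other and from the border.
place_cells <- function(field_shape, n_cells, radius, max_retries = 1000L) {
  centers <- matrix(numeric(0), 0L, 2L)
  min_sep2 <- (2 * radius + 2)^2
  lo <- radius + 2
  hi_r <- field_shape[1L] - radius - 1
  hi_c <- field_shape[2L] - radius - 1
  if (n_cells > 0 && (hi_r <= lo || hi_c <= lo)) {
    stop("field too small for the requested cell radius", call. = FALSE)
  }
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- c(stats::runif(1, lo, hi_r), stats::runif(1, lo, hi_c))
      if (nrow(centers) == 0L ||
          all((centers[, 1L] - cand[1L])^2 +
              (centers[, 2L] - cand[2L])^2 >= min_sep2)) {
        centers <- rbind(centers, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("degenerate geometry: could not place cell %d ",
                          "without overlap after %d retries"), i, max_retries),
           call. = FALSE)
    }
  }
  dimnames(centers) <- NULL
  centers
}

# (row, col) index matrix of the filled disk of given radius, clipped to the
# field bounds.
disk_pixels <- function(center, radius, field_shape) {
  r0 <- center[1L]
  c0 <- center[2L]
  rows <- max(1L, floor(r0 - radius)):min(field_shape[1L], ceiling(r0 + radius))
  cols <- max(1L, floor(c0 - radius)):min(field_shape[2L], ceiling(c0 + radius))
  grid <- expand.grid(row = rows, col = cols)
  keep <- (grid$row - r0)^2 + (grid$col - c0)^2 <= radius^2
  as.matrix(grid[keep, , drop = FALSE])
}

# Label mask (integer matrix) from cell centers/radius; cells are disjoint by
# construction so later labels never overwrite earlier ones.
cells_label_mask <- function(centers, radius, field_shape) {
  mask <- matrix(0L, field_shape[1L], field_shape[2L])
  for (i in seq_len(nrow(centers))) {
    px <- disk_pixels(centers[i, ], radius, field_shape)
    mask[px] <- i
  }
  mask
}
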