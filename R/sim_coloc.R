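#' Parameters for the lipid-aggregate / PLIN2 co-localization simulator
#'
#' Defines the study conditions emulated by [gen_coloc_field()]: T cells as
#' non-overlapping disks, cytoplasmic neutral-lipid aggregates imaged in a
#' Bodipy channel, and a PLIN2 channel that in a random `coloc_fraction` of
#' cells is linearly coupled to the Bodipy signal at aggregate pixels.
#'
#' Default intensities put the aggregate amplitude at peak
#' signal-to-noise ratio of about 10 under the Poisson + read-noise camera
#' model (amplitude 150 over background 100, noise sd ~ sqrt(250)); the
#' membrane amplitude of 400 makes segmentation unambiguous.
#'
#' @param field_shape Field size in pixels, `c(rows, cols)`.
#' @param n_cells Number of cells to place.
#' @param cell_radius Cell disk radius in pixels.
#' @param aggregates_per_cell Integer range `c(min, max)` of lipid aggregates
#'   per cell.
#' @param aggregate_radius Aggregate disk radius in pixels.
#' @param coloc_fraction Probability in `[0, 1]` that a cell's aggregates
#'   carry PLIN2 signal (the cell is "coupled").
#' @param coupling_slope Linear gain of PLIN2 on Bodipy in coupled cells.
#' @param membrane_intensity,aggregate_intensity Signal amplitudes (16-bit
#'   counts) of the cell body in the membrane channel and of aggregates in the
#'   Bodipy channel.
#' @param psf_sigma Isotropic Gaussian PSF sd in pixels (`0` = no blur).
#' @param background Constant background offset added to every channel.
#' @param read_noise_sd Additive Gaussian read-noise sd (`0` = off).
#' @param shot_noise Logical; apply Poisson shot noise.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return A list of class `coloc_sim_params`.
#' @export
coloc_sim_params <- function(field_shape = c(512L, 512L),
                             n_cells = 50L,
                             cell_radius = 10,
                             aggregates_per_cell = c(1L, 4L),
                             aggregate_radius = 2,
                             coloc_fraction = 0.7,
                             coupling_slope = 0.8,
                             membrane_intensity = 400,
                             aggregate_intensity = 150,
                             psf_sigma = 1,
                             background = 100,
                             read_noise_sd = 5,
                             shot_noise = TRUE,
                             seed = 1L) {
  stopifnot(length(field_shape) == 2L, all(field_shape >= 8),
            n_cells >= 0, cell_radius > 0, aggregate_radius > 0,
            length(aggregates_per_cell) == 2L,
            aggregates_per_cell[1L] >= 0,
            aggregates_per_cell[2L] >= aggregates_per_cell[1L],
            coloc_fraction >= 0, coloc_fraction <= 1,
            psf_sigma >= 0, background >= 0, read_noise_sd >= 0,
            is.logical(shot_noise))
  structure(list(field_shape = as.integer(field_shape),
                 n_cells = as.integer(n_cells),
                 cell_radius = cell_radius,
                 aggregates_per_cell = as.integer(aggregates_per_cell),
                 aggregate_radius = aggregate_radius,
                 coloc_fraction = coloc_fraction,
                 coupling_slope = coupling_slope,
                 membrane_intensity = membrane_intensity,
                 aggregate_intensity = aggregate_intensity,
                 psf_sigma = psf_sigma,
                 background = background,
                 read_noise_sd = read_noise_sd,
                 shot_noise = shot_noise,
                 seed = as.integer(seed)),
            class = "coloc_sim_params")
}

#' Simulate a Bodipy / PLIN2 co-localization field
#'
#' Generates a three-channel field (`membrane`, `bodipy`, `plin2`) with known
#' per-cell ground truth. In coupled cells the pre-noise PLIN2 intensity at
#' aggregate pixels equals `coupling_slope * bodipy + background`; in
#' uncoupled cells PLIN2 is background everywhere. The PSF blur is applied to
#' each channel before the camera noise model (Poisson shot noise, then
#' Gaussian read noise, then 16-bit quantization).
#'
#' @param params A [coloc_sim_params()] object.
#' @return A list with elements `image` (a [field_image()]) and `truth`, a
#'   list holding `cells` (data frame: `cell_id`, `row`, `col`, `radius`,
#'   `coupled`, `n_aggregates`), `aggregate_pixels` (per-cell `(row, col)`
#'   index matrices) and `label_mask` (integer matrix of ground-truth cell
#'   labels, usable with [rois_from_mask()]).
#' @examples
#' sim <- gen_coloc_field(coloc_sim_params(n_cells = 4, field_shape = c(128, 128)))
#' sim$truth$cells
#' @export
gen_coloc_field <- function(params) {
  stopifnot(inherits(params, "coloc_sim_params"))
  p <- params
  set.seed(p$seed)
  shape <- p$field_shape
  membrane <- matrix(0, shape[1L], shape[2L])
  bodipy <- matrix(0, shape[1L], shape[2L])

  centers <- place_cells(shape, p$n_cells, p$cell_radius)
  coupled <- if (p$n_cells > 0) stats::runif(p$n_cells) < p$coloc_fraction
             else logical(0)
  agg_px <- vector("list", p$n_cells)
  n_agg <- integer(p$n_cells)

  for (i in seq_len(p$n_cells)) {
    cell <- disk_pixels(centers[i, ], p$cell_radius, shape)
    membrane[cell] <- p$membrane_intensity
    n_agg[i] <- if (p$aggregates_per_cell[1L] == p$aggregates_per_cell[2L]) {
      p$aggregates_per_cell[1L]
    } else {
      sample(p$aggregates_per_cell[1L]:p$aggregates_per_cell[2L], 1L)
    }
    px_list <- vector("list", n_agg[i])
    max_off <- max(p$cell_radius - p$aggregate_radius - 1, 0)
    for (a in seq_len(n_agg[i])) {
      # aggregate center uniform in the disk that keeps it inside the cell
      repeat {
        off <- stats::runif(2, -max_off, max_off)
        if (sum(off^2) <= max_off^2) break
      }
      px_list[[a]] <- disk_pixels(centers[i, ] + off, p$aggregate_radius, shape)
    }
    px <- unique(do.call(rbind, px_list))
    bodipy[px] <- p$aggregate_intensity
    agg_px[[i]] <- px
  }

  membrane_img <- membrane + p$background
  bodipy_img <- bodipy + p$background
  plin2_img <- matrix(p$background, shape[1L], shape[2L])
  for (i in which(coupled)) {
    if (!is.null(agg_px[[i]]) && nrow(agg_px[[i]]) > 0) {
      plin2_img[agg_px[[i]]] <-
        p$coupling_slope * bodipy_img[agg_px[[i]]] + p$background
    }
  }

  channels <- lapply(list(membrane = membrane_img, bodipy = bodipy_img,
                          plin2 = plin2_img),
                     gaussian_blur, sigma = p$psf_sigma)
  channels <- lapply(channels, apply_camera_noise,
                     shot_noise = p$shot_noise,
                     read_noise_sd = p$read_noise_sd)

  cells <- data.frame(cell_id = seq_len(p$n_cells),
                      row = if (p$n_cells) centers[, 1L] else numeric(0),
                      col = if (p$n_cells) centers[, 2L] else numeric(0),
                      radius = rep(p$cell_radius, p$n_cells),
                      coupled = coupled,
                      n_aggregates = n_agg)
  list(image = field_image(channels),
       truth = list(cells = cells,
                    aggregate_pixels = agg_px,
                    label_mask = cells_label_mask(centers, p$cell_radius,
                                                  shape)))
}
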