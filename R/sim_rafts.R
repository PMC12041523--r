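#' Parameters for the CT-B lipid-raft field simulator
#'
#' Study conditions for [gen_raft_field()]: cells as disks in a membrane
#' (lineage) channel, and a CT-B channel with `puncta_per_cell` point-like
#' raft puncta on the membrane annulus. `clustering` interpolates the angular
#' spread of puncta between uniform over the whole circle (`0`) and confined
#' to a single arc of `arc_width` radians (`1`); each punctum deposits a fixed
#' total intensity, so the per-cell total CT-B signal does not depend on
#' `clustering`.
#'
#' @inheritParams coloc_sim_params
#' @param puncta_per_cell Number of raft puncta per cell.
#' @param puncta_intensity Total (integrated) intensity of one punctum.
#' @param clustering Concentration parameter in `[0, 1]`.
#' @param arc_width Arc width in radians reached at `clustering = 1`.
#' @param annulus_fraction Radial position of puncta as a fraction of the
#'   cell radius.
#' @return A list of class `raft_sim_params`.
#' @export
raft_sim_params <- function(field_shape = c(512L, 512L),
                            n_cells = 50L,
                            cell_radius = 10,
                            puncta_per_cell = 6L,
                            puncta_intensity = 2000,
                            clustering = 0,
                            arc_width = pi / 8,
                            annulus_fraction = 0.85,
                            membrane_intensity = 400,
                            psf_sigma = 1,
                            background = 100,
                            read_noise_sd = 5,
                            shot_noise = TRUE,
                            seed = 1L) {
  stopifnot(length(field_shape) == 2L, n_cells >= 0, cell_radius > 0,
            puncta_per_cell >= 0, puncta_intensity >= 0,
            clustering >= 0, clustering <= 1,
            arc_width > 0, arc_width <= 2 * pi,
            annulus_fraction > 0, annulus_fraction < 1,
            psf_sigma >= 0, background >= 0, read_noise_sd >= 0)
  structure(list(field_shape = as.integer(field_shape),
                 n_cells = as.integer(n_cells),
                 cell_radius = cell_radius,
                 puncta_per_cell = as.integer(puncta_per_cell),
                 puncta_intensity = puncta_intensity,
                 clustering = clustering,
                 arc_width = arc_width,
                 annulus_fraction = annulus_fraction,
                 membrane_intensity = membrane_intensity,
                 psf_sigma = psf_sigma,
                 background = background,
                 read_noise_sd = read_noise_sd,
                 shot_noise = shot_noise,
                 seed = as.integer(seed)),
            class = "raft_sim_params")
}

#' Simulate a CT-B lipid-raft field
#'
#' Generates a two-channel field (`membrane`, `ctb`) plus ground truth. Puncta
#' angles are drawn uniformly inside an arc whose width shrinks linearly from
#' the full circle at `clustering = 0` to `arc_width` at `clustering = 1`, so
#' the angular spread narrows monotonically with the clustering parameter
#' while the deposited total intensity stays fixed.
#'
#' @param params A [raft_sim_params()] object.
#' @return A list with `image` (a [field_image()]) and `truth`: `cells` data
#'   frame, per-cell `puncta` coordinate matrices (`row`, `col`, `angle`) and
#'   `label_mask` for [rois_from_mask()].
#' @export
gen_raft_field <- function(params) {
  stopifnot(inherits(params, "raft_sim_params"))
  p <- params
  set.seed(p$seed)
  shape <- p$field_shape
  membrane <- matrix(0, shape[1L], shape[2L])
  ctb <- matrix(0, shape[1L], shape[2L])

  centers <- place_cells(shape, p$n_cells, p$cell_radius)
  puncta <- vector("list", p$n_cells)
  width <- p$arc_width + (1 - p$clustering) * (2 * pi - p$arc_width)
  rho <- p$annulus_fraction * p$cell_radius

  for (i in seq_len(p$n_cells)) {
    membrane[disk_pixels(centers[i, ], p$cell_radius, shape)] <-
      p$membrane_intensity
    if (p$puncta_per_cell > 0) {
      theta0 <- stats::runif(1, 0, 2 * pi)
      theta <- theta0 + stats::runif(p$puncta_per_cell, -width / 2, width / 2)
      rr <- centers[i, 1L] + rho * sin(theta)
      cc <- centers[i, 2L] + rho * cos(theta)
      pr <- pmin(pmax(round(rr), 1L), shape[1L])
      pc <- pmin(pmax(round(cc), 1L), shape[2L])
      for (k in seq_len(p$puncta_per_cell)) {
        ctb[pr[k], pc[k]] <- ctb[pr[k], pc[k]] + p$puncta_intensity
      }
      puncta[[i]] <- cbind(row = pr, col = pc, angle = theta %% (2 * pi))
    } else {
      puncta[[i]] <- cbind(row = numeric(0), col = numeric(0),
                           angle = numeric(0))
    }
  }

  channels <- lapply(list(membrane = membrane + p$background,
                          ctb = ctb + p$background),
                     gaussian_blur, sigma = p$psf_sigma)
  channels <- lapply(channels, apply_camera_noise,
                     shot_noise = p$shot_noise,
                     read_noise_sd = p$read_noise_sd)

  cells <- data.frame(cell_id = seq_len(p$n_cells),
                      row = if (p$n_cells) centers[, 1L] else numeric(0),
                      col = if (p$n_cells) centers[, 2L] else numeric(0),
                      radius = rep(p$cell_radius, p$n_cells))
  list(image = field_image(channels),
       truth = list(cells = cells,
                    puncta = puncta,
                    arc_width_used = width,
                    label_mask = cells_label_mask(centers, p$cell_radius,
                                                  shape)))
}
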