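#' Parameters for the dye-dilution (CellTrace Violet) event simulator
#'
#' Study conditions for [gen_ctv_events()]: a proliferation dye loaded before
#' stimulation is halved at every division, so events of generation *i* are
#' log-normal around `undivided_log10_mean - i * log10(dilution_per_division)`
#' on the log10 intensity scale. `generation_fractions` are the cell-level
#' fractions of acquired events per generation 0..G; the default profile
#' `c(0.125, 0.125, 0.25, 0.5)` represents a well-stimulated culture in which
#' most acquired cells have divided two or three times.
#'
#' @param n_events Number of events to draw.
#' @param generation_fractions Non-negative vector over generations 0..G
#'   summing to 1 (tolerance 1e-9).
#' @param undivided_log10_mean Log10 intensity center of the undivided peak.
#' @param log10_sd Shared log10 peak width (biological + instrument CV).
#' @param dilution_per_division Dye dilution factor per division (> 1).
#' @param autofluorescence_floor Intensity added linearly to every event.
#' @param seed Integer seed.
#' @return A list of class `ctv_sim_params`.
#' @export
ctv_sim_params <- function(n_events = 20000L,
                           generation_fractions = c(0.125, 0.125, 0.25, 0.5),
                           undivided_log10_mean = 4,
                           log10_sd = 0.05,
                           dilution_per_division = 2,
                           autofluorescence_floor = 50,
                           seed = 1L) {
  stopifnot(n_events >= 1, length(generation_fractions) >= 1,
            all(generation_fractions >= 0),
            log10_sd >= 0, autofluorescence_floor >= 0)
  if (abs(sum(generation_fractions) - 1) > 1e-9) {
    stop("`generation_fractions` must sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  if (dilution_per_division <= 1) {
    stop("`dilution_per_division` must exceed 1", call. = FALSE)
  }
  structure(list(n_events = as.integer(n_events),
                 generation_fractions = generation_fractions,
                 undivided_log10_mean = undivided_log10_mean,
                 log10_sd = log10_sd,
                 dilution_per_division = dilution_per_division,
                 autofluorescence_floor = autofluorescence_floor,
                 seed = as.integer(seed)),
            class = "ctv_sim_params")
}

#' Simulate dye-dilution cytometry events
#'
#' @param params A [ctv_sim_params()] object.
#' @return A list with `events`, a data frame with one `ctv` intensity column
#'   (one row per event), and `truth`, a data frame with the true `generation`
#'   of each event.
#' @examples
#' sim <- gen_ctv_events(ctv_sim_params(n_events = 1000))
#' table(sim$truth$generation)
#' @export
gen_ctv_events <- function(params) {
  stopifnot(inherits(params, "ctv_sim_params"))
  p <- params
  set.seed(p$seed)
  gmax <- length(p$generation_fractions) - 1L
  gen <- sample.int(gmax + 1L, p$n_events, replace = TRUE,
                    prob = p$generation_fractions) - 1L
  mu <- p$undivided_log10_mean - gen * log10(p$dilution_per_division)
  lx <- if (p$log10_sd > 0) stats::rnorm(p$n_events, mu, p$log10_sd) else mu
  intensity <- 10^lx + p$autofluorescence_floor
  list(events = data.frame(ctv = intensity),
       truth = data.frame(generation = gen))
}
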