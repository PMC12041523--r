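#' Parameters for the lipidomics intensity-table simulator
#'
#' Study conditions for [gen_lipid_table()]: a species-by-sample intensity
#' table with one spiked internal-standard row per lipid class, two sample
#' groups (reference and case), log-normal measurement noise of coefficient
#' of variation `cv`, and seeded per-species group log2 fold-changes. Species
#' intensities are proportional to their true amounts scaled by the class
#' standard's response, so class-matched internal-standard normalization
#' recovers the true nmol amounts exactly when `cv = 0`.
#'
#' @param classes Character vector of lipid class labels; each must have a
#'   row in `standards` (unknown classes are a validation error).
#' @param species_per_class Analyte species per class.
#' @param n_samples_per_group Samples in each of the two groups.
#' @param group_names Labels of the reference and case group, in that order.
#' @param group_log2fc Named numeric vector mapping species names to seeded
#'   log2 fold-changes (case vs reference); unnamed species default to 0.
#' @param cv Log-normal coefficient of variation of measured intensities
#'   (>= 0; 0 gives the exact noise-free table).
#' @param is_intensity Measured intensity of each class's internal standard
#'   (scalar, or named by class).
#' @param baseline_nmol Geometric center of the true per-species amounts.
#' @param sample_gain_cv Log-normal CV of a per-sample global intensity gain
#'   (0 by default; the gain cancels in internal-standard normalization).
#' @param standards Standards map used to anchor the simulated responses;
#'   defaults to [internal_standards()].
#' @param seed Integer seed.
#' @return A list of class `lipid_sim_params`.
#' @export
lipid_sim_params <- function(classes = c("PC", "TAG", "SM", "CE", "PE"),
                             species_per_class = 8L,
                             n_samples_per_group = 5L,
                             group_names = c("HD", "CLL"),
                             group_log2fc = NULL,
                             cv = 0.2,
                             is_intensity = 1e6,
                             baseline_nmol = 1,
                             sample_gain_cv = 0,
                             standards = internal_standards(),
                             seed = 1L) {
  stopifnot(length(classes) >= 1, species_per_class >= 1,
            n_samples_per_group >= 1, length(group_names) == 2L,
            cv >= 0, all(is_intensity > 0), baseline_nmol > 0,
            sample_gain_cv >= 0)
  unknown <- setdiff(classes, standards$class)
  if (length(unknown)) {
    stop(sprintf("species assigned to unknown class(es): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(is_intensity) > 1L &&
      (is.null(names(is_intensity)) || !all(classes %in% names(is_intensity)))) {
    stop("`is_intensity` must be a scalar or named by class", call. = FALSE)
  }
  if (!is.null(group_log2fc) &&
      (is.null(names(group_log2fc)) || !all(nzchar(names(group_log2fc))))) {
    stop("`group_log2fc` must be a named numeric vector", call. = FALSE)
  }
  structure(list(classes = classes,
                 species_per_class = as.integer(species_per_class),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 group_names = group_names,
                 group_log2fc = group_log2fc,
                 cv = cv,
                 is_intensity = is_intensity,
                 baseline_nmol = baseline_nmol,
                 sample_gain_cv = sample_gain_cv,
                 standards = standards,
                 seed = as.integer(seed)),
            class = "lipid_sim_params")
}

#' Simulate a lipid species intensity table with internal standards
#'
#' @param params A [lipid_sim_params()] object.
#' @return A list with `table`, a [lipid_table()] whose rows include one
#'   internal-standard row per class, and `truth`, a list holding the
#'   per-species true amounts (`species` data frame with `nmol` and `log2fc`)
#'   and the per-sample gains.
#' @examples
#' sim <- gen_lipid_table(lipid_sim_params(classes = c("PC", "TAG"),
#'                                         species_per_class = 3,
#'                                         n_samples_per_group = 2, cv = 0))
#' sim$table
#' @export
gen_lipid_table <- function(params) {
  stopifnot(inherits(params, "lipid_sim_params"))
  p <- params
  set.seed(p$seed)
  std <- p$standards[match(p$classes, p$standards$class), , drop = FALSE]
  is_int <- if (length(p$is_intensity) == 1L) {
    stats::setNames(rep(p$is_intensity, length(p$classes)), p$classes)
  } else {
    p$is_intensity[p$classes]
  }

  species <- unlist(lapply(p$classes, function(cl) {
    sprintf("%s(%d:%d)", cl, 30 + 2 * seq_len(p$species_per_class),
            seq_len(p$species_per_class) %% 5)
  }))
  sp_class <- rep(p$classes, each = p$species_per_class)
  n_sp <- length(species)

  # true per-species reference amounts, log-uniform around the baseline
  true_nmol <- p$baseline_nmol * 2^stats::runif(n_sp, -2, 2)
  fc <- stats::setNames(rep(0, n_sp), species)
  if (!is.null(p$group_log2fc)) {
    known <- intersect(names(p$group_log2fc), species)
    fc[known] <- p$group_log2fc[known]
    missing <- setdiff(names(p$group_log2fc), species)
    if (length(missing)) {
      stop(sprintf("group_log2fc names not in the simulated species: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }

  n_tot <- 2L * p$n_samples_per_group
  sample_names <- paste0(rep(p$group_names, each = p$n_samples_per_group),
                         "_", rep(seq_len(p$n_samples_per_group), 2L))
  group <- rep(p$group_names, each = p$n_samples_per_group)

  sdlog <- if (p$cv > 0) sqrt(log(1 + p$cv^2)) else 0
  amounts <- outer(true_nmol, ifelse(group == p$group_names[2L], 1, 0),
                   function(a, g) a) *
    2^outer(fc, ifelse(group == p$group_names[2L], 1, 0), "*")
  if (sdlog > 0) {
    amounts <- amounts * matrix(stats::rlnorm(n_sp * n_tot, 0, sdlog),
                                n_sp, n_tot)
  }

  # per-sample gains drawn after the amount noise so that enabling the gain
  # leaves the amount stream (and hence the normalized truth) unchanged
  gains <- if (p$sample_gain_cv > 0) {
    stats::rlnorm(n_tot, 0, sqrt(log(1 + p$sample_gain_cv^2)))
  } else {
    rep(1, n_tot)
  }

  # response anchored to the class standard: intensity per nmol equals
  # is_intensity(class) / nmol(class standard), times the per-sample gain
  resp <- is_int[sp_class] / std$nmol[match(sp_class, std$class)]
  intensity <- amounts * resp * rep(gains, each = n_sp)

  is_rows <- t(vapply(seq_along(p$classes),
                      function(i) is_int[i] * gains,
                      numeric(n_tot)))
  all_int <- rbind(intensity, is_rows)
  rownames(all_int) <- c(species, std$standard)
  colnames(all_int) <- sample_names

  sp_df <- data.frame(species = c(species, std$standard),
                      class = c(sp_class, std$class),
                      is_standard = c(rep(FALSE, n_sp),
                                      rep(TRUE, nrow(std))))
  smp_df <- data.frame(sample = sample_names, group = group,
                       protein_ug = rep(100, n_tot))
  list(table = lipid_table(all_int, sp_df, smp_df),
       truth = list(species = data.frame(species = species,
                                         class = sp_class,
                                         nmol = true_nmol,
                                         log2fc = unname(fc)),
                    gains = stats::setNames(gains, sample_names)))
}
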