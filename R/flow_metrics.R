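#' Dye-dilution generation model configuration
#'
#' The proliferation model fitted by [fit_generations()]: a one-dimensional
#' Gaussian mixture in log10 intensity whose component centers are fixed at
#' `mu0 - i * delta` for generations `i = 0..max_generations`, with one
#' shared width and free weights. `delta` defaults to `log10(2)`, the
#' spacing implied by two-fold dye dilution per division.
#'
#' @param max_generations Highest generation fitted (G; default 8).
#' @param delta Peak spacing in log10 units (default `log10(2)`).
#' @param sigma Shared log10 peak width; `NULL` (default) fits it by EM, a
#'   number fixes it.
#' @param mu0 Source of the undivided-peak center: `"rightmost_peak"`
#'   (rightmost density mode of the sample itself),
#'   `"unstimulated_control_mode"` (density mode of a matched unstimulated
#'   control, the recommended choice when a control was carried), or
#'   `"fixed"`.
#' @param mu0_value Log10 center when `mu0 = "fixed"`.
#' @param assignment `"soft"` (expected counts, default) or `"hard"`
#'   (modal assignment).
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   largest weight change.
#' @return A list of class `generation_model_config`.
#' @export
generation_model_config <- function(max_generations = 8L,
                                    delta = log10(2),
                                    sigma = NULL,
                                    mu0 = c("rightmost_peak",
                                            "unstimulated_control_mode",
                                            "fixed"),
                                    mu0_value = NULL,
                                    assignment = c("soft", "hard"),
                                    max_iter = 500L,
                                    tol = 1e-8) {
  mu0 <- match.arg(mu0)
  assignment <- match.arg(assignment)
  stopifnot(max_generations >= 1, delta > 0,
            is.null(sigma) || sigma > 0, max_iter >= 1, tol > 0)
  if (mu0 == "fixed" && is.null(mu0_value)) {
    stop("`mu0_value` must be given when mu0 = 'fixed'", call. = FALSE)
  }
  structure(list(max_generations = as.integer(max_generations),
                 delta = delta, sigma = sigma, mu0 = mu0,
                 mu0_value = mu0_value, assignment = assignment,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "generation_model_config")
}

# mode of a log10 intensity sample via kernel density
log10_mode <- function(x) {
  d <- stats::density(log10(x[x > 0]))
  d$x[which.max(d$y)]
}

# rightmost local density maximum carrying at least 5% of the peak height
rightmost_peak <- function(lx) {
  d <- stats::density(lx)
  y <- d$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  is_peak <- is_peak & y >= 0.05 * max(y)
  if (!any(is_peak)) {
    return(d$x[which.max(y)])
  }
  max(d$x[is_peak])
}

#' Fit generation structure to dye-dilution events
#'
#' Expectation-maximization for the fixed-center Gaussian mixture described
#' in [generation_model_config()]. Weights are initialized from the
#' histogram mass within half a spacing of each center, making the fit
#' deterministic given the data and configuration. Counts are the expected
#' per-generation assignments (soft by default).
#'
#' @param events Data frame of per-event intensities (>= 200 events).
#' @param channel Intensity column name.
#' @param config A [generation_model_config()].
#' @param control_events Matched unstimulated events (data frame with the
#'   same channel), required when `mu0 = "unstimulated_control_mode"`.
#' @return An object of class `generation_profile`: list with `counts`
#'   (named vector over generations 0..G summing to the number of events),
#'   `weights`, `mu0`, `sigma`, `delta`, `assignment`, `n_events`,
#'   `iterations`, `converged`.
#' @export
fit_generations <- function(events, channel = "ctv",
                            config = generation_model_config(),
                            control_events = NULL) {
  stopifnot(is.data.frame(events),
            inherits(config, "generation_model_config"))
  if (!channel %in% names(events)) {
    stop(sprintf("channel '%s' not in events", channel), call. = FALSE)
  }
  x <- events[[channel]]
  if (length(x) < 200L) {
    stop("at least 200 events are required", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("event intensities must be finite and positive", call. = FALSE)
  }
  lx <- log10(x)
  mu0 <- switch(config$mu0,
                fixed = config$mu0_value,
                unstimulated_control_mode = {
                  if (is.null(control_events)) {
                    stop("`control_events` required for mu0 source ",
                         "'unstimulated_control_mode'", call. = FALSE)
                  }
                  log10_mode(control_events[[channel]])
                },
                rightmost_peak = rightmost_peak(lx))
  g <- 0:config$max_generations
  centers <- mu0 - g * config$delta
  if (min(lx) < min(centers) - config$delta) {
    warning("events below the lowest fitted generation center; consider ",
            "raising max_generations or checking the autofluorescence floor")
  }

  # initial weights: histogram mass within delta/2 of each center
  w <- vapply(centers, function(cc) {
    mean(abs(lx - cc) <= config$delta / 2)
  }, numeric(1))
  w <- (w + 1e-6) / sum(w + 1e-6)
  sigma <- if (is.null(config$sigma)) config$delta / 4 else config$sigma
  sigma_floor <- 1e-3

  n <- length(lx)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    # E step in log space for numerical safety
    logd <- vapply(seq_along(g), function(i) {
      stats::dnorm(lx, centers[i], sigma, log = TRUE) + log(w[i])
    }, numeric(n))
    m <- apply(logd, 1L, max)
    gamma <- exp(logd - m)
    gamma <- gamma / rowSums(gamma)
    w_new <- colMeans(gamma)
    if (is.null(config$sigma)) {
      sigma <- max(sqrt(sum(gamma * outer(lx, centers, "-")^2) / n),
                   sigma_floor)
    }
    if (max(abs(w_new - w)) < config$tol) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged) {
    stop(sprintf(paste0("EM did not converge in %d iterations ",
                        "(mu0 = %.3f, sigma = %.4f); inspect the data or ",
                        "fix sigma"), config$max_iter, mu0, sigma),
         call. = FALSE)
  }
  logd <- vapply(seq_along(g), function(i) {
    stats::dnorm(lx, centers[i], sigma, log = TRUE) + log(w[i])
  }, numeric(n))
  m <- apply(logd, 1L, max)
  gamma <- exp(logd - m)
  gamma <- gamma / rowSums(gamma)
  counts <- if (config$assignment == "soft") {
    colSums(gamma)
  } else {
    tabulate(max.col(gamma, ties.method = "first"), nbins = length(g))
  }
  names(counts) <- paste0("gen", g)
  structure(list(counts = counts, weights = w, mu0 = mu0, sigma = sigma,
                 delta = config$delta, assignment = config$assignment,
                 n_events = n, iterations = iter, converged = converged),
            class = "generation_profile")
}

#' @export
print.generation_profile <- function(x, ...) {
  cat(sprintf("<generation_profile> %d events, mu0 = %.3f, sigma = %.4f\n",
              x$n_events, x$mu0, x$sigma))
  print(round(x$counts, 1))
  invisible(x)
}

#' Percentage of divided cells
#'
#' `100 * sum(counts[i >= 1]) / sum(counts)`: the share of acquired events
#' lying beyond the undivided peak.
#'
#' @param profile A `generation_profile`, or a bare vector of per-generation
#'   counts (generation 0 first).
#' @return Percentage in `[0, 100]`.
#' @export
percent_divided <- function(profile) {
  counts <- if (inherits(profile, "generation_profile")) profile$counts
            else profile
  stopifnot(all(counts >= 0), sum(counts) > 0)
  100 * sum(counts[-1L]) / sum(counts)
}

#' Division index
#'
#' The average number of divisions a cell of the original (precursor)
#' population has undergone: with precursor counts `P_i = n_i / 2^i`,
#' `DI = sum(i * P_i) / sum(P_i)`. Zero iff no cell divided.
#'
#' @inheritParams percent_divided
#' @return Non-negative divisions-per-precursor value.
#' @export
division_index <- function(profile) {
  counts <- if (inherits(profile, "generation_profile")) profile$counts
            else profile
  stopifnot(all(counts >= 0), sum(counts) > 0)
  i <- seq_along(counts) - 1
  prec <- counts / 2^i
  sum(i * prec) / sum(prec)
}

#' Precursor counts of a generation profile
#'
#' @inheritParams percent_divided
#' @return Vector `P_i = n_i / 2^i` of founding-cell equivalents.
#' @export
precursor_counts <- function(profile) {
  counts <- if (inherits(profile, "generation_profile")) profile$counts
            else profile
  counts / 2^(seq_along(counts) - 1)
}

#' MFI normalization to a reference
#'
#' Elementwise `value / reference`, the convention for reporting mean
#' fluorescence intensity relative to a healthy-donor or unstimulated
#' reference.
#'
#' @param value Measured intensity (vectorized).
#' @param reference Reference intensity, strictly positive (recycled).
#' @return `value / reference`.
#' @export
normalize_mfi <- function(value, reference) {
  if (any(reference <= 0)) {
    stop("reference intensity must be positive", call. = FALSE)
  }
  value / reference
}

#' Stimulated / unstimulated fold-change within matched donors
#'
#' Divides each stimulated sample's intensity by its matched unstimulated
#' sample's intensity. With `donor_stim` / `donor_unstim` given, pairs are
#' matched by donor id and an unmatched donor is an error; otherwise the
#' vectors are taken as already aligned.
#'
#' @param stim,unstim Intensities of stimulated and unstimulated samples.
#' @param donor_stim,donor_unstim Optional donor ids for matching.
#' @return Named (by donor, when ids are given) fold-change vector.
#' @export
fold_change_stim <- function(stim, unstim, donor_stim = NULL,
                             donor_unstim = NULL) {
  if (!is.null(donor_stim) || !is.null(donor_unstim)) {
    if (is.null(donor_stim) || is.null(donor_unstim)) {
      stop("give both donor id vectors or neither", call. = FALSE)
    }
    stopifnot(length(donor_stim) == length(stim),
              length(donor_unstim) == length(unstim))
    idx <- match(donor_stim, donor_unstim)
    if (anyNA(idx)) {
      stop(sprintf("no unstimulated match for donor(s): %s",
                   paste(donor_stim[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    }
    unstim <- unstim[idx]
    names(stim) <- donor_stim
  } else if (length(stim) != length(unstim)) {
    stop("unmatched samples: lengths differ and no donor ids given",
         call. = FALSE)
  }
  if (any(unstim <= 0)) {
    stop("unstimulated intensity must be positive", call. = FALSE)
  }
  stim / unstim
}
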