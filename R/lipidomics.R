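#' Packaged class-matched internal-standard map
#'
#' Amounts (nmol per 2e6-cell pellet) of the non-endogenous lipid standards
#' spiked per class before extraction. Every analyte class must map to
#' exactly one standard; quantitation is single-point, so an analyte's amount
#' is its intensity ratio to the class standard times the spiked amount.
#' Where a class carries more than one spiked compound of the same class
#' label (ceramides, sphingoid bases) one is designated the class standard.
#' Acylcarnitines have no spiked standard and require a user-supplied row.
#'
#' @param path Optional CSV with columns `class`, `standard`, `nmol` to
#'   override the packaged defaults.
#' @return Data frame with columns `class`, `standard`, `nmol`.
#' @export
internal_standards <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "internal_standards.csv",
                        package = "tcellipid", mustWork = TRUE)
  }
  std <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "standard", "nmol") %in% names(std)))
  if (anyDuplicated(std$class)) {
    stop("each class must have exactly one internal standard", call. = FALSE)
  }
  if (any(std$nmol <= 0)) {
    stop("standard amounts must be positive", call. = FALSE)
  }
  std
}

#' Subclass-to-parent class aliases
#'
#' Maps annotation subclasses (ether/plasmalogen variants, hexosylceramide
#' nomenclature) to the parent class whose internal standard is used for
#' normalization. Editable by passing a replacement data frame to
#' [normalize_to_is()].
#'
#' @param path Optional CSV with columns `subclass`, `parent`.
#' @return Data frame with columns `subclass`, `parent`.
#' @export
class_aliases <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_aliases.csv",
                        package = "tcellipid", mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Lipid species intensity table
#'
#' Container for a species-by-sample intensity matrix with species-level
#' class annotation (including which rows are spiked internal standards) and
#' sample-level group metadata.
#'
#' @param intensity Numeric matrix, species in rows, samples in columns;
#'   non-negative. Row and column names must match the annotation.
#' @param species Data frame with columns `species`, `class`, `is_standard`.
#' @param samples Data frame with columns `sample`, `group` and optionally
#'   `protein_ug`.
#' @return An object of class `lipid_table`.
#' @export
lipid_table <- function(intensity, species, samples) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (any(intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  stopifnot(all(c("species", "class", "is_standard") %in% names(species)),
            all(c("sample", "group") %in% names(samples)),
            nrow(intensity) == nrow(species),
            ncol(intensity) == nrow(samples))
  if (is.null(rownames(intensity))) rownames(intensity) <- species$species
  if (is.null(colnames(intensity))) colnames(intensity) <- samples$sample
  stopifnot(identical(rownames(intensity), species$species),
            identical(colnames(intensity), samples$sample))
  if (anyDuplicated(species$species)) {
    stop("duplicated species names", call. = FALSE)
  }
  structure(list(intensity = intensity, species = species, samples = samples),
            class = "lipid_table")
}

#' @export
print.lipid_table <- function(x, ...) {
  cat(sprintf("<lipid_table> %d species (%d internal standards) x %d samples; groups: %s\n",
              nrow(x$intensity), sum(x$species$is_standard),
              ncol(x$intensity),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

# resolve each analyte class to the class key of its standard, via aliases
resolve_class <- function(cls, standards, aliases) {
  hit <- match(cls, aliases$subclass)
  resolved <- ifelse(is.na(hit), cls, aliases$parent[hit])
  missing <- setdiff(unique(resolved), standards$class)
  if (length(missing)) {
    stop(sprintf("no internal standard covers class(es): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  resolved
}

#' Class-matched internal-standard normalization
#'
#' Converts measured intensities to amounts in nmol: for analyte species *s*
#' of class *c* in sample *j*,
#' `amount(s, j) = intensity(s, j) / intensity(IS_c, j) * nmol(IS_c)`,
#' where `IS_c` is the spiked internal standard of class *c*. Any per-sample
#' global intensity gain cancels in the ratio.
#'
#' @param table A [lipid_table()] whose rows include the internal-standard
#'   species named in `standards`.
#' @param standards Standards map (see [internal_standards()]).
#' @param aliases Subclass alias table (see [class_aliases()]); set to an
#'   empty data frame to disable alias resolution.
#' @return An object of class `lipid_amounts`: list with `amounts` (analyte
#'   species x samples matrix, nmol; standard rows are dropped), `species`
#'   and `samples` annotation carried over from `table`.
#' @export
normalize_to_is <- function(table, standards = internal_standards(),
                            aliases = class_aliases()) {
  stopifnot(inherits(table, "lipid_table"))
  analyte <- !table$species$is_standard
  cls <- resolve_class(table$species$class[analyte], standards, aliases)
  std_rows <- match(standards$standard[match(cls, standards$class)],
                    table$species$species)
  if (anyNA(std_rows)) {
    bad <- unique(cls[is.na(std_rows)])
    stop(sprintf("standard row(s) missing from the table for class(es): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  std_int <- table$intensity[std_rows, , drop = FALSE]
  if (any(std_int <= 0)) {
    bad <- colnames(std_int)[apply(std_int <= 0, 2L, any)]
    stop(sprintf("zero internal-standard intensity in sample(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  nmol <- standards$nmol[match(cls, standards$class)]
  amounts <- table$intensity[analyte, , drop = FALSE] / std_int * nmol
  structure(list(amounts = amounts,
                 species = table$species[analyte, , drop = FALSE],
                 samples = table$samples),
            class = "lipid_amounts")
}

#' Per-sample normalization of lipid amounts
#'
#' @param amounts A `lipid_amounts` object from [normalize_to_is()].
#' @param mode `"protein"` divides each sample by its protein amount
#'   (nmol per microgram protein); `"total_pool"` divides each species by the
#'   sample's summed amounts, so per-sample fractions sum to 1.
#' @return A `lipid_amounts` object on the normalized scale.
#' @export
normalize_sample <- function(amounts, mode = c("total_pool", "protein")) {
  stopifnot(inherits(amounts, "lipid_amounts"))
  mode <- match.arg(mode)
  m <- amounts$amounts
  if (mode == "protein") {
    prot <- amounts$samples$protein_ug
    if (is.null(prot) || anyNA(prot)) {
      stop("protein amounts (`protein_ug`) required for mode = 'protein'",
           call. = FALSE)
    }
    m <- sweep(m, 2L, prot, "/")
  } else {
    totals <- colSums(m)
    if (any(totals <= 0)) {
      stop("cannot form total-pool fractions: non-positive sample total",
           call. = FALSE)
    }
    m <- sweep(m, 2L, totals, "/")
  }
  out <- amounts
  out$amounts <- m
  out$normalization <- mode
  out
}

#' Relative class profiles
#'
#' Per-sample class sums divided by the sample's total lipid amount.
#'
#' @param amounts A `lipid_amounts` object.
#' @return Class x sample matrix of relative abundances (columns sum to 1).
#' @export
class_profiles <- function(amounts) {
  stopifnot(inherits(amounts, "lipid_amounts"))
  sums <- rowsum(amounts$amounts, group = amounts$species$class)
  sweep(sums, 2L, colSums(amounts$amounts), "/")
}

#' Differential lipid abundance between two groups
#'
#' Per species: log2 fold-change of group mean amounts (case over reference),
#' Welch two-sample t-test on log2 amounts, a significance tier over the raw
#' p thresholds 0.05 / 0.01 / 0.001 and a flag for `|log2FC| >= 2` -- the
#' volcano-plot annotation convention. Raw p values are used for the tiers;
#' a Benjamini-Hochberg FDR column is provided as an extra.
#'
#' @param amounts A `lipid_amounts` object with exactly two groups, each of
#'   size >= 2.
#' @param ref Reference group label; defaults to the first group level.
#' @return Data frame with columns `species`, `class`, `log2fc`, `p`, `fdr`,
#'   `tier` (`"ns"`, `"*"`, `"**"`, `"***"`) and `large_fc`.
#' @export
lipid_differential <- function(amounts, ref = NULL) {
  stopifnot(inherits(amounts, "lipid_amounts"))
  grp <- amounts$samples$group
  lv <- unique(grp)
  if (length(lv) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  if (is.null(ref)) ref <- lv[1L]
  stopifnot(ref %in% lv)
  alt <- setdiff(lv, ref)
  a_ref <- amounts$amounts[, grp == ref, drop = FALSE]
  a_alt <- amounts$amounts[, grp == alt, drop = FALSE]
  if (ncol(a_ref) < 2L || ncol(a_alt) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  if (any(amounts$amounts <= 0)) {
    stop("amounts must be positive for log2 testing", call. = FALSE)
  }
  n_sp <- nrow(amounts$amounts)
  log2fc <- log2(rowMeans(a_alt) / rowMeans(a_ref))
  p <- vapply(seq_len(n_sp), function(i) {
    x <- log2(a_alt[i, ])
    y <- log2(a_ref[i, ])
    if (stats::var(x) < 1e-24 && stats::var(y) < 1e-24) {
      return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
    }
    stats::t.test(x, y)$p.value
  }, numeric(1))
  tier <- cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
              labels = c("***", "**", "*", "ns"))
  data.frame(species = amounts$species$species,
             class = amounts$species$class,
             log2fc = log2fc,
             p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             tier = as.character(tier),
             large_fc = abs(log2fc) >= 2,
             row.names = NULL)
}

#' PLS-DA variable importance in projection
#'
#' Fits a partial-least-squares discriminant model by the NIPALS algorithm
#' (autoscaled predictors, centered +/-1 group response) and returns per
#' species the VIP score
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)`,
#' where `p` is the number of retained species, `w_a` the a-th weight vector
#' and `SSY_a` the response variance explained by component a. The mean
#' squared VIP equals 1 by construction, so VIP > 1 marks above-average
#' contributors.
#'
#' @param amounts A `lipid_amounts` object with exactly two groups.
#' @param ncomp Number of latent components (default 2; capped at the number
#'   of informative dimensions).
#' @return An object of class `vip_result`: list with `vip` (named numeric),
#'   `ncomp` (components actually used), `groups`, `dropped` (zero-variance
#'   species removed before autoscaling).
#' @export
vip_scores <- function(amounts, ncomp = 2L) {
  stopifnot(inherits(amounts, "lipid_amounts"), ncomp >= 1)
  grp <- amounts$samples$group
  lv <- unique(grp)
  if (length(lv) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  if (min(table(grp)) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  x <- t(amounts$amounts)                       # samples x species
  v <- apply(x, 2L, stats::var)
  dropped <- colnames(x)[v < 1e-24]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance species before autoscaling",
                    length(dropped)))
    x <- x[, v >= 1e-24, drop = FALSE]
  }
  if (ncol(x) == 0L) {
    stop("no species with non-zero variance", call. = FALSE)
  }
  x <- scale(x)
  y <- ifelse(grp == lv[2L], 1, -1)
  y <- y - mean(y)

  n_sp <- ncol(x)
  a_max <- min(ncomp, nrow(x) - 1L, n_sp)
  w_mat <- matrix(0, n_sp, a_max)
  ssy <- numeric(a_max)
  used <- 0L
  for (a in seq_len(a_max)) {
    w <- drop(crossprod(x, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- drop(x %*% w)
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_load <- drop(crossprod(x, t_sc)) / tt
    q <- sum(y * t_sc) / tt
    x <- x - tcrossprod(t_sc, p_load)
    y <- y - q * t_sc
    w_mat[, a] <- w
    ssy[a] <- q^2 * tt
    used <- a
  }
  if (used == 0L || sum(ssy) <= 0) {
    stop("PLS fit explained no response variance", call. = FALSE)
  }
  w_mat <- w_mat[, seq_len(used), drop = FALSE]
  ssy <- ssy[seq_len(used)]
  vip <- sqrt(n_sp * drop(w_mat^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(x)
  structure(list(vip = vip, ncomp = used, groups = lv, dropped = dropped),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("<vip_result> %d species, %d component(s); %d with VIP > 1\n",
              length(x$vip), x$ncomp, sum(x$vip > 1)))
  invisible(x)
}

#' Select species by VIP score and export a z-score matrix
#'
#' @param result A `vip_result` from [vip_scores()].
#' @param amounts The `lipid_amounts` object the scores were computed from.
#' @param threshold VIP cutoff; species with `VIP > threshold` are selected.
#' @return List with `species` (selected names, possibly empty) and
#'   `zscores`, the selected species x samples matrix standardized per
#'   species (mean 0, sd 1 across samples) for heatmap display.
#' @export
select_vip <- function(result, amounts, threshold = 1) {
  stopifnot(inherits(result, "vip_result"), inherits(amounts, "lipid_amounts"))
  sel <- names(result$vip)[result$vip > threshold]
  m <- amounts$amounts[sel, , drop = FALSE]
  z <- t(scale(t(m)))
  list(species = sel, zscores = z)
}
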