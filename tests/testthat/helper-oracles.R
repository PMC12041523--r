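# Independent oracles used across tests. These deliberately re-derive each
# quantity by a different route than the package implementation.

# Two-sided permutation p for the slope/correlation test: |r| is a monotone
# transform of |t|, so permuting y and comparing |r| gives the reference
# distribution of the slope test.
perm_slope_p <- function(x, y, B = 1e4, seed = 99) {
  set.seed(seed)
  xc <- x - mean(x)
  yc <- y - mean(y)
  r_obs <- abs(sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2)))
  yp <- replicate(B, sample(yc))
  r_perm <- abs(as.vector(crossprod(xc, yp)) /
                  sqrt(sum(xc^2) * colSums(yp^2)))
  (1 + sum(r_perm >= r_obs - 1e-12)) / (B + 1)
}

# Textbook NIPALS PLS1 + VIP, written as plain loops (no crossprod, no
# vectorized VIP formula) to stay independent of the package code path.
oracle_vip <- function(amount_matrix, groups, ncomp = 2) {
  x <- t(amount_matrix)
  x <- apply(x, 2, function(col) (col - mean(col)) / stats::sd(col))
  y <- ifelse(groups == unique(groups)[2], 1, -1)
  y <- y - mean(y)
  p <- ncol(x)
  ws <- list()
  ssy <- c()
  for (a in seq_len(ncomp)) {
    w <- numeric(p)
    for (j in seq_len(p)) w[j] <- sum(x[, j] * y)
    w <- w / sqrt(sum(w * w))
    t_sc <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) t_sc[i] <- sum(x[i, ] * w)
    tt <- sum(t_sc * t_sc)
    pl <- numeric(p)
    for (j in seq_len(p)) pl[j] <- sum(x[, j] * t_sc) / tt
    q <- sum(y * t_sc) / tt
    for (j in seq_len(p)) x[, j] <- x[, j] - t_sc * pl[j]
    y <- y - q * t_sc
    ws[[a]] <- w
    ssy[a] <- q * q * tt
  }
  vip <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_along(ws)) acc <- acc + ssy[a] * ws[[a]][j]^2
    vip[j] <- sqrt(p * acc / sum(ssy))
  }
  names(vip) <- rownames(amount_matrix)
  vip
}

# Brute-force masked statistics for ROI oracles.
masked_stat <- function(mat, coords, fun) {
  vals <- numeric(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    vals[i] <- mat[coords[i, 1], coords[i, 2]]
  }
  fun(vals)
}

# Small lipid table built by hand: one sample, chosen analyte/standard
# intensities, suitable for worked-example checks.
toy_lipid_table <- function(classes, analyte_int, standard_int,
                            standards = internal_standards()) {
  std <- standards[match(classes, standards$class), ]
  species <- c(paste0(classes, "(36:2)"), std$standard)
  intensity <- matrix(c(analyte_int, standard_int), ncol = 1,
                      dimnames = list(species, "s1"))
  lipid_table(intensity,
              species = data.frame(species = species,
                                   class = c(classes, std$class),
                                   is_standard = rep(c(FALSE, TRUE),
                                                     each = length(classes))),
              samples = data.frame(sample = "s1", group = "g",
                                   protein_ug = 100))
}
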