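test_that("internal-standard normalization reproduces the spiked amounts", {
  tab <- toy_lipid_table(c("PC", "TAG", "SM"),
                         analyte_int = c(5e5, 2.5e5, 5e5),
                         standard_int = c(5e5, 5e5, 5e5))
  am <- normalize_to_is(tab)
  # intensity ratio 1 to the PC standard -> the PC standard amount, 2 nmol
  expect_equal(unname(am$amounts["PC(36:2)", 1]), 2)
  # TAG analyte at half its standard's intensity -> 0.5 * 0.5 = 0.25 nmol
  expect_equal(unname(am$amounts["TAG(36:2)", 1]), 0.25)
  expect_equal(unname(am$amounts["SM(36:2)", 1]), 2.129)
  # zero intensity -> zero amount
  tab0 <- toy_lipid_table("PC", analyte_int = 0, standard_int = 5e5)
  expect_equal(unname(normalize_to_is(tab0)$amounts[1, 1]), 0)
})

test_that("normalization cancels any per-sample global gain and flags bad standards", {
  sim <- gen_lipid_table(lipid_sim_params(cv = 0.15, sample_gain_cv = 0.3,
                                          seed = 4))
  am <- normalize_to_is(sim$table)
  # gains differ across samples but amounts depend only on the seeded truth
  sim0 <- gen_lipid_table(lipid_sim_params(cv = 0.15, sample_gain_cv = 0,
                                           seed = 4))
  am0 <- normalize_to_is(sim0$table)
  expect_equal(am$amounts, am0$amounts, tolerance = 1e-10)

  # missing class standard is a coverage error
  std <- internal_standards()
  expect_error(normalize_to_is(sim$table,
                               standards = std[std$class != "TAG", ]),
               "no internal standard covers")
  # zero standard intensity is a per-sample error
  broken <- sim$table
  std_row <- which(broken$species$species == "PC(14:0)2")
  broken$intensity[std_row, 2] <- 0
  expect_error(normalize_to_is(broken), "zero internal-standard")
})

test_that("subclass aliases route ether lipids to the parent-class standard", {
  std <- internal_standards()
  species <- c("PC[O](34:1)", "PC(14:0)2")
  tab <- lipid_table(matrix(c(1e6, 5e5), ncol = 1,
                            dimnames = list(species, "s1")),
                     species = data.frame(species = species,
                                          class = c("PC[O]", "PC"),
                                          is_standard = c(FALSE, TRUE)),
                     samples = data.frame(sample = "s1", group = "g"))
  am <- normalize_to_is(tab)
  expect_equal(unname(am$amounts[1, 1]), 1e6 / 5e5 * 2)
})

test_that("noise-free simulated tables round-trip to the exact seeded amounts", {
  sim <- gen_lipid_table(lipid_sim_params(cv = 0, seed = 2))
  am <- normalize_to_is(sim$table)
  hd <- am$amounts[, am$samples$group == "HD"]
  expect_equal(unname(hd), matrix(sim$truth$species$nmol, nrow(hd), ncol(hd)),
               tolerance = 1e-12)
})

test_that("per-sample normalization conserves fractions and protein scaling", {
  sim <- gen_lipid_table(lipid_sim_params(cv = 0.2, seed = 6))
  am <- normalize_to_is(sim$table)
  pool <- normalize_sample(am, "total_pool")
  expect_equal(unname(colSums(pool$amounts)), rep(1, ncol(pool$amounts)),
               tolerance = 1e-12)
  # single-species sample -> fraction 1
  one <- am
  one$amounts <- am$amounts[1, , drop = FALSE]
  one$species <- am$species[1, , drop = FALSE]
  expect_true(all(normalize_sample(one, "total_pool")$amounts == 1))
  # doubling all intensities leaves total-pool output unchanged
  doubled <- sim$table
  doubled$intensity <- 2 * doubled$intensity
  pool2 <- normalize_sample(normalize_to_is(doubled), "total_pool")
  expect_equal(pool$amounts, pool2$amounts, tolerance = 1e-12)

  prot <- normalize_sample(am, "protein")
  expect_equal(prot$amounts, sweep(am$amounts, 2,
                                   am$samples$protein_ug, "/"))
  noprot <- am
  noprot$samples$protein_ug <- NULL
  expect_error(normalize_sample(noprot, "protein"), "protein")
})

test_that("class profiles equal a brute-force group-by and partition to 1", {
  sim <- gen_lipid_table(lipid_sim_params(cv = 0.25, seed = 8))
  am <- normalize_to_is(sim$table)
  cp <- class_profiles(am)
  expect_equal(unname(colSums(cp)), rep(1, ncol(cp)), tolerance = 1e-12)
  for (cl in unique(am$species$class)) {
    manual <- colSums(am$amounts[am$species$class == cl, , drop = FALSE]) /
      colSums(am$amounts)
    expect_equal(cp[cl, ], manual)
  }
  # degenerate partitions
  one <- am
  one$amounts <- am$amounts[am$species$class == "PC", ]
  one$species <- am$species[am$species$class == "PC", ]
  expect_true(all(abs(class_profiles(one) - 1) < 1e-12))
})

test_that("differential abundance flags seeded fold-changes at the volcano thresholds", {
  fc <- c("PC(32:1)" = 3)
  sim <- gen_lipid_table(lipid_sim_params(cv = 0.1, group_log2fc = fc,
                                          n_samples_per_group = 10, seed = 5))
  d <- lipid_differential(normalize_to_is(sim$table), ref = "HD")
  hit <- d[d$species == "PC(32:1)", ]
  expect_lt(abs(hit$log2fc - 3), 0.3)
  expect_lte(hit$p, 0.01)
  expect_true(hit$large_fc)
  expect_true(hit$tier %in% c("**", "***"))
  # identical groups: log2FC 0 and p 1
  sim0 <- gen_lipid_table(lipid_sim_params(cv = 0, seed = 3))
  d0 <- lipid_differential(normalize_to_is(sim0$table), ref = "HD")
  expect_true(all(d0$log2fc == 0))
  expect_true(all(d0$p == 1))
})

test_that("the Welch t statistic matches a textbook 3+3 computation", {
  species <- c("PC(34:2)", "PC(14:0)2")
  intensity <- rbind(c(10, 12, 11, 30, 28, 35) * 1e4,
                     rep(5e5, 6))
  dimnames(intensity) <- list(species, paste0("s", 1:6))
  tab <- lipid_table(intensity,
                     species = data.frame(species = species,
                                          class = c("PC", "PC"),
                                          is_standard = c(FALSE, TRUE)),
                     samples = data.frame(sample = paste0("s", 1:6),
                                          group = rep(c("HD", "CLL"),
                                                      each = 3)))
  am <- normalize_to_is(tab)
  d <- lipid_differential(am, ref = "HD")
  x <- log2(c(30, 28, 35) * 1e4 / 5e5 * 2)
  y <- log2(c(10, 12, 11) * 1e4 / 5e5 * 2)
  # Welch by hand
  se <- sqrt(var(x) / 3 + var(y) / 3)
  tt <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(d$p[1], 2 * pt(-abs(tt), df), tolerance = 1e-12)
  expect_equal(d$log2fc[1], log2(mean(c(30, 28, 35)) / mean(c(10, 12, 11))),
               tolerance = 1e-12)
})

test_that("VIP scores satisfy their normalization and symmetry identities", {
  # single informative predictor: VIP = 1 by construction
  species <- c("PC(34:2)", "PC(14:0)2")
  intensity <- rbind(c(1, 1.1, 4, 4.2) * 1e5, rep(5e5, 4))
  dimnames(intensity) <- list(species, paste0("s", 1:4))
  tab <- lipid_table(intensity,
                     species = data.frame(species = species,
                                          class = "PC",
                                          is_standard = c(FALSE, TRUE)),
                     samples = data.frame(sample = paste0("s", 1:4),
                                          group = rep(c("a", "b"), each = 2)))
  v1 <- vip_scores(normalize_to_is(tab))
  expect_equal(unname(v1$vip), 1)

  # two exchangeable noise-free predictors: both VIP exactly 1
  species2 <- c("PC(34:2)", "PC(36:2)", "PC(14:0)2")
  intensity2 <- rbind(c(1, 1, 4, 4) * 1e5, c(2, 2, 8, 8) * 1e5, rep(5e5, 4))
  dimnames(intensity2) <- list(species2, paste0("s", 1:4))
  tab2 <- lipid_table(intensity2,
                      species = data.frame(species = species2,
                                           class = "PC",
                                           is_standard = c(FALSE, FALSE,
                                                           TRUE)),
                      samples = data.frame(sample = paste0("s", 1:4),
                                           group = rep(c("a", "b"),
                                                       each = 2)))
  v2 <- vip_scores(normalize_to_is(tab2))
  expect_equal(unname(v2$vip), c(1, 1))

  # sum of squared VIP equals the species count on an arbitrary fit
  sim <- gen_lipid_table(lipid_sim_params(cv = 0.3, seed = 10))
  v3 <- vip_scores(normalize_to_is(sim$table))
  expect_equal(sum(v3$vip^2), length(v3$vip), tolerance = 1e-9)
})

test_that("VIP matches an independently coded NIPALS oracle", {
  set.seed(77)
  amounts <- matrix(rlnorm(8 * 10, 0, 0.5), nrow = 8,
                    dimnames = list(paste0("sp", 1:8), paste0("s", 1:10)))
  groups <- rep(c("HD", "CLL"), each = 5)
  species <- data.frame(species = paste0("sp", 1:8), class = "PC",
                        is_standard = FALSE)
  am <- structure(list(amounts = amounts, species = species,
                       samples = data.frame(sample = paste0("s", 1:10),
                                            group = groups)),
                  class = "lipid_amounts")
  v <- vip_scores(am, ncomp = 2)
  expect_equal(v$vip, oracle_vip(amounts, groups, ncomp = 2),
               tolerance = 1e-6)
})

test_that("VIP selection finds the seeded species and standardizes z-scores", {
  fc <- c("PC(32:1)" = 3, "TAG(34:2)" = -2.5)
  sim <- gen_lipid_table(lipid_sim_params(cv = 0.1, group_log2fc = fc,
                                          seed = 5))
  am <- normalize_to_is(sim$table)
  v <- vip_scores(am)
  sel <- select_vip(v, am)
  expect_true(all(names(fc) %in% sel$species))
  expect_identical(names(sort(v$vip, decreasing = TRUE)[1:2]),
                   c("TAG(34:2)", "PC(32:1)"))
  expect_true(all(abs(rowMeans(sel$zscores)) < 1e-12))
  expect_equal(unname(apply(sel$zscores, 1, sd)), rep(1, nrow(sel$zscores)))

  # noise-free limit: null species carry no variance and are dropped, and
  # the two surviving seeded species are exchangeable, so each VIP is
  # exactly 1 (the boundary of the > 1 cutoff); select against a threshold
  # marginally below 1 to assert the selection is exactly the seeded set
  sim0 <- gen_lipid_table(lipid_sim_params(cv = 0, group_log2fc = fc,
                                           seed = 6))
  am0 <- normalize_to_is(sim0$table)
  v0 <- suppressWarnings(vip_scores(am0))
  expect_equal(unname(v0$vip), rep(1, 2))
  sel0 <- select_vip(v0, am0, threshold = 1 - 1e-9)
  expect_setequal(sel0$species, names(fc))
  d0 <- lipid_differential(am0, ref = "HD")
  flagged <- d0$species[d0$p <= 0.01 & abs(d0$log2fc) >= 2]
  expect_true(all(flagged %in% sel0$species))

  # an all-null fit selects nothing at a high threshold
  expect_identical(select_vip(v, am, threshold = Inf)$species, character(0))
})
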