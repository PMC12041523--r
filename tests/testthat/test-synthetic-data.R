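test_that("generators are bit-identical under a repeated seed", {
  p1 <- coloc_sim_params(n_cells = 6, field_shape = c(128, 128), seed = 11)
  expect_identical(gen_coloc_field(p1), gen_coloc_field(p1))
  p2 <- raft_sim_params(n_cells = 6, field_shape = c(128, 128), seed = 11)
  expect_identical(gen_raft_field(p2), gen_raft_field(p2))
  p3 <- ctv_sim_params(n_events = 500, seed = 11)
  expect_identical(gen_ctv_events(p3), gen_ctv_events(p3))
  p4 <- lipid_sim_params(seed = 11)
  expect_identical(gen_lipid_table(p4), gen_lipid_table(p4))
})

test_that("empty coloc field is pure background with empty ground truth", {
  sim <- gen_coloc_field(coloc_sim_params(n_cells = 0,
                                          field_shape = c(64, 64),
                                          shot_noise = FALSE,
                                          read_noise_sd = 0, psf_sigma = 0))
  expect_equal(nrow(sim$truth$cells), 0)
  for (ch in names(sim$image$channels)) {
    expect_true(all(channel(sim$image, ch) == 100))
  }
})

test_that("noise-free coupled cells obey the exact PLIN2 = slope*Bodipy + bg identity", {
  sim <- gen_coloc_field(coloc_sim_params(n_cells = 8,
                                          field_shape = c(256, 256),
                                          coloc_fraction = 1,
                                          coupling_slope = 0.8,
                                          psf_sigma = 0,
                                          shot_noise = FALSE,
                                          read_noise_sd = 0, seed = 4))
  bod <- channel(sim$image, "bodipy")
  pl <- channel(sim$image, "plin2")
  for (i in seq_len(8)) {
    px <- sim$truth$aggregate_pixels[[i]]
    expect_equal(pl[px], 0.8 * bod[px] + 100)
  }
  # uncoupled control: PLIN2 stays at background on aggregate pixels
  sim0 <- gen_coloc_field(coloc_sim_params(n_cells = 8,
                                           field_shape = c(256, 256),
                                           coloc_fraction = 0,
                                           psf_sigma = 0,
                                           shot_noise = FALSE,
                                           read_noise_sd = 0, seed = 4))
  pl0 <- channel(sim0$image, "plin2")
  expect_true(all(pl0 == 100))
})

test_that("coupled-cell fraction falls in the exact binomial 99% interval", {
  sim <- gen_coloc_field(coloc_sim_params(n_cells = 200,
                                          field_shape = c(1024, 1024),
                                          coloc_fraction = 0.7, seed = 1))
  n_coupled <- sum(sim$truth$cells$coupled)
  lo <- qbinom(0.005, 200, 0.7)
  hi <- qbinom(0.995, 200, 0.7)
  expect_gte(n_coupled, lo)
  expect_lte(n_coupled, hi)
  # conservation: ground-truth flags count the coupled cells exactly
  expect_identical(n_coupled, sum(sim$truth$cells$coupled))
})

test_that("pre-noise intensities scale exactly with the channel gains", {
  # psf off so pre-noise values stay integer: 16-bit quantization would
  # otherwise round(2x) vs 2*round(x) apart by one count
  base <- list(n_cells = 6, field_shape = c(160, 160), psf_sigma = 0,
               shot_noise = FALSE, read_noise_sd = 0, seed = 9)
  s1 <- gen_coloc_field(do.call(coloc_sim_params,
                                c(base, membrane_intensity = 400,
                                  aggregate_intensity = 150,
                                  background = 100)))
  s2 <- gen_coloc_field(do.call(coloc_sim_params,
                                c(base, membrane_intensity = 800,
                                  aggregate_intensity = 300,
                                  background = 200)))
  for (ch in c("membrane", "bodipy", "plin2")) {
    expect_identical(channel(s2$image, ch), 2 * channel(s1$image, ch))
  }
})

test_that("raft field with no puncta is background-only in the CT-B channel", {
  sim <- gen_raft_field(raft_sim_params(n_cells = 5, field_shape = c(128, 128),
                                        puncta_per_cell = 0,
                                        shot_noise = FALSE,
                                        read_noise_sd = 0, psf_sigma = 1))
  expect_true(all(channel(sim$image, "ctb") == 100))
})

test_that("fully clustered puncta stay within one arc of the configured width", {
  sim <- gen_raft_field(raft_sim_params(n_cells = 20, field_shape = c(256, 256),
                                        clustering = 1, arc_width = pi / 8,
                                        seed = 21))
  expect_equal(sim$truth$arc_width_used, pi / 8)
  for (pts in sim$truth$puncta) {
    ang <- sort(pts[, "angle"])
    # largest gap around the circle must leave the rest within arc_width
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    expect_lte(2 * pi - max(gaps), pi / 8 + 1e-9)
  }
})

test_that("ctv: degenerate fraction vectors are rejected, single generation recovered", {
  expect_error(ctv_sim_params(generation_fractions = c(0.6, 0.5)),
               "sum to 1")
  expect_error(ctv_sim_params(generation_fractions = c(0.5, 0.5),
                              dilution_per_division = 1), "exceed 1")
  sim <- gen_ctv_events(ctv_sim_params(n_events = 5000,
                                       generation_fractions = 1,
                                       autofluorescence_floor = 0, seed = 3))
  expect_true(all(sim$truth$generation == 0))
  expect_equal(mean(log10(sim$events$ctv)), 4, tolerance = 0.01)
})

test_that("ctv: the zero-width limit gives exactly two intensities at ratio 2", {
  sim <- gen_ctv_events(ctv_sim_params(n_events = 1000,
                                       generation_fractions = c(0.5, 0.5),
                                       log10_sd = 0,
                                       autofluorescence_floor = 0, seed = 5))
  vals <- sort(unique(sim$events$ctv))
  expect_length(vals, 2)
  expect_equal(vals[2] / vals[1], 2)
})

test_that("lipid generator: cv = 0 makes the two groups identical", {
  sim <- gen_lipid_table(lipid_sim_params(cv = 0, seed = 2))
  tab <- sim$table
  g <- tab$samples$group
  a <- tab$intensity[, g == "HD", drop = FALSE]
  b <- tab$intensity[, g == "CLL", drop = FALSE]
  expect_equal(unname(a), unname(b))
})

test_that("lipid generator rejects species in classes without a standard", {
  expect_error(lipid_sim_params(classes = c("PC", "NOTACLASS")),
               "unknown class")
})
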