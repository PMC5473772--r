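# Synthetic microscopy generator: populations, rendering, ground truth

test_that("construct regimes set photon budgets as designed", {
  empty <- sample_population(20, "EMPTY", seed = 1)
  expect_true(all(empty$cells$focus_photons == 0))
  expect_true(all(empty$cells$diffuse_level == 0))
  expect_equal(nrow(empty$foci), 0L)

  # split construct without an array: no reconstitution sites, no foci
  occ0 <- occupancy_params(n_arrays = 0)
  split0 <- sample_population(20, "SPLIT", occupancy = occ0, seed = 2)
  expect_true(all(split0$cells$focus_photons == 0))
  expect_equal(nrow(split0$foci), 0L)

  # with an array, each cell carries one focus per array copy
  occ2 <- occupancy_params(n_arrays = 2)
  split2 <- sample_population(20, "SPLIT", occupancy = occ2, seed = 3)
  expect_equal(nrow(split2$foci), 40L)
  expect_true(all(split2$cells$focus_photons > 0))
})

test_that("per-cell focus brightness saturates at the site capacity", {
  occ <- occupancy_params(pool_size = 1e6, affinity = 100)
  pop <- sample_population(50, "SPLIT", occupancy = occ, seed = 4,
                           brightness_per_fluorophore = 10)
  # even with huge expression noise, bound counts cannot exceed 64 sites
  expect_true(all(pop$cells$focus_photons <= 64 * 10 + 1e-6))
})

test_that("sampled cell areas match an independently simulated distribution", {
  ad <- area_distribution()
  pop <- do.call(rbind, lapply(1:13, function(k) {
    sample_population(80, "EMPTY", seed = 100 + k,
                      area_distribution = ad)$cells
  }))
  # independent oracle: same truncation rules, plain base R draws
  set.seed(999)
  n_oracle <- 20000
  len <- pmin(pmax(rnorm(n_oracle, ad$length_mean, ad$length_sd),
                   ad$min_length), ad$length_mean + 4 * ad$length_sd)
  wid <- pmin(pmax(rnorm(n_oracle, ad$width_mean, ad$width_sd),
                   ad$width_mean - 2), ad$width_mean + 2)
  oracle_area <- wid * (len - wid) + pi * (wid / 2)^2
  se <- sqrt(var(pop$area) / nrow(pop) + var(oracle_area) / n_oracle)
  expect_lt(abs(mean(pop$area) - mean(oracle_area)), 3 * se)
})

test_that("rasterized capsule areas track the analytic rod geometry", {
  pop <- sample_population(40, "EMPTY", seed = 5)
  img <- render_image(pop, optics_noise_config(seed = 5), noise = FALSE)
  expect_true(all(abs(img$truth$area_px - img$truth$area) /
                    img$truth$area < 0.10))
})

test_that("rendering is deterministic given the seed", {
  pop <- sample_population(10, "SPLIT", seed = 6)
  i1 <- render_image(pop, optics_noise_config(seed = 6))
  i2 <- render_image(pop, optics_noise_config(seed = 6))
  expect_identical(i1$pixels, i2$pixels)
  i3 <- render_image(pop, optics_noise_config(seed = 7))
  expect_false(identical(i1$pixels, i3$pixels))

  p1 <- sample_population(10, "SPLIT", seed = 8)
  p2 <- sample_population(10, "SPLIT", seed = 8)
  expect_identical(p1$cells, p2$cells)
})

test_that("a dark field renders all-zero without noise or offset", {
  pop <- sample_population(5, "EMPTY", seed = 9, autofluorescence = 0)
  img <- render_image(pop, optics_noise_config(offset = 0, seed = 1),
                      noise = FALSE)
  expect_true(all(img$pixels == 0L))
})

test_that("the noise-free renderer conserves photons", {
  pop <- sample_population(30, "SPLIT", seed = 10)
  cfg <- optics_noise_config(seed = 10)
  img <- render_image(pop, cfg, noise = FALSE)
  total_photons <- sum((pop$cells$diffuse_level + pop$cells$autofluorescence) *
                         img$truth$area_px) + sum(pop$foci$photons)
  expected_total <- cfg$gain * total_photons +
    cfg$offset * length(img$pixels)
  expect_equal(sum(img$expected_counts), expected_total, tolerance = 1e-9)

  # per-cell integral of the quantized plane: diffuse + focus budget,
  # within 1% PSF edge leakage
  for (i in sample(nrow(pop$cells), 10)) {
    sel <- img$label_mask == i
    got <- sum(img$pixels[sel]) - cfg$offset * sum(sel)
    want <- cfg$gain *
      ((pop$cells$diffuse_level[i] + pop$cells$autofluorescence[i]) *
         sum(sel) + pop$cells$focus_photons[i] * pop$cells$n_arrays[i])
    expect_lt(abs(got - want) / want, 0.01)
  }
})

test_that("ground truth is coherent: contiguous labels, foci inside cells", {
  pop <- sample_population(25, "SPLIT", seed = 11)
  img <- render_image(pop, optics_noise_config(seed = 11))
  labs <- sort(unique(as.vector(img$label_mask)))
  expect_equal(labs, 0:25)
  expect_equal(nrow(img$truth), 25L)
  for (j in seq_len(nrow(img$foci))) {
    expect_equal(img$label_mask[round(img$foci$y[j]), round(img$foci$x[j])],
                 img$foci$cell_id[j])
  }
})

test_that("splitting the fluorophore collapses whole-cell fluorescence", {
  full <- simulate_regime("FULL_LENGTH", 0L, 80, seed = 21)
  split <- simulate_regime("SPLIT", 0L, 80, seed = 22)
  expect_gte(mean(full$quants$mean_intensity) /
               mean(split$quants$mean_intensity), 5)
})

test_that("overcrowded fields are rejected with a clear error", {
  expect_error(sample_population(500, "EMPTY", seed = 1,
                                 frame_dim = c(256L, 256L)),
               "placement failed")
})

test_that("images, masks and truth tables survive a disk round-trip", {
  pop <- sample_population(8, "SPLIT", seed = 12)
  img <- render_image(pop, optics_noise_config(seed = 12))
  prefix <- file.path(tempdir(), "roundtrip")
  paths <- write_synthetic_image(img, prefix)
  expect_identical(read_count_tiff(paths["image"]), img$pixels)
  expect_identical(read_count_tiff(paths["mask"]), img$label_mask)
  truth <- read.csv(paths["truth"])
  expect_equal(nrow(truth), 8L)
})
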