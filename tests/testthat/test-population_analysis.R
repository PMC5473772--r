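# Area binning, control subtraction, regression, fold change

test_that("area bins drop groups with fewer than the minimum cells", {
  q <- make_quants(area = c(rep(105, 9), rep(205, 12)),
                   mean_intensity = c(rep(50, 9), rep(80, 12)))
  bins <- bin_by_area(q, window = 10, min_cells = 10)
  expect_equal(nrow(bins), 1L)          # the 9-cell group is excluded
  expect_equal(bins$bin_lower, 200)
  expect_equal(bins$mean_intensity, 80)
  expect_equal(bins$n_cells, 12L)

  same <- make_quants(area = rep(150, 30), mean_intensity = rep(42, 30))
  b1 <- bin_by_area(same)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$mean_intensity, 42)
})

test_that("disjoint bin means equal a brute-force grouping oracle", {
  set.seed(21)
  q <- make_quants(area = runif(400, 100, 400),
                   mean_intensity = runif(400, 0, 1000))
  bins <- bin_by_area(q, window = 10, min_cells = 10)
  oracle <- tapply(q$mean_intensity, floor(q$area / 10) * 10, mean)
  sizes <- tapply(q$mean_intensity, floor(q$area / 10) * 10, length)
  oracle <- oracle[sizes >= 10]
  expect_equal(bins$bin_lower, as.numeric(names(oracle)))
  expect_equal(bins$mean_intensity, as.vector(oracle))
})

test_that("sliding windows step by one pixel and overlap", {
  set.seed(22)
  q <- make_quants(area = runif(300, 100, 130),
                   mean_intensity = runif(300, 0, 10))
  sl <- bin_by_area(q, window = 10, min_cells = 10, mode = "sliding")
  expect_true(all(diff(sl$bin_lower) == 1))
  # every sliding mean is reproducible by direct selection
  k <- sample(nrow(sl), 5)
  for (i in k) {
    sel <- q$area >= sl$bin_lower[i] & q$area < sl$bin_upper[i]
    expect_equal(sl$mean_intensity[i], mean(q$mean_intensity[sel]))
  }
})

test_that("control subtraction shifts by the control grand mean and clamps", {
  ctrl <- make_quants(area = rep(100, 20), mean_intensity = rep(100, 20))
  test <- make_quants(area = rep(100, 3),
                      mean_intensity = c(350, 100, 40))
  adj <- subtract_control(test, ctrl)
  expect_equal(adj$mean_intensity, c(250, 0, 0))
  expect_equal(adj$clamped, c(FALSE, FALSE, TRUE))
  # clamped count equals an independent count of cells below the control mean
  set.seed(23)
  big <- make_quants(area = rep(100, 200),
                     mean_intensity = runif(200, 0, 300))
  adj2 <- subtract_control(big, ctrl)
  expect_equal(sum(adj2$clamped), sum(big$mean_intensity < 100))
  # a uniform population subtracted from itself is exactly zero
  selfed <- subtract_control(ctrl, ctrl)
  expect_true(all(selfed$mean_intensity == 0))
  expect_error(subtract_control(test, ctrl[0, ]), "empty")
})

test_that("regression recovers exact lines and matches the closed form", {
  x <- seq(100, 2000, length.out = 25)
  q <- make_quants(area = rep(100, 25), mean_intensity = x,
                   signal = x, background = 0.2 * x + 50)
  r <- regress_signal_vs_background(q)
  expect_equal(r$slope, 0.2, tolerance = 1e-12)
  expect_equal(r$intercept, 50, tolerance = 1e-9)
  expect_equal(r$n_points, 25L)

  set.seed(24)
  q2 <- make_quants(area = rep(100, 20), mean_intensity = runif(20),
                    signal = runif(20, 0, 60000),
                    background = runif(20, 0, 14000))
  r2 <- regress_signal_vs_background(q2)
  cf <- ols_closed_form(q2$signal, q2$background)
  expect_equal(r2$slope, cf$slope, tolerance = 1e-9)
  expect_equal(r2$intercept, cf$intercept, tolerance = 1e-9)
})

test_that("axis caps exclude cells and can exhaust the data", {
  q <- make_quants(area = rep(100, 5), mean_intensity = 1:5,
                   signal = rep(70000, 5), background = rep(100, 5))
  expect_error(regress_signal_vs_background(q), "survive the axis caps")
  mixed <- make_quants(area = rep(100, 6), mean_intensity = 1:6,
                       signal = c(1000, 2000, 3000, 70000, 4000, 5000),
                       background = c(100, 120, 90, 100, 16000, 130))
  r <- regress_signal_vs_background(mixed)
  expect_equal(r$n_points, 4L)  # one x-capped, one y-capped
})

test_that("fold change is 1 for identical strains and 2 for doubled signal", {
  a <- make_quants(area = rep(100, 50), mean_intensity = runif(50, 100, 300))
  expect_equal(estimate_fold_change(a, a)$fold, 1)
  b <- a
  b$mean_intensity <- 2 * a$mean_intensity
  expect_equal(estimate_fold_change(a, b)$fold, 2)
})

test_that("a zero-mean control leaves the fold estimate unchanged", {
  set.seed(25)
  a <- make_quants(area = rep(100, 40), mean_intensity = runif(40, 200, 400))
  b <- make_quants(area = rep(100, 40), mean_intensity = runif(40, 500, 700))
  zero_ctrl <- make_quants(area = rep(100, 10), mean_intensity = rep(0, 10))
  expect_equal(estimate_fold_change(a, b, control = zero_ctrl)$fold,
               estimate_fold_change(a, b)$fold)
})

test_that("the brightest-half subset selects the top 50% by mean intensity", {
  a <- make_quants(area = rep(100, 10), mean_intensity = 1:10 * 10)
  fc <- estimate_fold_change(a, a, subset_fraction = 0.5)
  expect_equal(fc$n_a, 5L)
  expect_equal(fc$denominator_mean, mean(c(60, 70, 80, 90, 100)))
  expect_equal(fc$fold, 1)
  expect_error(estimate_fold_change(a[0, ], a), "empty")
})

test_that("full-length and split regimes separate by regression slope", {
  fa <- simulate_regime("FULL_LENGTH", 1L, 100, seed = 61)
  sa <- simulate_regime("SPLIT", 1L, 100, seed = 61)
  slope_full <- regress_signal_vs_background(fa$quants)$slope
  slope_split <- regress_signal_vs_background(sa$quants)$slope
  expect_gt(slope_full, slope_split)
})
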