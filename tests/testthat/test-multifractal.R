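test_that("measure maps have closed forms on constant images", {
  x <- matrix(0.4, 9, 9)
  cfgs <- lapply(c("maximum", "inverse_minimum", "summation", "iso"),
                 mf_config)
  names(cfgs) <- c("maximum", "inverse_minimum", "summation", "iso")
  expect_equal(compute_measure_map(x, 3, cfgs$maximum), matrix(0.4, 9, 9))
  expect_equal(compute_measure_map(x, 1, cfgs$inverse_minimum),
               matrix(0.6, 9, 9))
  expect_equal(compute_measure_map(x, 5, cfgs$inverse_minimum),
               matrix(0.6, 9, 9))
  expect_equal(compute_measure_map(x, 5, cfgs$iso), matrix(25, 9, 9))
  expect_equal(compute_measure_map(x, 3, cfgs$summation),
               matrix(3.6, 9, 9), tolerance = 1e-12)
  expect_error(compute_measure_map(x, 4, cfgs$maximum), "odd")
})

test_that("vectorized measure maps equal the brute-force window oracle", {
  withr::local_seed(11)
  for (rep in 1:2) {
    x <- matrix(sample(0:255, 81, replace = TRUE) / 255, 9, 9)
    for (ms in c("maximum", "inverse_minimum", "summation", "iso")) {
      cfg <- mf_config(ms)
      for (w in c(1, 3, 5)) {
        expect_equal(compute_measure_map(x, w, cfg),
                     oracle_measure_map(x, w, ms, cfg$iso_tolerance),
                     tolerance = 1e-12,
                     label = sprintf("%s w=%d", ms, w))
      }
    }
  }
})

test_that("iso measure values are integers in [1, w^2]", {
  withr::local_seed(12)
  x <- matrix(runif(144), 12, 12)
  cfg <- mf_config("iso")
  for (w in c(1, 3, 5)) {
    m <- compute_measure_map(x, w, cfg)
    expect_true(all(m == round(m)))
    expect_true(all(m >= 1) && all(m <= w^2))
  }
})

test_that("alpha estimation is exact on flat and power-law measure stacks", {
  ww <- c(1, 3, 5)
  flat <- lapply(ww, function(w) matrix(2, 3, 3))
  expect_equal(estimate_alpha(flat, ww)$alpha, matrix(0, 3, 3),
               tolerance = 1e-12)
  squares <- lapply(ww, function(w) matrix(w^2, 3, 3))
  expect_equal(estimate_alpha(squares, ww)$alpha, matrix(2, 3, 3),
               tolerance = 1e-12)
  expect_error(estimate_alpha(flat[1], 1), ">= 2")

  # arbitrary positive measures against an independent regression
  mu <- c(2, 5, 11)
  st <- lapply(mu, function(m) matrix(m, 2, 2))
  ab <- oracle_loglog_fit(mu, ww)
  est <- estimate_alpha(st, ww)
  expect_equal(est$alpha[1, 1], ab[2], tolerance = 1e-10)
  expect_equal(est$intercept[1, 1], ab[1], tolerance = 1e-10)
})

test_that("constant images give the analytic alpha limits exactly", {
  x <- matrix(0.4, 16, 16)
  lim <- c(maximum = 0, inverse_minimum = 0, iso = 2, summation = 2)
  for (ms in names(lim)) {
    ai <- alpha_image(x, mf_config(ms), normalize = FALSE)
    expect_equal(ai$alpha, matrix(lim[[ms]], 16, 16), tolerance = 1e-12,
                 label = ms)
  }
})

test_that("rough fBm textures shift the mean alpha consistently across seeds", {
  cfg <- mf_config("maximum")
  d <- vapply(1:10, function(i) {
    a <- alpha_image(generate_fbm_texture(0.2, c(48, 48), seed = 200 + i),
                     cfg, normalize = FALSE)
    b <- alpha_image(generate_fbm_texture(0.8, c(48, 48), seed = 200 + i),
                     cfg, normalize = FALSE)
    mean(a$alpha) - mean(b$alpha)
  }, numeric(1))
  expect_true(all(d > 0) || all(d < 0))
})

test_that("alpha-histograms conserve mass and match a counting oracle", {
  # constant alpha map: all mass in one bin
  const <- alpha_histogram(matrix(1.5, 8, 8), matrix(TRUE, 8, 8), 100)
  expect_equal(const$heights[1], 1)
  expect_equal(sum(const$heights), 1)

  # linear ramp over a rectangular ROI vs direct bin counting
  amap <- matrix(seq(0, 1, length.out = 120), 10, 12)
  mask <- matrix(FALSE, 10, 12); mask[3:8, 2:11] <- TRUE
  h <- alpha_histogram(amap, mask, 10)
  v <- amap[mask]
  lo <- min(v); hi <- max(v)
  counts <- vapply(1:10, function(b) {
    lo_b <- lo + (b - 1) / 10 * (hi - lo)
    hi_b <- lo + b / 10 * (hi - lo)
    if (b < 10) sum(v >= lo_b & v < hi_b) else sum(v >= lo_b & v <= hi_b)
  }, numeric(1))
  expect_equal(h$heights, counts / sum(counts), tolerance = 1e-12)
  expect_equal(h$roi_pixel_count, sum(mask))
  expect_error(alpha_histogram(amap, matrix(FALSE, 10, 12)), "empty")

  # conservation over random cases
  withr::local_seed(13)
  for (i in 1:5) {
    amap <- matrix(rnorm(64), 8, 8)
    mask <- matrix(runif(64) < 0.6, 8, 8)
    if (!any(mask)) next
    expect_equal(sum(alpha_histogram(amap, mask, 100)$heights), 1,
                 tolerance = 1e-9)
  }
})

test_that("pixels beyond the window radius cannot change ROI histograms", {
  withr::local_seed(14)
  x <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(FALSE, 32, 32); mask[12:20, 12:20] <- TRUE
  cfg <- mf_config("iso")
  h1 <- alpha_histogram(alpha_image(x, cfg, normalize = FALSE), mask, 50)
  x2 <- x
  x2[1:5, ] <- runif(5 * 32)  # farther than max(w)/2 = 2 px from the ROI
  x2[, 28:32] <- runif(5 * 32)
  h2 <- alpha_histogram(alpha_image(x2, cfg, normalize = FALSE), mask, 50)
  expect_equal(h1$heights, h2$heights)
  expect_equal(h1$range, h2$range)
})

test_that("invalid multifractal configurations are rejected", {
  expect_error(mf_config(window_sizes = c(2, 4)), "odd")
  expect_error(mf_config(window_sizes = 3), ">= 2")
  expect_error(mf_config(window_sizes = c(5, 3)), "increasing")
  expect_error(mf_config(iso_tolerance = -1), "iso_tolerance")
  expect_error(mf_config(n_bins = 1), "n_bins")
})
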