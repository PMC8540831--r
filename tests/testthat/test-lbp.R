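test_that("LBP codes on flat and peaked neighbourhoods follow the sign rule", {
  # all differences zero and s(0) = 1: every bit set
  expect_equal(lbp_code_map(matrix(0.3, 7, 7), P = 8, R = 1),
               matrix(255, 7, 7))
  # centre strictly above all neighbours: code 0
  x <- matrix(0, 7, 7); x[4, 4] <- 1
  expect_equal(lbp_code_map(x, P = 8, R = 1)[4, 4], 0)
  expect_error(lbp_code_map(x, P = 2, R = 1), "P must be")
})

test_that("circular and elliptical code maps match the per-pixel oracle", {
  withr::local_seed(21)
  for (rep in 1:2) {
    x <- matrix(sample(0:255, 49, replace = TRUE) / 255, 7, 7)
    expect_equal(lbp_code_map(x, P = 8, R = 1),
                 oracle_code_map(x, 8, 1, 1), tolerance = 0)
    expect_equal(lbp_code_map(x, P = 8, R = 2),
                 oracle_code_map(x, 8, 2, 2), tolerance = 0)
    expect_equal(elbp_code_map(x, P = 8, R1 = 1, R2 = 4),
                 oracle_code_map(x, 8, 1, 4), tolerance = 0)
  }
})

test_that("a circle is the degenerate ellipse", {
  withr::local_seed(22)
  x <- matrix(runif(100), 10, 10)
  expect_identical(elbp_code_map(x, P = 8, R1 = 2, R2 = 2),
                   lbp_code_map(x, P = 8, R = 2))
})

test_that("code histograms are ROI proportions matching a direct tally", {
  withr::local_seed(23)
  x <- matrix(runif(144), 12, 12)
  cm <- lbp_code_map(x, P = 8, R = 1)
  mask <- matrix(runif(144) < 0.7, 12, 12)
  h <- code_histogram(cm, mask, P = 8)
  expect_length(h, 256)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(h, oracle_code_histogram(cm, mask, 8), tolerance = 1e-12)
  expect_error(code_histogram(cm, matrix(FALSE, 12, 12), 8), "empty")

  hc <- code_histogram(lbp_code_map(matrix(0.5, 8, 8), 8, 1),
                       matrix(TRUE, 8, 8), 8)
  expect_equal(hc[256], 1)  # code 255 is the last bin
})

test_that("MLBP concatenates per-radius histograms, each summing to 1", {
  withr::local_seed(24)
  x <- matrix(runif(400), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  d <- mlbp_descriptor(x, mask, radii = c(2, 4), P = 8)
  expect_length(d, 512)
  h2 <- code_histogram(lbp_code_map(x, 8, 2), mask, 8)
  h4 <- code_histogram(lbp_code_map(x, 8, 4), mask, 8)
  expect_equal(unname(d), c(h2, h4))
  expect_equal(sum(d[1:256]), 1, tolerance = 1e-9)
  expect_equal(sum(d[257:512]), 1, tolerance = 1e-9)
  expect_error(mlbp_descriptor(x, mask, radii = c(4, 2)), "increasing")
})

test_that("code maps are invariant to monotone and shift transforms", {
  withr::local_seed(25)
  x <- matrix(sample(0:99, 81, replace = TRUE) / 99, 9, 9)
  base_l <- lbp_code_map(x, 8, 2)
  base_e <- elbp_code_map(x, 8, 1, 4)
  # strictly increasing transform (interpolation is order-preserving on
  # quantized inputs only if applied to the codes' comparisons, so use an
  # affine monotone map, which commutes with bilinear interpolation)
  expect_equal(lbp_code_map(0.25 + 0.5 * x, 8, 2), base_l)
  expect_equal(elbp_code_map(0.25 + 0.5 * x, 8, 1, 4), base_e)
  expect_equal(lbp_code_map(x + 0.17, 8, 2), base_l)
})
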