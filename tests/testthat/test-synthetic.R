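test_that("phantoms land in their class density band and are deterministic", {
  s1 <- generate_phantom(phantom_spec("I", seed = 1))
  expect_gte(s1$realized_dense_fraction, 0)
  expect_lte(s1$realized_dense_fraction, 0.25)

  s1b <- generate_phantom(phantom_spec("I", seed = 1))
  expect_identical(s1$image$pixels, s1b$image$pixels)
  expect_identical(s1$breast_mask, s1b$breast_mask)

  # all classes, band membership asserted per sample
  for (cl in c("I", "II", "III", "IV")) {
    s <- generate_phantom(phantom_spec(cl, seed = 3))
    band <- density_band(cl)
    expect_gte(s$realized_dense_fraction, band[1])
    expect_lte(s$realized_dense_fraction, band[2])
    expect_false(any(s$breast_mask & s$pectoral_mask))
    expect_identical(dim(s$breast_mask), dim(s$image$pixels))
  }
})

test_that("class IV dense fraction verified by an independent pixel count", {
  s <- generate_phantom(phantom_spec("IV", seed = 7, noise_sd = 0))
  # recount above-threshold breast pixels directly from the saved image
  x <- s$image$pixels / 65535
  frac <- sum(x[s$breast_mask] > 0.6) / sum(s$breast_mask)
  expect_gt(frac, 0.75)
  expect_equal(frac, s$realized_dense_fraction, tolerance = 1e-3)
})

test_that("CC phantoms carry no pectoral region; tiny images are rejected", {
  s <- generate_phantom(phantom_spec("II", view = "CC", seed = 2))
  expect_false(any(s$pectoral_mask))
  expect_error(phantom_spec("I", image_size = c(32, 32)), "64")
})

test_that("fBm textures are deterministic, unit-range, and rougher at low Hurst", {
  f1 <- generate_fbm_texture(0.5, c(64, 64), seed = 3)
  f2 <- generate_fbm_texture(0.5, c(64, 64), seed = 3)
  expect_identical(f1, f2)
  expect_equal(min(f1), 0)
  expect_equal(max(f1), 1)
  expect_error(generate_fbm_texture(1.2, c(64, 64)), "hurst")

  # increment-scaling oracle: mean |lag-1 increment| larger for H = 0.2
  rough <- smooth <- numeric(8)
  for (i in seq_len(8)) {
    a <- generate_fbm_texture(0.2, c(64, 64), seed = 100 + i)
    b <- generate_fbm_texture(0.8, c(64, 64), seed = 100 + i)
    rough[i] <- mean(abs(diff(as.vector(a))))
    smooth[i] <- mean(abs(diff(as.vector(b))))
  }
  expect_true(all(rough > smooth))
})

test_that("generated datasets are balanced with a complete manifest", {
  ds <- generate_dataset(5, base_seed = 11,
                         spec_defaults = phantom_spec(image_size = c(64, 96)))
  expect_length(ds$samples, 20)
  expect_equal(nrow(ds$manifest), 20)
  expect_equal(unname(table(ds$manifest$label)), rep(5L, 4),
               ignore_attr = TRUE)
  fr <- ds$manifest$dense_fraction
  for (i in seq_len(20)) {
    band <- density_band(ds$manifest$label[i])
    expect_true(fr[i] >= band[1] && fr[i] <= band[2])
  }
})

test_that("mean breast intensity is non-decreasing from class I to IV", {
  means <- vapply(c("I", "II", "III", "IV"), function(cl) {
    m <- vapply(1:20, function(j) {
      s <- generate_phantom(phantom_spec(cl, image_size = c(64, 96),
                                         seed = 500 + j, noise_sd = 0.01))
      mean(s$image$pixels[s$breast_mask])
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
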