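test_that("contrast conversion follows (I - I0)/I0 and rejects degenerate input", {
  expect_equal(intensity_to_contrast(matrix(5, 3, 4)),
               matrix(0, 3, 4))
  img <- matrix(c(0.5, 1.5), 2, 2) # intensities I0/2 and 3 I0/2
  expect_equal(intensity_to_contrast(img), matrix(c(-0.5, 0.5), 2, 2))
  rnd <- withr::with_seed(1, matrix(runif(200, 0.1, 5), 10, 20))
  expect_equal(mean(intensity_to_contrast(rnd)), 0, tolerance = 1e-12)
  expect_error(intensity_to_contrast(matrix(0, 3, 3)), "zero mean")
  expect_error(intensity_to_contrast(matrix(-1, 2, 2)), "nonnegative")
})

test_that("row extraction preserves constants and matches the dense blur oracle", {
  const <- matrix(0.3, 21, 360)
  out <- make_row_image(const)
  expect_s3_class(out, "emd_image")
  expect_length(out$contrast, 360)
  expect_equal(out$contrast, rep(0.3, 360), tolerance = 1e-12)

  # single bright row far from the center decays to near zero
  img <- matrix(0, 41, 360)
  img[1, ] <- 1
  out_far <- make_row_image(img)
  expect_lt(max(abs(out_far$contrast)), 1e-6)

  # dense convolution oracle for the central row
  rnd <- withr::with_seed(2, matrix(rnorm(41 * 360), 41, 360))
  sigma <- 5.7 / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sigma)
  k <- dnorm(seq(-half, half), 0, sigma)
  k <- k / sum(k)
  central <- 41 %/% 2 + 1
  oracle_row <- colSums(rnd[central + seq(-half, half), ] * k)
  expect_equal(make_row_image(rnd)$contrast, oracle_row, tolerance = 1e-10)
})

test_that("reflective tiling matches the brute-force oracle and is seam-symmetric", {
  row <- withr::with_seed(3, rnorm(100))
  got <- flymotion:::reflect_tile(row, 360L)
  expect_equal(got, oracle_reflect_tile(row, 360L))
  # a crop of three copy-lengths is exactly [rev(r), r, rev(r)]:
  # mirror-symmetric about both reflection seams
  row2 <- withr::with_seed(8, rnorm(120))
  got3 <- flymotion:::reflect_tile(row2, 360L)
  expect_identical(got3, c(rev(row2), row2, rev(row2)))
  expect_identical(got3[121:240], rev(got3[c(1:120, 241:360)][1:120]))
})

test_that("mirrored 2-D input yields the mirrored panoramic row", {
  rnd <- withr::with_seed(4, matrix(rnorm(21 * 120), 21, 120))
  a <- make_row_image(rnd)$contrast
  b <- make_row_image(rnd[, rev(seq_len(120))])$contrast
  expect_equal(b, rev(a), tolerance = 1e-12)
})

test_that("down-sampling conserves the mean and rejects too-narrow input", {
  # width exactly 360 at 1-deg pitch: the tiled crop is the row itself
  rnd <- withr::with_seed(5, matrix(rnorm(21 * 360), 21, 360))
  sigma <- 5.7 / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sigma)
  k <- dnorm(seq(-half, half), 0, sigma); k <- k / sum(k)
  central_blur <- colSums(rnd[(21 %/% 2 + 1) + seq(-half, half), ] * k)
  expect_equal(mean(make_row_image(rnd)$contrast), mean(central_blur),
               tolerance = 1e-12)
  expect_error(make_row_image(matrix(1, 10, 1), pixel_pitch = 0.25),
               "narrower")
})

test_that("synthetic images are deterministic and match their target moments", {
  p <- synth_image_params(seed = 99)
  expect_identical(synth_image(p)$contrast, synth_image(p)$contrast)

  # Gaussian limit: no asymmetry, kurtosis target 3 -> identity map
  pg <- synth_image_params(asymmetry = 0, target_kurtosis = 3, seed = 12)
  pool_g <- unlist(lapply(synth_image_set(pg, 300)$image,
                          function(i) i$contrast))
  expect_equal(kurtosis(pool_g), 3, tolerance = 0.15)
  expect_equal(skewness(pool_g), 0, tolerance = 0.1)

  # heavy-tailed target: ensemble kurtosis within +/- 20%
  ph <- synth_image_params(target_kurtosis = 8, seed = 13)
  pool_h <- unlist(lapply(synth_image_set(ph, 1000)$image,
                          function(i) i$contrast))
  expect_gt(kurtosis(pool_h), 6.4)
  expect_lt(kurtosis(pool_h), 9.6)
  expect_gt(skewness(pool_h), 0)

  expect_error(synth_image_params(target_kurtosis = 0.5), "unattainable")
  expect_error(synth_image(synth_image_params(target_kurtosis = 1.2)),
               "not attainable")
})

test_that("synthetic spatial autocovariance decays over the first 10 degrees", {
  imgs <- synth_image_set(synth_image_params(seed = 21), n = 300)
  sc <- spatial_covariance(imgs, max_lag = 10)
  expect_equal(sc$lag, 0:10)
  # smooth 1/k field: require decay with a small Monte-Carlo allowance
  expect_true(all(diff(sc$covariance) < 0.02 * sc$covariance[1]))
  expect_lt(sc$covariance[11], sc$covariance[1])
})

test_that("plain PGM files round into contrast panoramas", {
  tf <- tempfile(fileext = ".pgm")
  vals <- withr::with_seed(6, sample(0:255, 15 * 400, replace = TRUE))
  writeLines(c("P2", "400 15", "255",
               paste(vals, collapse = " ")), tf)
  m <- read_pgm(tf)
  expect_equal(dim(m), c(15, 400))
  expect_equal(m[1, 1:3], vals[1:3])
  img <- make_row_image(intensity_to_contrast(m))
  expect_length(img$contrast, 360)
  expect_gte(min(img$contrast), -1)
})
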