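cfg_short <- photoreceptor_config(duration = 0.4)

test_that("configuration validates its grid", {
  expect_error(photoreceptor_config(dt = -0.005), "positive")
  expect_error(photoreceptor_config(duration = 0.003, dt = 0.005),
               "at least one time step")
  expect_error(photoreceptor_config(duration = 0.012, dt = 0.005),
               "integer multiple")
})

test_that("constant panoramas charge up with the temporal kernel mass", {
  img <- synth_image(synth_image_params(seed = 1))
  img$contrast <- rep(0.4, 360)
  for (v in c(0, 130)) {
    clip <- photoreceptor_response(img, v, offset = 33, cfg_short)
    Tk <- flymotion:::exp_kernel(cfg_short$temporal_tau, cfg_short$dt)
    expect_equal(unname(clip$V[2, ]), 0.4 * cumsum(Tk)[pmin(
      seq_len(cfg_short$n_steps), length(Tk))], tolerance = 1e-12)
  }
})

test_that("zero velocity converges to the static blurred contrast", {
  img <- synth_image(synth_image_params(seed = 2))
  clip <- photoreceptor_response(img, 0, offset = 80, cfg_short)
  b <- flymotion:::blur_panorama(img, cfg_short)
  for (i in 1:3) {
    xi <- 80 + (i - 1) * cfg_short$spacing
    expect_equal(unname(clip$V[i, cfg_short$n_steps]),
                 flymotion:::interp_periodic(b, xi), tolerance = 1e-9)
  }
})

test_that("simulated responses match the brute-force quadrature oracle", {
  img <- synth_image(synth_image_params(seed = 31))
  cfg <- photoreceptor_config(duration = 0.2)
  clip <- photoreceptor_response(img, 90, offset = 12.3, cfg)
  t_eval <- c(0.1, 0.2)
  idx <- round(t_eval / cfg$dt)
  for (rec in c(1L, 3L)) {
    orc <- oracle_photoreceptor(img, 90, 12.3, cfg, t_eval, rec)
    rel <- max(abs(clip$V[rec, idx] - orc)) / max(abs(clip$V))
    expect_lt(rel, 0.02)
  }
})

test_that("offset is periodic in 360 degrees", {
  img <- synth_image(synth_image_params(seed = 3))
  a <- photoreceptor_response(img, -75, offset = 10, cfg_short)
  b <- photoreceptor_response(img, -75, offset = 370, cfg_short)
  expect_equal(a$V, b$V, tolerance = 1e-12)
})

test_that("movie path agrees with the rigid-translation path", {
  img <- synth_image(synth_image_params(seed = 4))
  v <- 90
  tt <- cfg_short$dt * seq_len(cfg_short$n_steps)
  movie <- vapply(tt, function(t) {
    flymotion:::interp_periodic(img$contrast, (0:359) - v * t)
  }, numeric(360))
  pos <- 10 + (0:2) * cfg_short$spacing
  Vm <- movie_response(movie, 1, cfg_short$dt, pos, cfg_short)
  clip <- photoreceptor_response(img, v, offset = 10, cfg_short)
  expect_lt(max(abs(Vm - clip$V)) / max(abs(clip$V)), 0.02)
})

test_that("movie filtering is linear and handles constants", {
  movie <- withr::with_seed(5, matrix(rnorm(72 * 40), 72, 40))
  pos <- c(0, 5.1, 33)
  V1 <- movie_response(movie, 5, 0.025, pos, cfg_short)
  Vneg <- movie_response(-movie, 5, 0.025, pos, cfg_short)
  expect_equal(Vneg, -V1, tolerance = 1e-12)
  ones <- matrix(1, 72, 40)
  Vc <- movie_response(ones, 5, 0.025, pos, cfg_short)
  expect_equal(Vc[2, ], Vc[1, ], tolerance = 1e-12) # space-constant
  expect_equal(Vc[3, ], Vc[1, ], tolerance = 1e-12)
  expect_error(movie_response(movie, 5, 0.025, c(0, 400), cfg_short,
                              boundary = "error"), "span")
})

test_that("ensembles are mirror-paired exactly and reproducible", {
  ens <- test_ensemble()
  expect_equal(nrow(ens), 800)
  for (j in c(1, 5, 399)) {
    a <- ens$clip[[2 * j - 1]]
    b <- ens$clip[[2 * j]]
    expect_identical(unname(b$V), unname(a$V[3:1, ]))
    expect_identical(b$velocity, -a$velocity)
  }
  ens2 <- build_ensemble(test_images(), n_motions = 400, seed = 7,
                         cfg = photoreceptor_config(duration = 0.4))
  expect_identical(lapply(ens$clip, `[[`, "V"), lapply(ens2$clip, `[[`, "V"))
  expect_error(build_ensemble(list(), 10), "empty")
})

test_that("ensemble velocities follow the zero-mean 90 deg/s prior", {
  # short clips keep the Monte-Carlo check at n = 1e4 cheap
  cfg_tiny <- photoreceptor_config(duration = 0.05)
  ens <- build_ensemble(test_images()[1:5, ], n_motions = 10000, seed = 77,
                        cfg = cfg_tiny)
  v <- ens$velocity[ens$member == "draw"]
  expect_lt(abs(mean(v)), 3 * 90 / sqrt(length(v)))
  expect_gt(sd(v), 87)
  expect_lt(sd(v), 93)
  expect_equal(mean(ens$velocity), 0, tolerance = 1e-12) # exact by pairing
})
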