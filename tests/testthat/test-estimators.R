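banks <- random_banks(1000)

test_that("every built-in correlator negates under receptor reversal", {
  for (ch in banks[1:200]) {
    m <- mirror_pair(ch) # swap the two receptors the correlator reads
    expect_equal(hrc(m), -hrc(ch), tolerance = 1e-14)
    expect_equal(converging_3pt(m, "two_site"), -converging_3pt(ch, "two_site"),
                 tolerance = 1e-14)
    expect_equal(converging_3pt(m, "squared"), -converging_3pt(ch, "squared"),
                 tolerance = 1e-14)
    qm <- quadrant_signals(m)
    q <- quadrant_signals(ch)
    for (nm in names(q)) expect_equal(qm[[nm]], -q[[nm]], tolerance = 1e-14)
    # full 3-receptor reversal maps the (1,2) correlator onto minus the
    # (2,3) correlator
    f <- mirror_channels(ch)
    expect_equal(hrc(f, c(1, 2)), -hrc(ch, c(2, 3)), tolerance = 1e-14)
  }
})

test_that("contrast inversion negates odd and preserves even correlators", {
  for (ch in banks[1:200]) {
    inv <- -ch
    expect_equal(hrc(inv), hrc(ch), tolerance = 1e-14)           # order 2
    expect_equal(converging_3pt(inv, "two_site"),
                 -converging_3pt(ch, "two_site"), tolerance = 1e-14)
    expect_equal(converging_3pt(inv, "squared"),
                 -converging_3pt(ch, "squared"), tolerance = 1e-14)
  }
})

test_that("quadrants sum to the HRC and support the stated special cases", {
  for (ch in banks) {
    q <- quadrant_signals(ch)
    expect_equal(q$pp + q$pm + q$mp + q$mm, hrc(ch), tolerance = 1e-13)
    expect_equal(weighted_quadrant(ch, c(1, 1, 1, 1)), hrc(ch),
                 tolerance = 1e-13)
  }
  expect_equal(weighted_quadrant(banks[[1]], c(0, 0, 0, 0)), 0)
  allpos <- c(f1 = 1.2, g1 = 0.4, f2 = 0.8, g2 = 2.0, f3 = 0.3, g3 = 0.9)
  expect_equal(weighted_quadrant(allpos, c(1, 0, 0, 0)), hrc(allpos))
  q <- quadrant_signals(allpos)
  expect_equal(q$pm, 0)
  expect_equal(q$mp, 0)
  expect_equal(q$mm, 0)
})

test_that("converging 3-point correlator matches hand arithmetic", {
  ch <- c(f1 = 2, g1 = 0, f2 = 1, g2 = 3, f3 = 0, g3 = 0)
  expect_equal(converging_3pt(ch, "squared"), 2^2 * 3 - 1^2 * 0) # 12
  expect_equal(converging_3pt(ch, "two_site"), 2 * 1 * 3 - 1 * 2 * 0) # 6
  expect_error(converging_3pt(ch, "other"))
})

test_that("non-adjacent pairs need the explicit flag", {
  ch <- banks[[1]]
  expect_error(hrc(ch, pair = c(1, 3)), "Non-adjacent")
  expect_silent(hrc(ch, pair = c(1, 3), allow_nonadjacent = TRUE))
  expect_equal(hrc(ch, pair = c(1, 3), allow_nonadjacent = TRUE),
               ch[["f1"]] * ch[["g3"]] - ch[["g1"]] * ch[["f3"]])
})

test_that("correlation classes form an invertible, parity-typed basis", {
  for (ch in banks[1:200]) {
    q <- quadrant_signals(ch)
    cl <- correlation_classes(q)
    expect_equal(cl$even2, hrc(ch) / 4, tolerance = 1e-13)
    back <- classes_to_quadrants(cl)
    for (nm in names(q)) expect_equal(back[[nm]], q[[nm]], tolerance = 1e-12)
    # contrast inversion swaps pp<->mm and pm<->mp: even classes are
    # invariant, odd classes negate
    cli <- correlation_classes(quadrant_signals(-ch))
    expect_equal(cli$even2, cl$even2, tolerance = 1e-13)
    expect_equal(cli$even_gt2, cl$even_gt2, tolerance = 1e-13)
    expect_equal(cli$odd, -cl$odd, tolerance = 1e-13)
    expect_equal(cli$oddstar, -cl$oddstar, tolerance = 1e-13)
  }
  # the two odd labels are swappable by configuration
  q1 <- quadrant_signals(banks[[3]])
  expect_equal(correlation_classes(q1, "highpass")$odd,
               correlation_classes(q1, "lowpass")$oddstar)
})

test_that("polynomial feature enumeration has the documented sizes and order", {
  expect_equal(nrow(poly_exponents(2)), 14)
  expect_equal(nrow(poly_exponents(4)), 69)
  expect_equal(nrow(poly_exponents(6)), 209)
  ex <- poly_exponents(4)
  expect_true(all(rowSums(ex) >= 1 & rowSums(ex) <= 4))
  expect_false(is.unsorted(apply(ex, 1, paste, collapse = ""))) # lexicographic
  chs <- test_channels()
  expect_equal(ncol(poly_features(chs, 2)), 14)
  expect_equal(ncol(poly_features(chs, 4)), 69)
  expect_equal(ncol(poly_features(chs, 6)), 209)
  expect_error(poly_features(chs[, c("f1", "g1")], 4), "arity")
})

test_that("arity-2 features are mirror-antisymmetrized nonlinearity pairs", {
  ch <- banks[[2]]
  X <- poly_features(as.list(ch), 2)
  ex <- attr(X, "exponents")
  k <- which(ex[, 1] == 1 & ex[, 2] == 1)
  expect_equal(unname(X[1, k]),
               ch[["f1"]] * ch[["g2"]] - ch[["f2"]] * ch[["g1"]])
  m <- mirror_pair(ch)
  Xm <- poly_features(as.list(m), 2)
  expect_equal(unname(Xm), -unname(X), tolerance = 1e-14)
})

test_that("polynomial special-case weights reproduce the HRC and HRC average", {
  # arity 4: w1001 = -w0110 != 0 is the HRC
  ex4 <- poly_exponents(4)
  w4 <- numeric(69)
  nm4 <- paste0("w", apply(ex4, 1, paste, collapse = ""))
  w4[nm4 == "w1001"] <- 2.5
  w4[nm4 == "w0110"] <- -2.5
  m4 <- emd_model("poly4", w4)
  # arity 6 special case equals the average of the two neighboring HRCs
  ex6 <- poly_exponents(6)
  nm6 <- paste0("w", apply(ex6, 1, paste, collapse = ""))
  w6 <- numeric(209)
  w6[nm6 == "w100100"] <- 1
  w6[nm6 == "w011000"] <- -1
  w6[nm6 == "w001001"] <- 1
  w6[nm6 == "w000110"] <- -1
  m6 <- emd_model("poly6", w6)
  for (ch in banks[1:300]) {
    expect_equal(evaluate_model(m4, ch), 2.5 * hrc(ch), tolerance = 1e-13)
    avg2 <- (hrc(ch, c(1, 2)) + hrc(ch, c(2, 3))) / 2
    expect_equal(evaluate_model(m6, ch), 2 * avg2, tolerance = 1e-13)
  }
})

test_that("the model wrapper is a faithful adapter", {
  ch <- banks[[4]]
  expect_equal(evaluate_model(emd_model("hrc", 1), ch), hrc(ch))
  expect_equal(evaluate_model(emd_model("quadrant", c(1, 1, 1, 1)), ch),
               hrc(ch), tolerance = 1e-13)
  expect_error(evaluate_model(emd_model("hrc", NA_real_), ch), "unset")
  expect_error(emd_model("quadrant", c(1, 2)), "4 weights")
  # evaluation on a real filter bank picks the readout time point
  k <- make_kernels()
  bank <- filter_bank(test_ensemble()$clip[[3]], k)
  ro <- bank$channels[, bank$readout_index]
  expect_equal(evaluate_model(emd_model("hrc", 1), bank), hrc(ro))
  expect_equal(evaluate_model(emd_model("poly4", rep(0.1, 69)), bank),
               sum(0.1 * poly_features(as.list(ro), 4)), tolerance = 1e-12)
})
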