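# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

test_images <- function() {
  fixture("images", function() {
    synth_image_set(synth_image_params(seed = 303), n = 40)
  })
}

# Small, fast ensemble for unit tests (short clips).
test_ensemble <- function() {
  fixture("ensemble", function() {
    build_ensemble(test_images(), n_motions = 400, seed = 7,
                   cfg = photoreceptor_config(duration = 0.4))
  })
}

test_channels <- function() {
  fixture("channels", function() {
    ensemble_channels(test_ensemble())
  })
}

# Study-conditions ensemble for the acceptance checks: synthetic images
# with kurtosis ~8 and positive skew, 1e4 mirror pairs, full-length clips.
acceptance_ensemble <- function() {
  fixture("acc_ensemble", function() {
    imgs <- synth_image_set(synth_image_params(seed = 11), n = 200)
    build_ensemble(imgs, n_motions = 10000, seed = 5)
  })
}

acceptance_channels <- function() {
  fixture("acc_channels", function() {
    ensemble_channels(acceptance_ensemble())
  })
}
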