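test_that("mean arterial pressure follows the one-third rule", {
  expect_equal(mean_arterial_pressure(80, 120), 80 + 40 / 3)
  expect_equal(mean_arterial_pressure(95, 95), 95)
  expect_equal(mean_arterial_pressure(70, 130), 90)
  expect_error(mean_arterial_pressure(120, 80), ">=")
  # linear in both inputs, bounded between dia and sys
  d <- runif(20, 60, 90); s <- d + runif(20, 10, 60)
  m <- mean_arterial_pressure(d, s)
  expect_true(all(m >= d & m <= s))
  expect_equal(mean_arterial_pressure(2 * d, 2 * s), 2 * m)
})

test_that("VAS categories average their assigned items", {
  out <- vas_categories(rep(4.2, 16))
  expect_equal(out$alertness, 4.2)
  expect_equal(out$contentedness, 4.2)
  expect_equal(out$calmness, 4.2)
  expect_error(vas_categories(rep(1, 15)), "16")
  # permuting items within a category leaves the score unchanged
  set.seed(2)
  items <- runif(16, 0, 10)
  map <- vas_default_mapping()
  items2 <- items
  items2[map$alertness] <- items[sample(map$alertness)]
  expect_equal(vas_categories(items)$alertness,
               vas_categories(items2)$alertness)
  expect_equal(length(map$alertness), 9)
  expect_equal(length(map$contentedness), 5)
  expect_equal(length(map$calmness), 2)
})

test_that("percent change is exact and round-trips", {
  expect_equal(percent_change(110, 100), 10)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(75, 100), -25)
  expect_error(percent_change(5, 0), "zero")
  b <- 87.3
  pc <- percent_change(64.1, b)
  expect_equal(b * (1 + pc / 100), 64.1)
})

test_that("pupil preprocessing passes through clean in-band signal", {
  sf <- 500
  t <- seq(0, 20 - 1 / sf, by = 1 / sf)
  x <- sin(2 * pi * 0.7 * t) + 0.5 * sin(2 * pi * 3 * t)
  y <- pupil_preprocess(x, sfreq = sf)
  expect_gt(cor(x[1000:9000], y[1000:9000]), 0.999)
  # idempotence on clean traces
  y2 <- pupil_preprocess(y, sfreq = sf)
  mid <- 1000:9000
  expect_lt(mean((y2[mid] - y[mid])^2) / mean(y[mid]^2), 0.01)
  # constant trace is zeroed (DC removed)
  z <- pupil_preprocess(rep(5, sf * 10), sfreq = sf)
  expect_lt(max(abs(z)), 1e-6)
})

test_that("synthetic blink responses are removed by FIR deconvolution", {
  set.seed(8)
  sf <- 100
  n <- 120 * sf
  t <- seq(0, by = 1 / sf, length.out = n)
  clean <- sin(2 * pi * 0.13 * t) + 0.3 * sin(2 * pi * 0.47 * t)
  # irregular blink times so event regressors are not phase-locked to signal
  onsets <- sort(3 + cumsum(runif(22, 2.5, 7)))
  onsets <- onsets[onsets < 112]
  blinks <- tibble::tibble(onset = onsets, offset = onsets + 0.12)
  kern_t <- seq(0, 4, by = 1 / sf)
  kernel <- -1.5 * kern_t * exp(-kern_t / 0.6) # transient constriction
  dirty <- clean
  for (o in blinks$offset) {
    i0 <- round(o * sf)
    ix <- i0 + seq_along(kernel) - 1
    keep <- ix <= n
    dirty[ix[keep]] <- dirty[ix[keep]] + kernel[keep]
  }
  # blink gap artifact
  for (k in seq_len(nrow(blinks))) {
    i0 <- round(blinks$onset[k] * sf); i1 <- round(blinks$offset[k] * sf)
    dirty[i0:i1] <- dirty[i0:i1] - 4
  }
  cleaned <- pupil_preprocess(dirty, sfreq = sf, blinks = blinks,
                              deconv_window = 4)
  ref <- pupil_preprocess(clean, sfreq = sf)
  expect_gt(cor(cleaned, ref), 0.95)
  # without deconvolution the artifact remains
  no_deconv <- pupil_preprocess(dirty, sfreq = sf,
                                blinks = blinks[0, , drop = FALSE])
  expect_gt(cor(cleaned, ref), cor(no_deconv, ref))
})

test_that("excessive blink coverage raises an error", {
  blinks <- tibble::tibble(onset = 0, offset = 8)
  expect_error(pupil_preprocess(rnorm(1000), sfreq = 100, blinks = blinks),
               "50%")
})

test_that("dark/bright pupil summary averages the final five seconds", {
  sf <- 200
  tr <- c(rep(6, 15 * sf), rep(4, 15 * sf))
  out <- pupil_darkbright(tr, sfreq = sf)
  expect_equal(out$p_max, 6)
  expect_equal(out$p_min, 4)
  # constant trace: both equal
  out2 <- pupil_darkbright(rep(5.5, 30 * sf), sfreq = sf)
  expect_equal(out2$p_max, out2$p_min)
  expect_error(pupil_darkbright(rep(5, 10 * sf), sfreq = sf), "truncated")
  # an additive offset shifts both measures equally
  out3 <- pupil_darkbright(tr + 0.5, sfreq = sf)
  expect_equal(out3$p_max - out$p_max, 0.5)
  expect_equal(out3$p_min - out$p_min, 0.5)
})
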