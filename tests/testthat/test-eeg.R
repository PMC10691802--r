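test_that("baseline subtraction zeroes the baseline window exactly", {
  ep <- make_epochs(n_trials = 3, signal = function(ch, t) 5 + sin(2 * pi * t),
                    noise_sd = 0.5, seed = 2)
  out <- epoch_and_baseline(ep, window = c(-1, 1), baseline = c(-0.5, -0.2))
  bsel <- out$times >= -0.5 & out$times <= -0.2
  bmeans <- apply(out$data[, , bsel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bmeans)), 1e-12)
  # a constant signal is identically zero after baseline removal
  cst <- make_epochs(n_trials = 2, signal = function(ch, t) 7)
  out2 <- epoch_and_baseline(cst, baseline = c(-0.5, 0))
  expect_lt(max(abs(out2$data)), 1e-12)
})

test_that("downsampling 512 Hz four-second epochs to 128 Hz yields 512 samples", {
  mont <- standard_montage()
  times <- seq(-2, 2 - 1 / 512, by = 1 / 512)
  dat <- array(rnorm(2 * nrow(mont) * length(times)),
               c(2, nrow(mont), length(times)))
  ep <- eeg_epochs(dat, times, 512, mont, lock = "stimulus")
  out <- epoch_and_baseline(ep, downsample_to = 128)
  expect_equal(dim(out$data)[3], 512)
  expect_equal(out$sfreq, 128)
  expect_error(epoch_and_baseline(ep, downsample_to = 100), "integer")
})

test_that("response locking aligns t = 0 with the stimulus-locked sample at rt", {
  rt <- 0.6
  ep <- make_epochs(n_trials = 1, sfreq = 128, span = c(-1, 1.5),
                    meta = tibble::tibble(rt = rt),
                    signal = function(ch, t) sin(2 * pi * 3 * t))
  resp <- epoch_and_baseline(ep, lock = "response", window = c(-0.4, 0.2))
  i_resp <- which.min(abs(resp$times))
  i_stim <- which.min(abs(ep$times - rt))
  expect_equal(resp$data[1, , i_resp], ep$data[1, , i_stim])
})

test_that("trials whose response window leaves the epoch are dropped", {
  ep <- make_epochs(n_trials = 2, sfreq = 128, span = c(-1, 1),
                    meta = tibble::tibble(rt = c(0.5, 0.95)))
  expect_message(
    out <- epoch_and_baseline(ep, lock = "response", window = c(-0.4, 0.2)),
    "dropped"
  )
  expect_equal(dim(out$data)[1], 1)
})

test_that("CSD is zero for uniform maps, linear, and reference-free", {
  ep <- make_epochs(n_trials = 2, signal = function(ch, t) 3)
  csd <- csd_transform(ep)
  expect_lt(max(abs(csd$data)), 1e-6 * 3)
  expect_equal(csd$units, "uV/cm^2")

  mont <- standard_montage()
  pos <- as.matrix(mont[, c("x", "y", "z")])
  cz <- pos[mont$channel == "Cz", ]
  topo <- exp(-(acos(pmin(pmax(pos %*% cz, -1), 1)) / 1.0)^2)
  dat <- array(topo, c(1, nrow(mont), 1))
  mk <- function(d) eeg_epochs(d, 0, 512, mont, lock = "stimulus")
  base <- csd_transform(mk(dat))
  expect_equal(csd_transform(mk(3 * dat))$data, 3 * base$data,
               tolerance = 1e-10)
  expect_equal(csd_transform(mk(dat + 10))$data, base$data,
               tolerance = 1e-6)
  # spatial sharpening: fewer channels above half maximum after CSD
  frac_above <- function(v) mean(v > max(v) / 2)
  expect_lt(frac_above(base$data[1, , 1]), frac_above(topo))
})

test_that("CSD refuses channels without positions", {
  mont <- standard_montage()
  mont$x[3] <- NA
  dat <- array(rnorm(64 * 2), c(1, 64, 2))
  ep <- eeg_epochs(dat, c(0, 1 / 512), 512, mont, lock = "stimulus")
  expect_error(csd_transform(ep), mont$channel[3])
})

test_that("contra/ipsi assignment reproduces the cue-by-stimulus truth table", {
  meta <- tibble::tibble(
    cue_side = c("right", "left", "left", "right"),
    stim_side = c("right", "right", "left", "left")
  )
  # left-hemisphere ROI carries +1, right-hemisphere ROI carries -1
  stim_roi <- roi_spec("stimulus")
  ep <- make_epochs(n_trials = 4, meta = meta, signal = function(ch, t) {
    if (ch %in% stim_roi$left) 1 else if (ch %in% stim_roi$right) -1 else 0
  })
  lab <- assign_contra_ipsi(ep, stim_roi, reference = "cue")
  one <- lab[lab$time == lab$time[1], ]

  pick <- function(trial, hemi) one[one$trial == trial &
                                      one$hemisphere == hemi, ]
  # trial 1: cue right, target right -> left ROI is the cued target
  expect_equal(pick(1, "left")$attention, "cued")
  expect_equal(pick(1, "left")$stimulus, "target")
  expect_equal(pick(1, "right")$attention, "uncued")
  expect_equal(pick(1, "right")$stimulus, "noise")
  # trial 2: cue left, target right -> right ROI is the cued noise
  expect_equal(pick(2, "right")$attention, "cued")
  expect_equal(pick(2, "right")$stimulus, "noise")
  expect_equal(pick(2, "left")$attention, "uncued")
  expect_equal(pick(2, "left")$stimulus, "target")
  # cue left -> cued-location trace comes from the right hemisphere
  expect_equal(unique(one$value[one$trial == 2 &
                                  one$attention == "cued"]), -1)
})

test_that("flipping all cue sides swaps contra and ipsi exactly", {
  meta <- tibble::tibble(cue_side = c("left", "right"),
                         stim_side = c("left", "right"))
  ep <- make_epochs(n_trials = 2, meta = meta, noise_sd = 1, seed = 5)
  lab1 <- assign_contra_ipsi(ep, roi_spec("stimulus"), reference = "cue")
  ep2 <- ep
  ep2$meta$cue_side <- ifelse(meta$cue_side == "left", "right", "left")
  lab2 <- assign_contra_ipsi(ep2, roi_spec("stimulus"), reference = "cue")
  m1 <- lab1[order(lab1$trial, lab1$hemisphere, lab1$time), ]
  m2 <- lab2[order(lab2$trial, lab2$hemisphere, lab2$time), ]
  expect_identical(m1$value, m2$value)
  expect_identical(m1$role,
                   ifelse(m2$role == "contra", "ipsi", "contra"))
})

test_that("CPP metrics return the t = 0 amplitude and the exact OLS slope", {
  k <- 4.2
  ep <- make_epochs(n_trials = 1, sfreq = 128, span = c(-0.6, 0.25),
                    meta = tibble::tibble(rt = NA_real_),
                    signal = function(ch, t) {
                      if (ch %in% c("CPz", "CP1", "CP2")) k * t + 2 else 0
                    })
  ep$lock <- "response"
  m <- cpp_metrics(ep)
  expect_equal(m$cpp_slope, k, tolerance = 1e-10)
  i0 <- which.min(abs(ep$times))
  expect_equal(m$cpp_peak, k * ep$times[i0] + 2, tolerance = 1e-10)
  expect_error(cpp_metrics(ep, slope_window = c(-2, 0)), "window")
})

test_that("the Morlet cycle rule and power scaling hold", {
  ep <- make_epochs(n_trials = 2, sfreq = 256, span = c(-1, 1),
                    signal = function(ch, t) sin(2 * pi * 10 * t))
  ep$data[2, , ] <- 2 * ep$data[1, , ]
  tfr <- morlet_tfr(ep, freqs = seq(2, 40, 2), channels = c("Oz", "POz"))
  mid <- which.min(abs(tfr$times - 0.25))
  spect <- tfr$power[1, 1, , mid]
  expect_equal(tfr$freqs[which.max(spect)], 10)
  expect_equal(tfr$power[2, 1, 5, mid] / tfr$power[1, 1, 5, mid], 4,
               tolerance = 0.01)
  expect_error(
    morlet_tfr(make_epochs(n_trials = 1, sfreq = 128, span = c(0, 0.25)),
               freqs = 2),
    "2 Hz"
  )
})

test_that("power of well-separated sinusoids adds with small cross-terms", {
  f1 <- 8; f2 <- 24
  base <- function(f) function(ch, t) sin(2 * pi * f * t)
  ep1 <- make_epochs(n_trials = 1, sfreq = 256, span = c(-1, 1),
                     signal = base(f1))
  ep2 <- make_epochs(n_trials = 1, sfreq = 256, span = c(-1, 1),
                     signal = base(f2))
  ep12 <- ep1
  ep12$data <- ep1$data + ep2$data
  freqs <- c(8, 24)
  mid <- function(tfr) which.min(abs(tfr$times - 0.2))
  t1 <- morlet_tfr(ep1, freqs, channels = "Oz")
  t2 <- morlet_tfr(ep2, freqs, channels = "Oz")
  t12 <- morlet_tfr(ep12, freqs, channels = "Oz")
  for (fi in 1:2) {
    sum_sep <- t1$power[1, 1, fi, mid(t1)] + t2$power[1, 1, fi, mid(t2)]
    expect_equal(t12$power[1, 1, fi, mid(t12)], sum_sep,
                 tolerance = 0.05 * sum_sep)
  }
})

test_that("decibel normalization satisfies the log identities", {
  ep <- make_epochs(n_trials = 1, sfreq = 256, span = c(-1, 1),
                    signal = function(ch, t) sin(2 * pi * 10 * t))
  tfr <- morlet_tfr(ep, freqs = 10, channels = "Oz")
  mk_db <- function(scale) {
    t2 <- tfr
    t2$power <- tfr$power * scale # rescale signal everywhere
    t2$power[, , , tfr$times < -0.25] <- tfr$power[, , , tfr$times < -0.25]
    db_normalize(t2, baseline_window = c(-0.6, -0.3))
  }
  mid <- which.min(abs(tfr$times - 0.25))
  expect_equal(mk_db(1)$power[1, 1, 1, mid], 0, tolerance = 0.05)
  expect_equal(mk_db(10)$power[1, 1, 1, mid], 10, tolerance = 0.05)
  expect_equal(mk_db(0.1)$power[1, 1, 1, mid], -10, tolerance = 0.05)
  expect_error(db_normalize(tfr, baseline_window = c(5, 6)), "baseline")
})

test_that("alpha lateralization is zero for hemispherically symmetric power", {
  meta <- tibble::tibble(cue_side = c("left", "right"))
  occ <- roi_spec("occipital")
  ep <- make_epochs(n_trials = 2, sfreq = 256, span = c(-1, 1), meta = meta,
                    signal = function(ch, t) {
                      if (ch %in% c(occ$left, occ$right)) {
                        sin(2 * pi * 10 * t)
                      } else 0
                    })
  tfr <- morlet_tfr(ep, freqs = c(8, 10, 12),
                    channels = c(occ$left, occ$right))
  lat <- alpha_lateralization(tfr)
  expect_lt(max(abs(lat$lateralization)), 1e-10)
  # band average equals the arithmetic mean of the band bins
  fsel <- tfr$freqs >= 8 & tfr$freqs <= 12
  lix <- match(occ$left, tfr$channels$channel)
  manual <- mean(tfr$power[1, lix, fsel, 100])
  got <- lat[lat$trial == 1, ]
  # trial 1 cue left: ipsi = left hemisphere
  expect_equal(got$ipsi[100], manual, tolerance = 1e-12)
  expect_error(alpha_lateralization(tfr, band = c(90, 100)), "band")
})
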