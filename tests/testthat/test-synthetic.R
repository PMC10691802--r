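test_that("behavioral generation is byte-identical under a fixed seed", {
  cfg <- generative_config(n_subjects = 2, n_blocks = 1, trials_per_block = 20)
  b1 <- generate_behavior(cfg, seed = 5)
  b2 <- generate_behavior(cfg, seed = 5)
  expect_identical(b1, b2)
  b3 <- generate_behavior(cfg, seed = 6)
  expect_false(identical(b1$rt, b3$rt))
})

test_that("the null switch removes condition effects from behavior", {
  cfg <- generative_config(n_subjects = 20, n_blocks = 1,
                           trials_per_block = 80, sessions = "PLC",
                           null_effects = TRUE)
  expect_equal(cfg$effects$v_validity, 0)
  beh <- generate_behavior(cfg, seed = 7)
  summ <- condition_summary(beh, extra_groups = "subject") |>
    dplyr::select("subject", "validity", "dprime") |>
    tidyr::pivot_wider(names_from = "validity", values_from = "dprime")
  expect_lt(abs(mean(summ$valid - summ$invalid)), 0.25)
})

test_that("generated sessions respect the design balance", {
  cfg <- generative_config(n_subjects = 1, n_blocks = 2, trials_per_block = 40)
  beh <- generate_behavior(cfg, seed = 9)
  per_session <- beh |>
    dplyr::group_by(drug) |>
    dplyr::summarise(
      n = dplyr::n(),
      valid = sum(validity == "valid"),
      left_cue = sum(cue_side == "left")
    )
  expect_true(all(per_session$n == 80))
  expect_true(all(per_session$valid == 64))
  expect_true(all(per_session$left_cue == 40))
})

test_that("EEG generation is reproducible and carries the behavior meta", {
  cfg <- generative_config(n_subjects = 1, n_blocks = 1, trials_per_block = 20,
                           sessions = "PLC")
  beh <- generate_behavior(cfg, seed = 11)
  e1 <- generate_eeg(cfg, beh, seed = 3)
  e2 <- generate_eeg(cfg, beh, seed = 3)
  expect_identical(e1$data, e2$data)
  expect_equal(nrow(e1$meta), dim(e1$data)[1])
  expect_equal(dim(e1$data)[2], 64)
  expect_equal(e1$sfreq, 512)
})

test_that("generated alpha suppression is recovered at the configured depth", {
  cfg <- generative_config(n_subjects = 2, n_blocks = 1, trials_per_block = 60,
                           sessions = "PLC")
  beh <- generate_behavior(cfg, seed = 13)
  occ <- roi_channels(roi_spec("occipital"))
  lats <- purrr::map_dbl(sprintf("S%02d", 1:2), function(su) {
    ep <- generate_eeg(cfg, beh, subject = su, drug = "PLC",
                       seed = 13 + match(su, sprintf("S%02d", 1:2)))
    tfr <- morlet_tfr(select_channels(ep, occ), freqs = seq(6, 14, 2))
    tfr_db <- db_normalize(tfr, baseline_window = c(-1.55, -1.35))
    lat <- alpha_lateralization(tfr_db)
    mean(lat$lateralization[lat$time > -0.6 & lat$time < -0.1])
  })
  expect_lt(abs(mean(lats) - cfg$eeg$alpha_lateralization_db), 0.2)
})

test_that("physio panels are reproducible and carry the ATX arousal effect", {
  cfg <- generative_config(n_subjects = 12)
  p1 <- generate_physio(cfg, seed = 4)
  p2 <- generate_physio(cfg, seed = 4)
  expect_identical(p1$vitals, p2$vitals)
  expect_true(all(p1$vitals$bp_sys > p1$vitals$bp_dia))
  expect_equal(nrow(p1$vitals), 12 * 3 * 3)

  # percent change from baseline is positive for heart rate under ATX
  pc <- p1$vitals |>
    dplyr::group_by(subject, drug) |>
    dplyr::summarise(
      pc_hr = percent_change(heart_rate[timepoint == "4h"],
                             heart_rate[timepoint == "baseline"]),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "drug", values_from = "pc_hr")
  expect_gt(mean(pc$ATX - pc$PLC), 0)

  # pupil dark/bright derivation sees the ATX shift on both measures
  db <- p1$pupil |>
    dplyr::mutate(purrr::map_dfr(trace, pupil_darkbright)) |>
    dplyr::group_by(drug) |>
    dplyr::summarise(p_max = mean(p_max), p_min = mean(p_min))
  expect_gt(db$p_max[db$drug == "ATX"], db$p_max[db$drug == "PLC"])
  expect_gt(db$p_min[db$drug == "ATX"], db$p_min[db$drug == "PLC"])
})

test_that("the null physio configuration carries no drug effect", {
  cfg <- generative_config(n_subjects = 10, null_effects = TRUE)
  p <- generate_physio(cfg, seed = 6)
  hr <- p$vitals |>
    dplyr::filter(timepoint == "4h") |>
    dplyr::group_by(drug) |>
    dplyr::summarise(hr = mean(heart_rate))
  expect_lt(diff(range(hr$hr)), 4)
})
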