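test_that("d-prime and criterion match the inverse-normal oracle", {
  # large counts so the log-linear correction is negligible
  tr <- make_sdt_trials(2000, 1500, 2000, 500) # H = 0.75, FA = 0.25
  s <- sdt_metrics(tr)
  expect_equal(s$dprime, 2 * qnorm(0.75), tolerance = 0.01)
  expect_equal(s$criterion, 0, tolerance = 1e-10)

  tr2 <- make_sdt_trials(1000, 500, 1000, 500) # H = FA
  expect_equal(sdt_metrics(tr2)$dprime, 0, tolerance = 1e-10)

  tr3 <- make_sdt_trials(2000, 1800, 2000, 1800) # H = FA = 0.9
  s3 <- sdt_metrics(tr3)
  expect_equal(s3$dprime, 0, tolerance = 1e-10)
  expect_equal(s3$criterion, -qnorm(0.9), tolerance = 0.01)
})

test_that("extreme rates stay finite under the log-linear correction", {
  tr <- make_sdt_trials(50, 50, 50, 0) # perfect performance
  s <- sdt_metrics(tr)
  expect_true(is.finite(s$dprime))
  expect_gt(s$dprime, 3)
})

test_that("relabeling the signal class preserves d-prime and flips criterion", {
  tr <- make_sdt_trials(400, 300, 400, 120)
  s_cw <- sdt_metrics(tr, signal = "cw")
  s_ccw <- sdt_metrics(tr, signal = "ccw")
  expect_equal(s_cw$dprime, s_ccw$dprime, tolerance = 1e-10)
  expect_equal(s_cw$criterion, -s_ccw$criterion, tolerance = 1e-10)
})

test_that("condition summaries apply the RT exclusion rule", {
  tr <- tibble::tibble(
    drug = "PLC", validity = "valid",
    orientation = rep(c("cw", "ccw"), 10),
    accuracy = rep(c(1, 0), 10),
    rt = c(rep(0.6, 18), 1.5, NA)
  )
  summ <- condition_summary(tr)
  expect_equal(summ$n_trials, 18) # rt = 1.5 s and the missed trial excluded
  # a trial exactly at the 1.4 s deadline is kept
  tr$rt[19] <- 1.4
  expect_equal(condition_summary(tr)$n_trials[1], 19)
})

test_that("cell trial counts sum to the post-filter total", {
  cfg <- generative_config(n_subjects = 3, n_blocks = 1, trials_per_block = 40)
  beh <- generate_behavior(cfg, seed = 12)
  summ <- condition_summary(beh, extra_groups = "subject")
  kept <- sum(!is.na(beh$rt) & beh$rt <= 1.4)
  expect_equal(sum(summ$n_trials), kept)
})

test_that("synthetic data with a validity drift advantage shows higher valid d-prime", {
  cfg <- generative_config(n_subjects = 10, n_blocks = 1,
                           trials_per_block = 160, sessions = "PLC")
  beh <- generate_behavior(cfg, seed = 14)
  summ <- condition_summary(beh, extra_groups = "subject") |>
    dplyr::select("subject", "validity", "dprime") |>
    tidyr::pivot_wider(names_from = "validity", values_from = "dprime")
  expect_gt(mean(summ$valid - summ$invalid), 0)
})

test_that("alpha binning median-splits evenly within subject and session", {
  set.seed(4)
  tr <- tidyr::expand_grid(subject = c("S1", "S2"), drug = c("PLC", "ATX"),
                           trial = 1:100) |>
    dplyr::mutate(
      validity = rep(c("valid", "invalid"), length.out = dplyr::n()),
      orientation = sample(c("cw", "ccw"), dplyr::n(), replace = TRUE),
      accuracy = rbinom(dplyr::n(), 1, 0.75),
      alpha = rnorm(dplyr::n())
    )
  out <- bin_by_alpha(tr)
  counts <- out |>
    dplyr::group_by(subject, drug, alpha_bin) |>
    dplyr::summarise(n = sum(n_signal + n_noise),
                     .groups = "drop")
  expect_true(all(counts$n == 50))

  # odd trial count: the low bin is larger by one
  tr_odd <- tr |> dplyr::filter(!(subject == "S1" & drug == "PLC" &
                                    trial == 100))
  out_odd <- bin_by_alpha(tr_odd) |>
    dplyr::filter(subject == "S1", drug == "PLC") |>
    dplyr::group_by(alpha_bin) |>
    dplyr::summarise(n = sum(n_signal + n_noise))
  expect_equal(out_odd$n[out_odd$alpha_bin == "low"], 50)
  expect_equal(out_odd$n[out_odd$alpha_bin == "high"], 49)
})

test_that("alpha bins track a generator coupling of alpha and accuracy", {
  set.seed(6)
  n <- 4000
  alpha <- rnorm(n)
  p_correct <- plogis(1.1 - 0.8 * alpha) # low alpha -> more accurate
  tr <- tibble::tibble(
    subject = "S1", drug = "PLC",
    validity = rep(c("valid", "invalid"), length.out = n),
    orientation = sample(c("cw", "ccw"), n, replace = TRUE),
    accuracy = rbinom(n, 1, p_correct),
    alpha = alpha
  )
  out <- bin_by_alpha(tr) |>
    dplyr::group_by(alpha_bin) |>
    dplyr::summarise(dprime = mean(dprime))
  expect_gt(out$dprime[out$alpha_bin == "low"],
            out$dprime[out$alpha_bin == "high"])

  # and a null coupling gives matched bins
  tr$accuracy <- rbinom(n, 1, 0.75)
  out0 <- bin_by_alpha(tr) |>
    dplyr::group_by(alpha_bin) |>
    dplyr::summarise(dprime = mean(dprime))
  expect_lt(abs(diff(out0$dprime)), 0.25)
})
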