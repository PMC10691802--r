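# Shared fixtures built in code.

# trial table with exact hit/false-alarm counts (cw = signal)
make_sdt_trials <- function(n_signal, hits, n_noise, fas) {
  tibble::tibble(
    orientation = c(rep("cw", n_signal), rep("ccw", n_noise)),
    response = c(rep("cw", hits), rep("ccw", n_signal - hits),
                 rep("cw", fas), rep("ccw", n_noise - fas))
  )
}

# long within-subject table for the permutation/ANOVA tests
make_rm_long <- function(n_subj, conds, n_samples, seed, effect = 0,
                         effect_samples = integer()) {
  set.seed(seed)
  d <- tidyr::expand_grid(subject = seq_len(n_subj), cond = conds,
                          sample = seq_len(n_samples))
  d$value <- rnorm(nrow(d))
  if (effect != 0 && length(effect_samples)) {
    sel <- d$cond == conds[1] & d$sample %in% effect_samples
    d$value[sel] <- d$value[sel] + effect
  }
  d
}

# small synthetic epochs object with given per-channel signal function
make_epochs <- function(n_trials = 4, sfreq = 128, span = c(-1, 1),
                        meta = NULL, signal = function(ch, times) 0,
                        noise_sd = 0, seed = 1) {
  set.seed(seed)
  mont <- standard_montage()
  times <- seq(span[1], span[2] - 1 / sfreq, by = 1 / sfreq)
  dat <- array(0, c(n_trials, nrow(mont), length(times)))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(nrow(mont))) {
      dat[tr, ch, ] <- signal(mont$channel[ch], times) +
        noise_sd * rnorm(length(times))
    }
  }
  eeg_epochs(dat, times, sfreq, mont, meta = meta, lock = "stimulus")
}
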