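#' Generative configuration for study-shaped synthetic datasets
#'
#' Defines the study conditions emulated by the synthetic-data generators:
#' 28 subjects, three drug sessions (placebo PLC, atomoxetine ATX, donepezil
#' DNP), 2 blocks x 280 trials per session with 80\% cue validity, diffusion
#' parameters producing staircased (~75\% correct) performance, and EEG/
#' physiological effect structure mirroring the analysis targets: a positive
#' cue-validity effect on drift rate (+0.17), a positive ATX effect on drift
#' rate (+0.15) with a small interaction (+0.04) and a small ATX slowing of
#' non-decision time; a response-locked centro-parietal ramp whose build-up
#' rate scales with the per-trial drift; cue-locked contralateral alpha
#' suppression (-1 dB); lateral occipito-temporal deflections in the
#' reported latency windows (cue ~70-336 ms, stimulus identity ~352-500 ms,
#' drug ~406-586 ms post-stimulus); and an ATX effect on heart rate, blood
#' pressure and pupil size.
#'
#' @param n_subjects Number of subjects (default 28).
#' @param n_blocks,trials_per_block Session design (default 2 x 280).
#' @param validity Cue validity (default 0.8).
#' @param sessions Drug sessions (default PLC/ATX/DNP).
#' @param null_effects If `TRUE`, zero every condition effect (behavioral,
#'   EEG and physiological) for type-I calibration.
#' @param ... Overrides of any element of the returned list.
#' @return A list of class `generative_config`.
#' @export
generative_config <- function(n_subjects = 28, n_blocks = 2,
                              trials_per_block = 280, validity = 0.8,
                              sessions = c("PLC", "ATX", "DNP"),
                              null_effects = FALSE, ...) {
  cfg <- list(
    n_subjects = n_subjects,
    n_blocks = n_blocks,
    trials_per_block = trials_per_block,
    validity = validity,
    sessions = sessions,
    # group-level diffusion parameters (means, between-subject SDs)
    ddm = list(
      mu_v = 0.8, sd_v = 0.25,
      mu_a = 1.4, sd_a = 0.15,
      mu_t0 = 0.3, sd_t0 = 0.05,
      sv = 0.3
    ),
    # condition effects expressed as regression coefficients under the
    # weighted effect coding (validity -0.8/+0.2; drug -1/+1 vs placebo)
    effects = list(
      v_validity = 0.17,
      v_atx = 0.15,
      v_interaction_atx = 0.04,
      v_dnp = 0,
      t0_atx = 0.02,
      t0_validity = 0
    ),
    eeg = list(
      sfreq = 512,
      epoch = c(-2, 2),
      cue_onset = -1.3,
      noise_1f = 4, noise_1f_exponent = 1,
      noise_white = 0.8,
      alpha_freq = 10,
      alpha_amp = 14,
      alpha_lateralization_db = -1,
      alpha_ramp_start = 0.12, # ramp onset, s after cue onset
      alpha_ramp_end = 0.6,    # plateau reached, s after cue onset
      cpp_gain = 20,           # uV per (evidence/s) of per-trial drift
      cue_bump = list(window = c(0.070, 0.336), amp = 1.5),
      stim_bump = list(window = c(0.352, 0.500), amp = 1.5),
      drug_bump = list(window = c(0.406, 0.586), amp_dnp = 1.5, amp_atx = -0.8)
    ),
    physio = list(
      hr = list(mean = 65, sd_subj = 6, sd_meas = 2.5, atx = 8),
      bp_sys = list(mean = 120, sd_subj = 7, sd_meas = 3, atx = 7),
      bp_dia = list(mean = 75, sd_subj = 5, sd_meas = 2.5, atx = 4),
      vas = list(mean = 5, sd_subj = 0.8, sd_meas = 0.5, atx = 0),
      pupil = list(dark = 6.5, bright = 4.5, sd_subj = 0.4, sd_meas = 0.1,
                   atx = 0.5, sfreq = 1000),
      timepoints = c("baseline", "4h", "7h")
    ),
    null_effects = null_effects
  )
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  if (cfg$null_effects) {
    cfg$effects <- purrr::map(cfg$effects, ~0)
    cfg$eeg$alpha_lateralization_db <- 0
    cfg$eeg$cue_bump$amp <- 0
    cfg$eeg$stim_bump$amp <- 0
    cfg$eeg$drug_bump$amp_dnp <- 0
    cfg$eeg$drug_bump$amp_atx <- 0
    cfg$physio$hr$atx <- 0
    cfg$physio$bp_sys$atx <- 0
    cfg$physio$bp_dia$atx <- 0
    cfg$physio$pupil$atx <- 0
  }
  class(cfg) <- c("generative_config", "list")
  cfg
}

# per-trial drift / boundary / non-decision given subject params and design;
# ATX sessions follow the pairwise weighted-effect model exactly (code +1,
# non-ATX -1); DNP deltas (default 0) shift DNP sessions relative to PLC
.trial_ddm_params <- function(design, subj, effects) {
  val_code <- ifelse(design$validity == "valid", 0.2, -0.8)
  atx_code <- ifelse(design$drug == "ATX", 1, -1)
  is_dnp <- design$drug == "DNP"
  v <- subj$v + effects$v_validity * val_code +
    effects$v_atx * atx_code +
    effects$v_interaction_atx * val_code * atx_code +
    2 * effects$v_dnp * is_dnp
  t0 <- subj$t0 + effects$t0_atx * atx_code +
    effects$t0_validity * val_code
  list(v = v, a = rep(subj$a, nrow(design)), t0 = pmax(t0, 0.05))
}

#' Generate a study-shaped behavioral dataset
#'
#' Draws subject-level diffusion parameters from the configured group
#' distributions, builds balanced session designs per subject and drug
#' session, applies the configured condition effects through the same
#' weighted effect coding the hierarchical fitter uses, and simulates RT and
#' accuracy from the diffusion process.
#'
#' @param config A [generative_config()].
#' @param seed Integer seed (fully determines the output).
#' @return A trial tibble: `subject`, `drug`, `block`, `trial`, `cue_side`,
#'   `stim_side`, `orientation`, `validity`, `rt` (s), `accuracy`,
#'   `response`, plus the per-trial generative drift `v_true`.
#' @export
generate_behavior <- function(config = generative_config(), seed = 1L) {
  old <- .Random.seed_exists()
  on.exit(old$restore(), add = TRUE)
  set.seed(seed)

  dd <- config$ddm
  subj_tbl <- tibble::tibble(
    subject = sprintf("S%02d", seq_len(config$n_subjects)),
    v = rnorm(config$n_subjects, dd$mu_v, dd$sd_v),
    a = pmax(rnorm(config$n_subjects, dd$mu_a, dd$sd_a), 0.5),
    t0 = pmax(rnorm(config$n_subjects, dd$mu_t0, dd$sd_t0), 0.1)
  )

  out <- purrr::map_dfr(seq_len(config$n_subjects), function(si) {
    subj <- subj_tbl[si, ]
    purrr::map_dfr(config$sessions, function(drug) {
      dseed <- seed * 10000L + si * 10L + match(drug, config$sessions)
      design <- generate_session_design(
        config$n_blocks, config$trials_per_block,
        validity = config$validity, drug = drug, seed = dseed
      )
      tp <- .trial_ddm_params(design, subj, config$effects)
      rts <- numeric(nrow(design))
      accs <- integer(nrow(design))
      for (i in seq_len(nrow(design))) {
        sim <- .ddm_simulate_cpp(1L, tp$v[i], tp$a[i], tp$a[i] / 2, tp$t0[i],
                                 dd$sv, 1e-3, 20,
                                 as.numeric(dseed) * 4096 + i)
        rts[i] <- sim$rt[1]
        accs[i] <- sim$accuracy[1]
      }
      other <- function(o) ifelse(o == "cw", "ccw", "cw")
      design |>
        dplyr::mutate(
          subject = subj$subject,
          rt = rts,
          accuracy = accs,
          response = ifelse(accs == 1, .data$orientation,
                            other(.data$orientation)),
          v_true = tp$v,
          t0_true = tp$t0
        ) |>
        dplyr::select("subject", dplyr::everything())
    })
  })
  out
}

# spectrally shaped 1/f^exponent Gaussian noise, one trace
.pink_noise <- function(n, sfreq, exponent = 1) {
  white <- rnorm(n)
  fr <- fft(white)
  f <- c(1, seq_len(n - 1)) # avoid DC blowup
  f <- pmin(f, n - f + 1)   # mirrored frequency index
  scale <- 1 / (f^(exponent / 2))
  x <- Re(fft(fr * scale, inverse = TRUE)) / n
  x / sd(x)
}

.gauss_bump <- function(times, window, amp) {
  ctr <- mean(window)
  sdv <- diff(window) / 4
  amp * exp(-(times - ctr)^2 / (2 * sdv^2))
}

#' Generate synthetic EEG epochs for one subject and session
#'
#' Builds stimulus-locked 64-channel epochs (default -2 to 2 s at 512 Hz)
#' containing: spectrally shaped 1/f background noise; occipital alpha
#' oscillators whose contralateral-to-cue amplitude ramps down after cue
#' onset to the configured lateralization (in dB of power); a centro-parietal
#' ramp rising from stimulus onset + t0 to the trial's response, with
#' build-up rate proportional to the per-trial drift; lateral
#' occipito-temporal deflections in the configured cue / stimulus-identity /
#' drug latency windows; and white sensor noise. Channel geometry is the
#' idealized spherical 10-10 layout.
#'
#' @param config A [generative_config()].
#' @param behavior Trial tibble from [generate_behavior()] (RTs drive the
#'   ramp timing); supply one subject x session subset or use `subject`/
#'   `drug` to select it.
#' @param subject,drug Select the subject/session to synthesize.
#' @param seed Integer seed.
#' @return An `eeg_epochs` object (stimulus-locked) whose meta is the
#'   behavior subset (trials without a usable RT are skipped with a message).
#' @export
generate_eeg <- function(config = generative_config(), behavior,
                         subject = behavior$subject[1],
                         drug = behavior$drug[1], seed = 1L) {
  old <- .Random.seed_exists()
  on.exit(old$restore(), add = TRUE)
  set.seed(seed)

  ec <- config$eeg
  meta <- behavior |>
    dplyr::filter(.data$subject == !!subject, .data$drug == !!drug)
  if (!nrow(meta)) stop("no behavior rows for that subject/session",
                        call. = FALSE)
  usable <- !is.na(meta$rt) & (meta$rt < max(ec$epoch) - 0.2)
  if (!all(usable)) {
    message(sum(!usable), " trial(s) skipped: no response inside the epoch")
    meta <- meta[usable, ]
  }

  sf <- ec$sfreq
  times <- seq(ec$epoch[1], by = 1 / sf, length.out = diff(ec$epoch) * sf)
  ns <- length(times)
  mont <- standard_montage()
  nch <- nrow(mont)
  ntr <- nrow(meta)

  alpha_rois <- roi_spec("occipital")
  stim_rois <- roi_spec("stimulus")
  cpp_chans <- roi_channels(roi_spec("cpp"))
  lix_a <- match(alpha_rois$left, mont$channel)
  rix_a <- match(alpha_rois$right, mont$channel)
  lix_s <- match(stim_rois$left, mont$channel)
  rix_s <- match(stim_rois$right, mont$channel)
  cix <- match(cpp_chans, mont$channel)

  # amplitude ratio realizing the configured power lateralization in dB;
  # suppression ramps in after the cue and plateaus well before the stimulus
  amp_ratio <- 10^(ec$alpha_lateralization_db / 20)
  ramp <- rep(1, ns)
  r0 <- ec$cue_onset + ec$alpha_ramp_start
  r1 <- ec$cue_onset + ec$alpha_ramp_end
  ramp_sel <- times >= r0 & times < r1
  ramp[ramp_sel] <- 1 + (amp_ratio - 1) * (times[ramp_sel] - r0) / (r1 - r0)
  ramp[times >= r1] <- amp_ratio

  data <- array(0, c(ntr, nch, ns))
  for (tr in seq_len(ntr)) {
    m <- matrix(0, nch, ns)
    for (ch in seq_len(nch)) {
      m[ch, ] <- ec$noise_1f * .pink_noise(ns, sf, ec$noise_1f_exponent) +
        ec$noise_white * rnorm(ns)
    }
    cue_left <- meta$cue_side[tr] == "left"
    # alpha oscillators: contra-to-cue hemisphere is suppressed after the cue
    ph_l <- runif(1, 0, 2 * pi)
    ph_r <- runif(1, 0, 2 * pi)
    osc_l <- ec$alpha_amp * sin(2 * pi * ec$alpha_freq * times + ph_l)
    osc_r <- ec$alpha_amp * sin(2 * pi * ec$alpha_freq * times + ph_r)
    if (cue_left) osc_r <- osc_r * ramp else osc_l <- osc_l * ramp
    m[lix_a, ] <- sweep(m[lix_a, , drop = FALSE], 2, osc_l, `+`)
    m[rix_a, ] <- sweep(m[rix_a, , drop = FALSE], 2, osc_r, `+`)

    # centro-parietal ramp: starts at t0, peaks at the response, decays
    rt <- meta$rt[tr]
    t0 <- if ("t0_true" %in% names(meta)) meta$t0_true[tr] else 0.3
    vtr <- if ("v_true" %in% names(meta)) abs(meta$v_true[tr]) else 1
    slope <- ec$cpp_gain * vtr
    up <- times >= t0 & times <= rt
    m[cix, up] <- sweep(m[cix, up, drop = FALSE], 2,
                        slope * (times[up] - t0), `+`)
    peak <- slope * (rt - t0)
    down <- times > rt & times <= rt + 0.3
    m[cix, down] <- sweep(m[cix, down, drop = FALSE], 2,
                          peak * (1 - (times[down] - rt) / 0.3), `+`)

    # lateral occipito-temporal deflections (stimulus-locked windows)
    stim_left <- meta$stim_side[tr] == "left"
    cued_ix <- if (cue_left) rix_s else lix_s     # hemi contra to cue
    uncued_ix <- if (cue_left) lix_s else rix_s
    target_ix <- if (stim_left) rix_s else lix_s  # hemi contra to stimulus
    base_bump <- .gauss_bump(times, ec$cue_bump$window, ec$cue_bump$amp)
    m[cued_ix, ] <- sweep(m[cued_ix, , drop = FALSE], 2, base_bump, `+`)
    stim_bump <- .gauss_bump(times, ec$stim_bump$window, ec$stim_bump$amp)
    m[target_ix, ] <- sweep(m[target_ix, , drop = FALSE], 2, stim_bump, `+`)
    drug_amp <- switch(meta$drug[tr],
                       DNP = ec$drug_bump$amp_dnp,
                       ATX = ec$drug_bump$amp_atx, 0)
    if (drug_amp != 0) {
      db <- .gauss_bump(times, ec$drug_bump$window, drug_amp)
      m[c(lix_s, rix_s), ] <- sweep(m[c(lix_s, rix_s), , drop = FALSE], 2,
                                    db, `+`)
    }
    data[tr, , ] <- m
  }

  eeg_epochs(data, times, sf, mont, meta = meta, lock = "stimulus",
             units = "uV")
}

#' Generate a synthetic physiological panel
#'
#' Heart rate, systolic/diastolic blood pressure and 16 VAS items per
#' subject x session x timepoint (baseline, +4 h, +7 h), plus a 30 s
#' dark/bright pupil trace per subject x session with seeded blinks. The ATX
#' session adds the configured offsets at the post-baseline timepoints
#' (pupil: at both windows).
#'
#' @param config A [generative_config()].
#' @param seed Integer seed.
#' @return A list of class `physio_panel`: `vitals` (long tibble with
#'   heart_rate, bp_sys, bp_dia), `vas` (tibble with item columns `vas_1` ..
#'   `vas_16`), and `pupil` (tibble with one list-column trace and blink
#'   annotations per subject x session).
#' @export
generate_physio <- function(config = generative_config(), seed = 1L) {
  old <- .Random.seed_exists()
  on.exit(old$restore(), add = TRUE)
  set.seed(seed)

  pc <- config$physio
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  grid <- tidyr::expand_grid(
    subject = subjects, drug = config$sessions, timepoint = pc$timepoints
  )
  subj_base <- tibble::tibble(
    subject = subjects,
    hr0 = rnorm(length(subjects), pc$hr$mean, pc$hr$sd_subj),
    sys0 = rnorm(length(subjects), pc$bp_sys$mean, pc$bp_sys$sd_subj),
    dia0 = rnorm(length(subjects), pc$bp_dia$mean, pc$bp_dia$sd_subj),
    vas0 = rnorm(length(subjects), pc$vas$mean, pc$vas$sd_subj)
  )
  post <- function(tp) tp != "baseline"
  vitals <- grid |>
    dplyr::left_join(subj_base, by = "subject") |>
    dplyr::mutate(
      atx_on = (.data$drug == "ATX") & post(.data$timepoint),
      heart_rate = .data$hr0 + pc$hr$atx * .data$atx_on +
        rnorm(dplyr::n(), 0, pc$hr$sd_meas),
      bp_sys = .data$sys0 + pc$bp_sys$atx * .data$atx_on +
        rnorm(dplyr::n(), 0, pc$bp_sys$sd_meas),
      bp_dia = .data$dia0 + pc$bp_dia$atx * .data$atx_on +
        rnorm(dplyr::n(), 0, pc$bp_dia$sd_meas)
    ) |>
    dplyr::mutate(bp_sys = pmax(.data$bp_sys, .data$bp_dia + 10)) |>
    dplyr::select("subject", "drug", "timepoint", "heart_rate", "bp_sys",
                  "bp_dia")

  vas <- grid
  vas_base <- subj_base$vas0[match(grid$subject, subjects)] +
    pc$vas$atx * (grid$drug == "ATX") * post(grid$timepoint)
  for (k in 1:16) {
    vas[[paste0("vas_", k)]] <- pmin(pmax(
      vas_base + rnorm(nrow(grid), 0, pc$vas$sd_meas), 0), 10)
  }

  sf <- pc$pupil$sfreq
  pupil <- tidyr::expand_grid(subject = subjects, drug = config$sessions) |>
    dplyr::mutate(purrr::map2_dfr(.data$subject, .data$drug, function(su, dr) {
      dshift <- pc$pupil$atx * (dr == "ATX")
      d_dark <- pc$pupil$dark + rnorm(1, 0, pc$pupil$sd_subj) + dshift
      d_bright <- pc$pupil$bright + rnorm(1, 0, pc$pupil$sd_subj) + dshift
      nwin <- 15 * sf
      tr <- c(rep(d_dark, nwin), rep(d_bright, nwin))
      # smooth light-response transition
      trans <- seq(0, 1, length.out = 2 * sf)
      tr[nwin + seq_along(trans)] <- d_dark + (d_bright - d_dark) * trans
      tr <- tr + pc$pupil$sd_meas * .pink_noise(length(tr), sf, 1)
      n_blinks <- 3 + rbinom(1, 3, 0.5)
      onsets <- sort(runif(n_blinks, 1, 29))
      blinks <- tibble::tibble(onset = onsets, offset = onsets + 0.15)
      for (b in seq_len(n_blinks)) {
        i0 <- round(blinks$onset[b] * sf); i1 <- round(blinks$offset[b] * sf)
        tr[i0:i1] <- tr[i0:i1] - 3
      }
      tibble::tibble(trace = list(tr), blinks = list(blinks))
    }))

  structure(list(vitals = vitals, vas = vas, pupil = pupil),
            class = "physio_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
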