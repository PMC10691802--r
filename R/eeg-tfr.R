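#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with complex Morlet wavelets and returns
#' single-trial power. The number of wavelet cycles grows with frequency as
#' `cycles(f) = f / 2` (so e.g. 5 cycles at 10 Hz), giving a fixed temporal
#' Gaussian SD of `1 / (4 pi)` s across frequencies. Wavelets are normalized
#' to unit energy; power is the squared magnitude of the analytic
#' convolution.
#'
#' @param epochs An `eeg_epochs`.
#' @param freqs Frequencies in Hz (default 2 to 40 in steps of 2).
#' @param cycle_rule Function mapping frequency to cycle count
#'   (default `f / 2`).
#' @param channels Optional channel subset to transform.
#' @param support SD multiple defining the wavelet extent (default 3.5).
#' @return An `eeg_tfr` object: `power` array (trials x channels x freqs x
#'   samples, raw power), `freqs`, `times`, `channels`, `meta`,
#'   `units = "power"`.
#' @export
morlet_tfr <- function(epochs, freqs = seq(2, 40, by = 2),
                       cycle_rule = function(f) f / 2,
                       channels = epochs$channels$channel, support = 3.5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ep <- select_channels(epochs, channels)
  nd <- dim(ep$data)
  n_samp <- nd[3]
  dt <- 1 / ep$sfreq

  # wavelets; error if the epoch cannot hold the longest one
  wavelets <- lapply(freqs, function(f) {
    cyc <- cycle_rule(f)
    sigma_t <- cyc / (2 * pi * f)
    half <- ceiling(support * sigma_t / dt)
    if (2 * half + 1 > n_samp) {
      stop(sprintf("epoch too short for the %g Hz wavelet (needs %d samples, have %d)",
                   f, 2 * half + 1, n_samp), call. = FALSE)
    }
    tw <- seq(-half, half) * dt
    w <- exp(-tw^2 / (2 * sigma_t^2)) * exp(1i * 2 * pi * f * tw)
    w / sqrt(sum(Mod(w)^2) * dt) # unit energy
  })

  n_fft <- stats::nextn(n_samp + max(lengths(wavelets)) - 1L, 2)
  Wf <- lapply(wavelets, function(w) fft(c(w, rep(0, n_fft - length(w)))))

  power <- array(NA_real_, c(nd[1], nd[2], length(freqs), n_samp))
  for (tr in seq_len(nd[1])) {
    for (chn in seq_len(nd[2])) {
      x <- ep$data[tr, chn, ]
      Xf <- fft(c(x, rep(0, n_fft - n_samp)))
      for (fi in seq_along(freqs)) {
        conv <- fft(Xf * Wf[[fi]], inverse = TRUE) / n_fft
        half <- (length(wavelets[[fi]]) - 1L) / 2L
        y <- conv[(half + 1L):(half + n_samp)] * dt
        power[tr, chn, fi, ] <- Mod(y)^2
      }
    }
  }
  structure(
    list(power = power, freqs = freqs, times = ep$times, sfreq = ep$sfreq,
         channels = ep$channels, meta = ep$meta, lock = ep$lock,
         units = "power"),
    class = "eeg_tfr"
  )
}

#' @export
print.eeg_tfr <- function(x, ...) {
  cat(sprintf(
    "<eeg_tfr> %d trials x %d channels x %d freqs x %d samples (%s), %s-locked\n",
    dim(x$power)[1], dim(x$power)[2], dim(x$power)[3], dim(x$power)[4],
    x$units, x$lock
  ))
  invisible(x)
}

#' Decibel baseline normalization of time-frequency power
#'
#' `power(dB) = 10 * log10(signal / baseline)`, with the baseline taken as
#' the mean power in the baseline window per channel and frequency. For
#' condition-level maps the baseline is averaged over trials
#' (`baseline_by = "average"`); for single-trial analyses each trial is
#' normalized by its own baseline (`baseline_by = "trial"`).
#'
#' @param tfr An `eeg_tfr` with raw power.
#' @param baseline_window `c(t_min, t_max)` in epoch time (s). For
#'   stimulus-locked epochs with the cue at -1.3 s, the canonical -250 to
#'   -50 ms pre-cue window is `c(-1.55, -1.35)`.
#' @param baseline_by `"average"` or `"trial"`.
#' @return An `eeg_tfr` in dB.
#' @export
db_normalize <- function(tfr, baseline_window,
                         baseline_by = c("average", "trial")) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (tfr$units != "power") {
    stop("db_normalize expects raw power", call. = FALSE)
  }
  baseline_by <- match.arg(baseline_by)
  bsel <- tfr$times >= baseline_window[1] - 1e-9 &
    tfr$times <= baseline_window[2] + 1e-9
  if (!any(bsel)) stop("baseline window outside the epoch", call. = FALSE)

  base_tr <- apply(tfr$power[, , , bsel, drop = FALSE], c(1, 2, 3), mean)
  if (baseline_by == "average") {
    base_cf <- apply(base_tr, c(2, 3), mean) # channels x freqs
    if (any(base_cf <= 0)) stop("zero baseline power", call. = FALSE)
    tfr$power <- 10 * log10(sweep(tfr$power, c(2, 3), base_cf, `/`))
  } else {
    if (any(base_tr <= 0)) stop("zero baseline power", call. = FALSE)
    tfr$power <- 10 * log10(sweep(tfr$power, c(1, 2, 3), base_tr, `/`))
  }
  tfr$units <- "dB"
  tfr
}

#' Alpha-band lateralization relative to the cued hemifield
#'
#' Averages power over the alpha band per hemisphere ROI, maps each
#' hemisphere to contralateral/ipsilateral relative to the cued side
#' (contra = hemisphere opposite the cue), and returns per-trial time
#' courses plus their difference (lateralization = contra - ipsi; attention
#' to the cued hemifield shows as negative lateralization of dB power).
#'
#' @param tfr An `eeg_tfr` (typically dB-normalized).
#' @param roi A [roi_spec()] with `left`/`right` channel sets (default
#'   occipital).
#' @param band `c(f_min, f_max)` in Hz (default 8-12).
#' @param reference Side column defining contra/ipsi (default `"cue"`).
#' @return Long tibble: `trial`, `time`, `contra`, `ipsi`, `lateralization`.
#' @export
alpha_lateralization <- function(tfr, roi = roi_spec("occipital"),
                                 band = c(8, 12), reference = "cue") {
  stopifnot(inherits(tfr, "eeg_tfr"))
  fsel <- tfr$freqs >= band[1] - 1e-9 & tfr$freqs <= band[2] + 1e-9
  if (!any(fsel)) stop("band outside computed frequencies", call. = FALSE)
  side_col <- paste0(reference, "_side")
  if (!side_col %in% names(tfr$meta)) {
    stop("meta lacks ", side_col, call. = FALSE)
  }
  lix <- match(roi$left, tfr$channels$channel)
  rix <- match(roi$right, tfr$channels$channel)
  if (anyNA(lix) || anyNA(rix)) {
    stop("ROI channels missing from the TFR", call. = FALSE)
  }
  # trials x samples, band- and ROI-averaged
  left_p <- apply(tfr$power[, lix, fsel, , drop = FALSE], c(1, 4), mean)
  right_p <- apply(tfr$power[, rix, fsel, , drop = FALSE], c(1, 4), mean)

  side <- tfr$meta[[side_col]]
  nt <- dim(tfr$power)[1]
  ns <- length(tfr$times)
  contra <- ifelse(side == "left", 1, 0) # cue left -> right hemisphere contra
  contra_p <- ifelse(matrix(contra, nt, ns), right_p, left_p)
  ipsi_p <- ifelse(matrix(contra, nt, ns), left_p, right_p)

  tibble::tibble(
    trial = rep(seq_len(nt), each = ns),
    time = rep(tfr$times, times = nt),
    contra = as.vector(t(contra_p)),
    ipsi = as.vector(t(ipsi_p)),
    lateralization = as.vector(t(contra_p - ipsi_p))
  )
}

#' Per-trial scalar alpha lateralization score
#'
#' Mean lateralization (contra - ipsi alpha power) over a time window;
#' the per-trial input for the alpha-binned sensitivity analysis.
#'
#' @inheritParams alpha_lateralization
#' @param window `c(t_min, t_max)` in s.
#' @return Numeric vector, one score per trial.
#' @export
alpha_trial_scores <- function(tfr, roi = roi_spec("occipital"),
                               band = c(8, 12), window, reference = "cue") {
  lat <- alpha_lateralization(tfr, roi, band, reference)
  lat |>
    dplyr::filter(.data$time >= window[1], .data$time <= window[2]) |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(alpha = mean(.data$lateralization)) |>
    dplyr::pull(.data$alpha)
}

#' Tidy long table of time-frequency power
#'
#' @param x An `eeg_tfr`.
#' @param ... Unused.
#' @return Long tibble: `trial`, `channel`, `freq`, `time`, `power`.
#' @export
tidy.eeg_tfr <- function(x, ...) {
  d <- dim(x$power)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3] * d[4]),
    channel = rep(rep(x$channels$channel, each = d[1]), times = d[3] * d[4]),
    freq = rep(rep(x$freqs, each = d[1] * d[2]), times = d[4]),
    time = rep(x$times, each = d[1] * d[2] * d[3]),
    power = as.vector(x$power)
  )
}
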