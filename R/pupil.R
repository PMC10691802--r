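#' Preprocess a pupil diameter trace
#'
#' Cleans a continuous pupillometry trace: blinks are linearly interpolated,
#' the trace is band-pass filtered (zero-phase forward-backward filtering;
#' default 0.01-10 Hz), and the transient pupil responses evoked by blinks
#' and saccades are estimated by least-squares finite-impulse-response
#' deconvolution and subtracted.
#'
#' @param trace Numeric diameter trace.
#' @param sfreq Sampling rate (Hz, default 1000).
#' @param blinks Tibble with `onset`/`offset` (s) of blink annotations,
#'   or NULL.
#' @param saccades Tibble with `onset` (s) of saccade annotations, or NULL.
#' @param band `c(low, high)` pass band in Hz.
#' @param deconv_window Kernel extent after each event in s (default 6).
#' @param deconv_bin Kernel resolution in s (default 0.05).
#' @param filter_order Butterworth order for the band edges (default 3).
#' @return Cleaned numeric trace (zero-mean by construction of the
#'   high-pass).
#' @details Blink interpolation spans a small pad around each annotation.
#'   The lower band edge (0.01 Hz) has a period far longer than typical
#'   traces, so it acts as slow-drift removal; it is implemented by
#'   subtracting a zero-phase low-pass of the trace, falling back to mean
#'   removal when the trace is shorter than one cutoff period. An error is
#'   raised when blinks cover more than half of the trace.
#' @export
pupil_preprocess <- function(trace, sfreq = 1000, blinks = NULL,
                             saccades = NULL, band = c(0.01, 10),
                             deconv_window = 6, deconv_bin = 0.05,
                             filter_order = 3) {
  n <- length(trace)
  x <- as.numeric(trace)

  blink_mask <- rep(FALSE, n)
  if (!is.null(blinks) && nrow(blinks)) {
    if (any(blinks$onset < 0) || any(blinks$offset > n / sfreq)) {
      stop("blink annotations outside the trace span", call. = FALSE)
    }
    pad <- round(0.05 * sfreq)
    for (i in seq_len(nrow(blinks))) {
      i0 <- max(1L, round(blinks$onset[i] * sfreq) - pad)
      i1 <- min(n, round(blinks$offset[i] * sfreq) + pad)
      blink_mask[i0:i1] <- TRUE
    }
    if (mean(blink_mask) > 0.5) {
      stop("blinks cover more than 50% of the trace", call. = FALSE)
    }
    good <- which(!blink_mask)
    x[blink_mask] <- approx(good, x[good], xout = which(blink_mask),
                            rule = 2)$y
  }

  # band-pass: zero-phase low-pass at the upper edge, slow-drift removal at
  # the lower edge; reflection padding suppresses filtfilt edge transients
  nyq <- sfreq / 2
  pad_filt <- function(x, flt) {
    np <- min(length(x) - 1L, 3L * sfreq)
    padded <- c(2 * x[1] - rev(x[2:(np + 1)]), x,
                2 * x[n] - rev(x[(n - np):(n - 1)]))
    signal::filtfilt(flt, padded)[(np + 1):(np + n)]
  }
  x <- x - mean(x)
  bf_low <- signal::butter(filter_order, band[2] / nyq, type = "low")
  x <- pad_filt(x, bf_low)
  if (n / sfreq > 1 / band[1]) {
    bf_hp <- signal::butter(filter_order, band[1] / nyq, type = "low")
    x <- x - pad_filt(x, bf_hp)
  }

  # FIR deconvolution of blink/saccade responses (binned impulse basis, OLS)
  events <- list()
  if (!is.null(blinks) && nrow(blinks)) events$blink <- blinks$offset
  if (!is.null(saccades) && nrow(saccades)) events$saccade <- saccades$onset
  n_lag <- round(deconv_window / deconv_bin)
  if (length(events) && n_lag >= 1) {
    bin_len <- round(deconv_bin * sfreq)
    cols <- list()
    for (ev in names(events)) {
      onsets <- round(events[[ev]] * sfreq)
      for (l in seq_len(n_lag)) {
        col <- numeric(n)
        for (o in onsets) {
          i0 <- o + (l - 1L) * bin_len + 1L
          i1 <- min(o + l * bin_len, n)
          if (i0 <= n) col[i0:max(i0, i1)] <- 1
        }
        cols[[paste0(ev, "_", l)]] <- col
      }
    }
    X <- do.call(cbind, cols)
    keep <- colSums(X) > 0
    if (any(keep)) {
      X <- X[, keep, drop = FALSE]
      beta <- stats::lm.fit(X, x)$coefficients
      beta[is.na(beta)] <- 0
      x <- x - as.vector(X %*% beta)
    }
  }
  x
}
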