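#' EEG epochs container
#'
#' Light S3 container for an epoched EEG tensor: `data` is a numeric array
#' of trials x channels x samples, `times` are seconds relative to the event
#' in `lock`, `channels` is a position table (see [standard_montage()]), and
#' `meta` is a tibble of trial-level covariates (one row per trial;
#' typically cue side, stimulus side, orientation, validity, accuracy, rt).
#'
#' @param data trials x channels x samples array.
#' @param times Numeric vector of sample times (s), strictly increasing.
#' @param sfreq Sampling rate (Hz).
#' @param channels Tibble with at least `channel`; positions `x`, `y`, `z`
#'   are required for CSD.
#' @param meta Tibble with one row per trial.
#' @param lock Event the epochs are locked to: `"stimulus"`, `"cue"` or
#'   `"response"`.
#' @param units Data units (default `"uV"`; `"uV/cm^2"` after CSD).
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, times, sfreq, channels, meta = NULL,
                       lock = c("stimulus", "cue", "response"),
                       units = "uV") {
  lock <- match.arg(lock)
  stopifnot(length(dim(data)) == 3L)
  if (length(times) != dim(data)[3]) {
    stop("`times` length must match the sample dimension", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (nrow(channels) != dim(data)[2]) {
    stop("channel table must match the channel dimension", call. = FALSE)
  }
  if (is.null(meta)) meta <- tibble::tibble(.rows = dim(data)[1])
  if (nrow(meta) != dim(data)[1]) {
    stop("`meta` must have one row per trial", call. = FALSE)
  }
  structure(
    list(data = data, times = times, sfreq = sfreq, channels = channels,
         meta = meta, lock = lock, units = units),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, %s-locked [%.3f, %.3f] s (%s)\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq, x$lock,
    min(x$times), max(x$times), x$units
  ))
  invisible(x)
}

#' Number of trials/channels/samples
#' @param x An `eeg_epochs`.
#' @export
n_trials <- function(x) dim(x$data)[1]

.chan_index <- function(epochs, channels) {
  ix <- match(channels, epochs$channels$channel)
  if (anyNA(ix)) {
    stop("channel(s) not present: ",
         paste(channels[is.na(ix)], collapse = ", "), call. = FALSE)
  }
  ix
}

#' Select a subset of channels
#' @param epochs An `eeg_epochs`.
#' @param channels Channel names to keep.
#' @return An `eeg_epochs` restricted to those channels.
#' @export
select_channels <- function(epochs, channels) {
  ix <- .chan_index(epochs, channels)
  epochs$data <- epochs$data[, ix, , drop = FALSE]
  epochs$channels <- epochs$channels[ix, ]
  epochs
}

#' Re-lock, crop, baseline and downsample epochs
#'
#' Re-expresses stimulus-locked epochs around a different event, crops to an
#' analysis window, subtracts the per-trial per-channel mean over a baseline
#' window, and optionally downsamples (anti-alias low-pass, then decimation
#' by an integer factor).
#'
#' @param epochs An `eeg_epochs` (stimulus- or cue-locked).
#' @param lock Target lock: `"stimulus"`, `"cue"` or `"response"`. Cue onset
#'   is taken from `cue_onset`; response times from `meta$rt`. Trials whose
#'   response-locked window falls outside the recorded span are dropped with
#'   a message.
#' @param window `c(t_min, t_max)` in seconds relative to the new lock.
#' @param baseline `c(b_min, b_max)` in seconds relative to the new lock, or
#'   `NULL` to skip baseline correction. Must lie inside `window`.
#' @param downsample_to Target rate in Hz (must divide `sfreq`), or `NULL`.
#' @param cue_onset Cue onset in stimulus time (default -1.3 s: 300 ms cue
#'   plus 1000 ms cue-stimulus interval).
#' @return A new `eeg_epochs`.
#' @export
epoch_and_baseline <- function(epochs, lock = "stimulus",
                               window = c(min(epochs$times), max(epochs$times)),
                               baseline = NULL, downsample_to = NULL,
                               cue_onset = -1.3) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  lock <- match.arg(lock, c("stimulus", "cue", "response"))

  data <- epochs$data
  times <- epochs$times
  meta <- epochs$meta
  dt <- 1 / epochs$sfreq

  if (lock == "cue" && epochs$lock == "stimulus") {
    times <- times - cue_onset
  } else if (lock == "response") {
    if (!"rt" %in% names(meta)) {
      stop("response locking needs `rt` in meta", call. = FALSE)
    }
    n_new <- length(seq(window[1], window[2] - 1e-9, by = dt))
    keep <- logical(nrow(meta))
    out <- array(NA_real_, c(nrow(meta), dim(data)[2], n_new))
    for (i in seq_len(nrow(meta))) {
      rt <- meta$rt[i]
      if (is.na(rt)) next
      i0 <- which.min(abs(times - (rt + window[1])))
      idx <- i0 + seq_len(n_new) - 1L
      if (abs(times[i0] - (rt + window[1])) > dt || max(idx) > length(times)) next
      out[i, , ] <- data[i, , idx]
      keep[i] <- TRUE
    }
    if (!all(keep)) {
      message(sum(!keep), " trial(s) dropped: response window outside epoch")
    }
    data <- out[keep, , , drop = FALSE]
    meta <- meta[keep, ]
    times <- seq(window[1], by = dt, length.out = n_new)
  } else if (lock != epochs$lock && !(lock == "stimulus" && epochs$lock == "stimulus")) {
    stop("cannot re-lock ", epochs$lock, "-locked epochs to ", lock,
         call. = FALSE)
  }

  if (lock != "response") {
    sel <- times >= window[1] - 1e-9 & times <= window[2] + 1e-9
    if (!any(sel)) stop("window outside the epoch span", call. = FALSE)
    data <- data[, , sel, drop = FALSE]
    times <- times[sel]
  }

  if (!is.null(downsample_to)) {
    factor <- epochs$sfreq / downsample_to
    if (abs(factor - round(factor)) > 1e-9) {
      stop("downsample factor must be an integer", call. = FALSE)
    }
    factor <- as.integer(round(factor))
    if (factor > 1L) {
      bf <- signal::butter(4, 0.8 / factor, type = "low")
      nd <- dim(data)
      flat <- matrix(aperm(data, c(3, 1, 2)), nrow = nd[3])
      flat <- apply(flat, 2, function(x) signal::filtfilt(bf, x))
      keep_ix <- seq(1L, nd[3], by = factor)
      flat <- flat[keep_ix, , drop = FALSE]
      data <- aperm(array(flat, c(length(keep_ix), nd[1], nd[2])), c(2, 3, 1))
      times <- times[keep_ix]
    }
  }

  if (!is.null(baseline)) {
    if (baseline[1] < times[1] - 1e-9 || baseline[2] > times[length(times)] + 1e-9) {
      stop("baseline window must lie inside the epoch window", call. = FALSE)
    }
    bsel <- times >= baseline[1] - 1e-9 & times <= baseline[2] + 1e-9
    bmean <- apply(data[, , bsel, drop = FALSE], c(1, 2), mean)
    data <- sweep(data, c(1, 2), bmean, `-`)
  }

  eeg_epochs(data, times,
             sfreq = if (is.null(downsample_to)) epochs$sfreq else downsample_to,
             channels = epochs$channels, meta = meta, lock = lock,
             units = epochs$units)
}

#' Simple peak-to-peak artifact rejection
#'
#' Drops trials whose peak-to-peak amplitude exceeds a threshold on any
#' channel. This is a deliberately simple amplitude-based rejector; it does
#' not detect or repair bad channels.
#'
#' @param epochs An `eeg_epochs`.
#' @param threshold Peak-to-peak rejection threshold in the data units
#'   (default 150 uV).
#' @return `eeg_epochs` with offending trials removed; the number removed is
#'   reported via `message()`.
#' @export
reject_artifacts <- function(epochs, threshold = 150) {
  ptp <- apply(epochs$data, c(1, 2), function(x) diff(range(x)))
  bad <- apply(ptp, 1, max) > threshold
  if (any(bad)) {
    message(sum(bad), " trial(s) rejected (peak-to-peak > ", threshold, ")")
    epochs$data <- epochs$data[!bad, , , drop = FALSE]
    epochs$meta <- epochs$meta[!bad, ]
  }
  epochs
}

#' Label hemispheric ROI traces as cued/uncued and target/noise
#'
#' For each trial, averages the left and right ROI channels and labels each
#' hemisphere's trace by the attentional status of the hemifield it
#' represents (a hemisphere represents the contralateral hemifield):
#' the hemisphere contralateral to the cue carries the *cued* location, the
#' one contralateral to the stimulus carries the *target*, the other the
#' *noise* patch. `reference` selects which side defines contra/ipsi.
#'
#' @param epochs An `eeg_epochs` whose meta has `cue_side` (and `stim_side`
#'   for stimulus labeling).
#' @param roi A [roi_spec()] with `left` and `right` channel sets.
#' @param reference `"cue"` or `"stimulus"`.
#' @return A long tibble: `trial`, `hemisphere`, `role` (`"contra"`/
#'   `"ipsi"` relative to `reference`), `attention` (`"cued"`/`"uncued"`),
#'   `stimulus` (`"target"`/`"noise"`, `NA` when `stim_side` is absent),
#'   `time`, `value`. Trials with a missing reference side are dropped with
#'   a message.
#' @export
assign_contra_ipsi <- function(epochs, roi = roi_spec("stimulus"),
                               reference = c("cue", "stimulus")) {
  reference <- match.arg(reference)
  meta <- epochs$meta
  side_col <- if (reference == "cue") "cue_side" else "stim_side"
  if (!side_col %in% names(meta)) {
    stop("meta lacks ", side_col, call. = FALSE)
  }
  ok <- !is.na(meta[[side_col]])
  if (!all(ok)) {
    message(sum(!ok), " trial(s) dropped: missing ", side_col)
  }

  lix <- .chan_index(epochs, roi$left)
  rix <- .chan_index(epochs, roi$right)
  left_tr <- apply(epochs$data[ok, lix, , drop = FALSE], c(1, 3), mean)
  right_tr <- apply(epochs$data[ok, rix, , drop = FALSE], c(1, 3), mean)
  meta <- meta[ok, ]
  nt <- nrow(meta)
  times <- epochs$times

  hemi_info <- function(hemi) {
    ref_side <- meta[[side_col]]
    role <- ifelse(ref_side == hemi, "ipsi", "contra")
    attention <- if ("cue_side" %in% names(meta)) {
      ifelse(meta$cue_side == hemi, "uncued", "cued")
    } else NA_character_
    stimulus <- if ("stim_side" %in% names(meta)) {
      ifelse(meta$stim_side == hemi, "noise", "target")
    } else NA_character_
    tibble::tibble(
      trial = rep(seq_len(nt), each = length(times)),
      hemisphere = hemi,
      role = rep(role, each = length(times)),
      attention = rep(attention, each = length(times)),
      stimulus = rep(stimulus, each = length(times)),
      time = rep(times, times = nt),
      value = as.vector(t(if (hemi == "left") left_tr else right_tr))
    )
  }
  dplyr::bind_rows(hemi_info("left"), hemi_info("right"))
}

#' Centro-parietal positivity peak and build-up rate
#'
#' From response-locked epochs, computes per trial the CPP peak -- the ROI
#' average amplitude at the response sample (t = 0) -- and the CPP slope,
#' the ordinary-least-squares slope of the ROI-average trace over the
#' pre-response window (default -250 to 0 ms).
#'
#' @param response_locked Response-locked `eeg_epochs`.
#' @param roi Channel set (default the centro-parietal [roi_spec()]).
#' @param slope_window `c(t_min, t_max)` in s relative to the response.
#' @return A tibble with the epoch meta plus `cpp_peak` and `cpp_slope`
#'   (units of the data per s).
#' @export
cpp_metrics <- function(response_locked, roi = roi_spec("cpp"),
                        slope_window = c(-0.25, 0)) {
  epochs <- response_locked
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (epochs$lock != "response") {
    stop("cpp_metrics needs response-locked epochs", call. = FALSE)
  }
  if (slope_window[1] < min(epochs$times) - 1e-9 ||
      slope_window[2] > max(epochs$times) + 1e-9) {
    stop("slope window outside the epoch", call. = FALSE)
  }
  chans <- if (inherits(roi, "roi_spec")) roi_channels(roi) else roi
  ix <- .chan_index(epochs, chans)
  tr <- apply(epochs$data[, ix, , drop = FALSE], c(1, 3), mean)

  t0_ix <- which.min(abs(epochs$times))
  wsel <- epochs$times >= slope_window[1] - 1e-9 &
    epochs$times <= slope_window[2] + 1e-9
  tw <- epochs$times[wsel]
  tw_c <- tw - mean(tw)
  denom <- sum(tw_c^2)
  slopes <- as.vector(tr[, wsel, drop = FALSE] %*% tw_c) / denom

  dplyr::bind_cols(
    epochs$meta,
    tibble::tibble(cpp_peak = tr[, t0_ix], cpp_slope = slopes)
  )
}

#' Condition-average ERP as a tidy table
#'
#' @param epochs An `eeg_epochs`.
#' @param channels Channels to include (default all).
#' @param by Meta columns to average within (default none: grand average).
#' @return Long tibble: grouping columns, `channel`, `time`, `value`.
#' @export
erp_table <- function(epochs, channels = epochs$channels$channel,
                      by = character()) {
  ix <- .chan_index(epochs, channels)
  groups <- if (length(by)) {
    interaction(epochs$meta[by], drop = TRUE, sep = "|")
  } else factor(rep("all", n_trials(epochs)))
  purrr::map_dfr(levels(groups), function(g) {
    sel <- groups == g
    avg <- apply(epochs$data[sel, ix, , drop = FALSE], c(2, 3), mean)
    out <- tibble::tibble(
      channel = rep(channels, times = length(epochs$times)),
      time = rep(epochs$times, each = length(channels)),
      value = as.vector(avg)
    )
    if (length(by)) {
      vals <- strsplit(g, "|", fixed = TRUE)[[1]]
      for (k in seq_along(by)) out[[by[k]]] <- vals[k]
    }
    out
  })
}
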