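#' Mean arterial pressure
#'
#' `MAP = diastolic + (systolic - diastolic) / 3`. Linear in both inputs and
#' bounded between the diastolic and systolic values.
#'
#' @param dia Diastolic blood pressure (mmHg).
#' @param sys Systolic blood pressure (mmHg); must be >= `dia`.
#' @return MAP in mmHg.
#' @examples
#' mean_arterial_pressure(80, 120) # 93.33
#' @export
mean_arterial_pressure <- function(dia, sys) {
  if (any(sys < dia)) {
    stop("systolic pressure must be >= diastolic", call. = FALSE)
  }
  dia + (sys - dia) / 3
}

#' Default 16-item visual-analogue-scale category assignment
#'
#' The standard 16-item mood/arousal instrument aggregates into three
#' categories: 9 alertness items, 5 contentedness items and 2 calmness
#' items. The exact assignment is configurable because instruments differ in
#' item order; this default follows the conventional layout.
#'
#' @return Named list of item indices.
#' @export
vas_default_mapping <- function() {
  list(
    alertness = c(1, 3, 4, 5, 10, 11, 12, 13, 16),
    contentedness = c(2, 6, 7, 9, 15),
    calmness = c(8, 14)
  )
}

#' Aggregate 16 VAS item scores into three categories
#'
#' Item scores are the marked positions in cm from the left end of each
#' scale; category scores are the means of the assigned items.
#'
#' @param items Numeric vector of exactly 16 item scores (cm), or a matrix
#'   with 16 columns (rows = observations).
#' @param mapping Item-to-category assignment (see [vas_default_mapping()]).
#' @return A tibble with columns `alertness`, `contentedness`, `calmness`.
#' @examples
#' vas_categories(rep(5, 16))
#' @export
vas_categories <- function(items, mapping = vas_default_mapping()) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  if (ncol(items) != 16) {
    stop("expected exactly 16 VAS items, got ", ncol(items), call. = FALSE)
  }
  tibble::tibble(
    alertness = rowMeans(items[, mapping$alertness, drop = FALSE]),
    contentedness = rowMeans(items[, mapping$contentedness, drop = FALSE]),
    calmness = rowMeans(items[, mapping$calmness, drop = FALSE])
  )
}

#' Percentage change from baseline
#'
#' @param value Measurement.
#' @param baseline_value Baseline measurement (non-zero).
#' @return `100 * (value - baseline_value) / baseline_value`.
#' @examples
#' percent_change(110, 100) # +10
#' @export
percent_change <- function(value, baseline_value) {
  if (any(baseline_value == 0)) stop("zero baseline", call. = FALSE)
  100 * (value - baseline_value) / baseline_value
}

#' Dark/bright pupil diameter summary
#'
#' From a trace covering a 15 s dark-background window followed by a 15 s
#' bright-background window, returns the maximal pupil diameter `p_max`
#' (mean over the final 5 s of the dark window) and the minimal diameter
#' `p_min` (mean over the final 5 s of the bright window).
#'
#' @param trace Numeric pupil diameter trace.
#' @param sfreq Sampling rate in Hz (default 1000).
#' @param window_s Duration of each presentation window (default 15).
#' @param average_s Averaging span at the end of each window (default 5).
#' @return A tibble with `p_max` and `p_min`.
#' @export
pupil_darkbright <- function(trace, sfreq = 1000, window_s = 15,
                             average_s = 5) {
  need <- 2 * window_s * sfreq
  if (length(trace) < need) {
    stop("trace truncated: need ", need, " samples, have ", length(trace),
         call. = FALSE)
  }
  w <- window_s * sfreq
  a <- average_s * sfreq
  dark_end <- w
  bright_end <- 2 * w
  tibble::tibble(
    p_max = mean(trace[(dark_end - a + 1):dark_end]),
    p_min = mean(trace[(bright_end - a + 1):bright_end])
  )
}
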