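#' Signal-detection sensitivity and criterion
#'
#' Computes d' = z(H) - z(FA) and criterion c = -(z(H) + z(FA)) / 2 from a
#' trial table, treating clockwise targets as the "signal" class by
#' convention (d' is unaffected by the labeling; criterion flips sign).
#' Extreme rates are handled with the log-linear correction: 0.5 is added to
#' every cell count and 1 to every denominator, keeping z finite at observed
#' rates of 0 or 1.
#'
#' @param trials Tibble with columns `orientation` (`"cw"`/`"ccw"`) and
#'   `response` (`"cw"`/`"ccw"`), or `accuracy` (0/1) from which the response
#'   is reconstructed.
#' @param signal Which orientation counts as signal (default `"cw"`).
#' @return A one-row tibble: `dprime`, `criterion`, `n_signal`, `n_noise`.
#' @examples
#' tr <- tibble::tibble(
#'   orientation = rep(c("cw", "ccw"), each = 4),
#'   response = c("cw", "cw", "cw", "ccw", "ccw", "ccw", "ccw", "cw")
#' )
#' sdt_metrics(tr)
#' @export
sdt_metrics <- function(trials, signal = "cw") {
  if (!"response" %in% names(trials)) {
    if (!"accuracy" %in% names(trials)) {
      stop("need a `response` or `accuracy` column", call. = FALSE)
    }
    other <- function(o) ifelse(o == "cw", "ccw", "cw")
    trials$response <- ifelse(trials$accuracy == 1, trials$orientation,
                              other(trials$orientation))
  }
  noise <- setdiff(c("cw", "ccw"), signal)
  sig_trials <- trials$orientation == signal
  if (sum(sig_trials) == 0 || sum(!sig_trials) == 0) {
    stop("both signal and noise orientations must be present", call. = FALSE)
  }
  n_sig <- sum(sig_trials)
  n_noise <- sum(!sig_trials)
  hits <- sum(sig_trials & trials$response == signal)
  fas <- sum(!sig_trials & trials$response == signal)
  # log-linear correction
  h <- (hits + 0.5) / (n_sig + 1)
  fa <- (fas + 0.5) / (n_noise + 1)
  tibble::tibble(
    dprime = qnorm(h) - qnorm(fa),
    criterion = -(qnorm(h) + qnorm(fa)) / 2,
    n_signal = n_sig,
    n_noise = n_noise
  )
}

#' Per-condition behavioral summary
#'
#' Applies the trial exclusion rules (responses slower than the response
#' deadline are excluded; missed trials carry `rt = NA` and are excluded),
#' then summarises d', criterion and RT per drug x cue-validity cell.
#'
#' @param trials Trial tibble with `drug`, `validity`, `orientation`,
#'   `accuracy` (and/or `response`), `rt` in seconds.
#' @param rt_max Exclusion threshold in seconds (default 1.4; trials with
#'   `rt > rt_max` are excluded).
#' @param extra_groups Additional grouping columns (e.g. `"subject"`).
#' @return A tibble, one row per condition cell: `dprime`, `criterion`,
#'   `mean_rt`, `median_rt`, `n_trials`. Missing cells yield a row of `NA`
#'   with a warning.
#' @export
condition_summary <- function(trials, rt_max = 1.4,
                              extra_groups = character()) {
  kept <- trials |>
    dplyr::filter(!is.na(.data$rt), .data$rt <= rt_max)
  groups <- c(extra_groups, "drug", "validity")
  full_cells <- kept |>
    dplyr::distinct(dplyr::across(dplyr::all_of(extra_groups))) |>
    tidyr::expand_grid(
      drug = unique(trials$drug),
      validity = unique(trials$validity)
    )
  if (!nrow(full_cells)) {
    full_cells <- tidyr::expand_grid(drug = unique(trials$drug),
                                     validity = unique(trials$validity))
  }
  out <- kept |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(function(d, key) {
      s <- sdt_metrics(d)
      tibble::tibble(
        dprime = s$dprime, criterion = s$criterion,
        mean_rt = mean(d$rt), median_rt = median(d$rt),
        n_trials = nrow(d)
      )
    }) |>
    dplyr::ungroup()
  out <- dplyr::left_join(full_cells, out, by = groups)
  if (anyNA(out$n_trials)) {
    warning("empty condition cell(s); rows emitted with NA", call. = FALSE)
    out$n_trials[is.na(out$n_trials)] <- 0L
  }
  out
}

#' Sensitivity binned by prestimulus alpha lateralization
#'
#' Median-splits trials within subject (and within drug session, matching the
#' per-session EEG normalization) into two evenly sized bins of a per-trial
#' lateralized alpha-power score, then computes d' per drug x validity x bin.
#' With an odd trial count the low bin is larger by one trial.
#'
#' @param trials Trial tibble including a per-trial `alpha` column (only
#'   EEG-clean trials should be supplied).
#' @param alpha_col Name of the alpha score column (default `"alpha"`).
#' @return Tibble with one row per subject x drug x validity x alpha_bin.
#' @export
bin_by_alpha <- function(trials, alpha_col = "alpha") {
  stopifnot(alpha_col %in% names(trials))
  group_cols <- intersect(c("subject", "drug"), names(trials))
  binned <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::mutate(
      alpha_bin = ifelse(
        rank(.data[[alpha_col]], ties.method = "first") <=
          ceiling(dplyr::n() / 2),
        "low", "high"
      )
    ) |>
    dplyr::ungroup()
  binned |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(group_cols, "validity", "alpha_bin")
    ))) |>
    dplyr::group_modify(function(d, key) sdt_metrics(d)) |>
    dplyr::ungroup()
}
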