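#' Asymptotic accuracy of a weighted up-down staircase
#'
#' A weighted up-down staircase that increases the stimulus-strength variable
#' by one step after errors and decreases it by `step / ratio` after correct
#' responses equilibrates where expected upward and downward movement cancel:
#' `p * (step / ratio) = (1 - p) * step`, i.e. `p = ratio / (1 + ratio)`.
#' With the reference 3:1 error:correct weighting this is 75\% correct.
#'
#' @param ratio Error:correct step-size ratio (> 0).
#' @return The equilibrium proportion correct.
#' @examples
#' staircase_equilibrium(3) # 0.75
#' @export
staircase_equilibrium <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0) {
    stop("`ratio` must be a single positive number", call. = FALSE)
  }
  ratio / (1 + ratio)
}

#' Run a weighted up-down adaptive staircase
#'
#' Simulates the adaptive procedure used to fix task difficulty: stimulus
#' opacity rises by `step` after each error and falls by `step / ratio` after
#' each correct response (3:1 weighting targets 75\% correct). The run stops
#' after `n_reversals` behavioral reversals -- changes in the response
#' sequence from correct to error or vice versa -- and the converged
#' threshold is the mean opacity over reversal trials.
#'
#' @param observer A function mapping opacity in \[0, 1\] to P(correct); must
#'   be monotone non-decreasing and return probabilities.
#' @param step Opacity increment after an error (default 0.01).
#' @param ratio Error:correct step ratio (default 3).
#' @param n_reversals Stop criterion (default 50).
#' @param start_opacity Initial opacity (default 0.8).
#' @param seed Integer seed for the simulated responses.
#' @param two_phase If `TRUE`, run a second staircase starting from the
#'   first phase's threshold (mirroring the two-block intake procedure) and
#'   report the second phase; default `FALSE`.
#' @param max_trials Safety cap on trial count.
#'
#' @return A list of class `staircase_result` with `opacity_trace` (opacity
#'   presented on each trial), `correct` (response sequence),
#'   `reversal_indices`, `threshold` (mean opacity at reversals) and
#'   `n_trials`.
#' @examples
#' obs <- logistic_observer(threshold = 0.3, slope = 12)
#' st <- run_staircase(obs, seed = 2)
#' st$threshold
#' @export
run_staircase <- function(observer, step = 0.01, ratio = 3,
                          n_reversals = 50, start_opacity = 0.8, seed = 1L,
                          two_phase = FALSE, max_trials = 20000L) {
  stopifnot(is.function(observer), step > 0, ratio > 0, n_reversals >= 1)

  run_one <- function(start, seed) {
    old <- .Random.seed_exists()
    on.exit(old$restore(), add = TRUE)
    set.seed(seed)

    opacity <- numeric(0)
    correct <- logical(0)
    x <- start
    n_rev <- 0L
    i <- 0L
    while (n_rev < n_reversals && i < max_trials) {
      i <- i + 1L
      p <- observer(x)
      if (!is.finite(p) || p < 0 || p > 1) {
        stop("observer returned a probability outside [0, 1]", call. = FALSE)
      }
      opacity[i] <- x
      correct[i] <- runif(1) < p
      if (i > 1L && correct[i] != correct[i - 1L]) n_rev <- n_rev + 1L
      x <- if (correct[i]) x - step / ratio else x + step
      x <- min(max(x, 0), 1)
    }
    reversals <- which(diff(correct) != 0) + 1L
    reversals <- head(reversals, n_reversals)
    list(
      opacity_trace = opacity,
      correct = correct,
      reversal_indices = reversals,
      threshold = mean(opacity[reversals]),
      n_trials = i
    )
  }

  res <- run_one(start_opacity, seed)
  if (two_phase) res <- run_one(res$threshold, seed + 1L)
  class(res) <- "staircase_result"
  res
}

#' Logistic psychometric observer
#'
#' Convenience factory for a simulated observer whose accuracy rises
#' logistically with opacity from chance (0.5) to `lapse`-limited ceiling.
#'
#' @param threshold Opacity of the psychometric midpoint.
#' @param slope Logistic slope (per opacity unit).
#' @param guess Lower asymptote (2AFC chance = 0.5).
#' @param lapse Lapse rate shrinking the upper asymptote.
#' @return A function opacity -> P(correct).
#' @export
logistic_observer <- function(threshold = 0.3, slope = 12, guess = 0.5,
                              lapse = 0) {
  force(threshold); force(slope); force(guess); force(lapse)
  function(opacity) {
    guess + (1 - guess - lapse) / (1 + exp(-slope * (opacity - threshold)))
  }
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf(
    "<staircase_result> %d trials, %d reversals, threshold = %.4f\n",
    x$n_trials, length(x$reversal_indices), x$threshold
  ))
  invisible(x)
}
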