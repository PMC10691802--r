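#' Drift diffusion model parameters
#'
#' Container for the generative parameters of a two-boundary diffusion
#' process under accuracy coding: drift rate `v` (evidence/s), boundary
#' separation `a`, non-decision time `t0` (s), trial-to-trial drift SD `sv`,
#' and starting point `z` fixed at `a / 2` (the accuracy-coding convention;
#' starting-point bias is analyzed separately through the signal-detection
#' criterion).
#'
#' @param v Drift rate.
#' @param a Boundary separation (> 0).
#' @param t0 Non-decision time (>= 0).
#' @param sv Inter-trial drift-rate SD (>= 0).
#' @param z Starting point; defaults to `a / 2` and must lie in (0, a).
#' @return A list of class `ddm_params`.
#' @examples
#' ddm_params(v = 1, a = 2, t0 = 0.3)
#' @export
ddm_params <- function(v, a, t0 = 0, sv = 0, z = a / 2) {
  stopifnot(is.numeric(v), is.numeric(a), is.numeric(t0), is.numeric(sv))
  if (a <= 0) stop("`a` must be positive", call. = FALSE)
  if (t0 < 0) stop("`t0` must be non-negative", call. = FALSE)
  if (sv < 0) stop("`sv` must be non-negative", call. = FALSE)
  if (z <= 0 || z >= a) stop("`z` must lie strictly between 0 and a", call. = FALSE)
  structure(list(v = v, a = a, t0 = t0, sv = sv, z = z), class = "ddm_params")
}

#' Simulate the drift diffusion process
#'
#' Simulates first-passage times of a diffusion with drift `v` (drawn per
#' trial from Normal(`v`, `sv`)), boundaries at 0 and `a`, start `z`, by
#' Euler-Maruyama integration with a per-step Brownian-bridge crossing
#' correction that removes the leading discretization bias. Under accuracy
#' coding the upper boundary is the correct response.
#'
#' @param params A [ddm_params()] object.
#' @param n Number of trials.
#' @param seed Integer seed (dedicated RNG stream; does not disturb R's RNG).
#' @param dt Integration step in seconds (default 0.001).
#' @param tmax Censoring horizon for the decision time (default 20 s); the
#'   rare censored trial gets `rt = NA`.
#' @return A tibble with columns `rt` (s, decision time + `t0`) and
#'   `accuracy` (1 = upper/correct boundary).
#' @examples
#' sim <- simulate_ddm(ddm_params(v = 1, a = 2, t0 = 0.3), n = 1000, seed = 1)
#' mean(sim$accuracy)
#' @export
simulate_ddm <- function(params, n, seed = 1L, dt = 1e-3, tmax = 20) {
  stopifnot(inherits(params, "ddm_params"), n >= 1, dt > 0)
  res <- .ddm_simulate_cpp(as.integer(n), params$v, params$a, params$z,
                           params$t0, params$sv, dt, tmax, as.numeric(seed))
  tibble::tibble(rt = res$rt, accuracy = res$accuracy)
}

#' Wiener first-passage-time density
#'
#' Exact density of the first passage through one boundary of the diffusion,
#' computed from the classical small-time / large-time series expansions with
#' an automatic switch at a truncation-error bound of 1e-7. Trial-to-trial
#' drift variability (`sv > 0`) is handled in closed form by analytically
#' integrating the drift-dependent factor over Normal(`v`, `sv`) drifts.
#'
#' @param t Vector of times (s), measured from stimulus onset (so density is
#'   0 for `t <= t0`).
#' @param boundary `"upper"` (correct under accuracy coding) or `"lower"`.
#' @param params A [ddm_params()] object.
#' @return Density values (1/s), same length as `t`.
#' @examples
#' p <- ddm_params(v = 1, a = 2, t0 = 0.3)
#' wfpt_density(c(0.2, 0.5, 1), "upper", p)
#' @export
wfpt_density <- function(t, boundary = c("upper", "lower"), params) {
  boundary <- match.arg(boundary)
  if (any(!is.finite(t))) stop("`t` must be finite", call. = FALSE)
  stopifnot(inherits(params, "ddm_params"))
  .wfpt_density_cpp(as.numeric(t), as.integer(boundary == "upper"),
                    params$v, params$a, params$z, params$t0, params$sv)
}

#' Analytic boundary-choice probability
#'
#' Closed-form absorption probability at the upper boundary for a diffusion
#' without drift variability: `P(upper) = (1 - exp(-2 v z)) / (1 - exp(-2 v a))`,
#' reducing to `z / a` as `v -> 0`. Used as the independent oracle for the
#' simulator and for normalization checks of the first-passage density.
#'
#' @param params A [ddm_params()] object with `sv = 0`.
#' @return Probability of hitting the upper boundary.
#' @examples
#' choice_probability(ddm_params(v = 1, a = 2)) # plogis(2)
#' @export
choice_probability <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  if (params$sv != 0) {
    stop("closed form requires sv = 0; use simulate_ddm() for sv > 0",
         call. = FALSE)
  }
  v <- params$v; a <- params$a; z <- params$z
  if (abs(v) < 1e-12) return(z / a)
  # expm1 keeps the ratio stable for small |v|
  (-expm1(-2 * v * z)) / (-expm1(-2 * v * a))
}

#' Cumulative first-passage distribution by quadrature
#'
#' Numerical CDF of [wfpt_density()] on a fine grid (trapezoid rule), used
#' for inverse-CDF sampling and normalization checks.
#'
#' @inheritParams wfpt_density
#' @param t_upper Upper end of the grid (s).
#' @param n_grid Grid resolution.
#' @return A tibble with columns `t` and `F` (CDF at `t`).
#' @export
wfpt_cdf <- function(boundary = c("upper", "lower"), params, t_upper = 20,
                     n_grid = 20000L) {
  boundary <- match.arg(boundary)
  tg <- seq(params$t0, t_upper, length.out = n_grid)
  f <- wfpt_density(tg, boundary, params)
  Fg <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(tg)))
  tibble::tibble(t = tg, F = Fg)
}

#' Sample RTs by inverting the first-passage CDF
#'
#' @inheritParams wfpt_cdf
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Numeric vector of RTs from the given boundary, conditioned on
#'   absorption at that boundary.
#' @export
wfpt_sample <- function(n, boundary = c("upper", "lower"), params,
                        seed = 1L, t_upper = 20) {
  boundary <- match.arg(boundary)
  cdf <- wfpt_cdf(boundary, params, t_upper = t_upper)
  total <- max(cdf$F)
  old <- .Random.seed_exists()
  on.exit(old$restore(), add = TRUE)
  set.seed(seed)
  u <- runif(n) * total
  approx(cdf$F, cdf$t, xout = u, ties = "ordered")$y
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("<ddm_params> v=%.3f a=%.3f t0=%.3f sv=%.3f z=%.3f\n",
              x$v, x$a, x$t0, x$sv, x$z))
  invisible(x)
}
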