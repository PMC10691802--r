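# Hierarchical Bayesian accuracy-coded DDM regression.
#
# Model, per trial i of subject s with coded design row X_i = (drug,
# validity, drug:validity):
#   v_i  = v_s  + X_i' beta_v
#   a_i  = a_s  + X_i' beta_a      (a_i > 0)
#   t0_i = t0_s + X_i' beta_t0     (0 <= t0_i < rt_i)
#   rt_i, accuracy_i ~ Wiener first passage (z = a_i / 2, group-level sv)
# Subject parameters are exchangeable: v_s ~ N(mu_v, sigma_v^2), etc.
# Weakly-informative priors: beta, mu ~ N(0, 2); sigma, sv ~ half-N(1).
# Sampling is Metropolis-within-Gibbs: random-walk MH for subject blocks,
# group coefficient blocks and sv (proposal scales adapted during burn-in,
# then frozen); conjugate Gibbs for the group means; log-scale MH for the
# group SDs. Split-Rhat is attached for every parameter.

PRIOR_SD_BETA <- 2
PRIOR_SD_MU <- 2
PRIOR_SD_SIGMA <- 1 # half-normal
PRIOR_SD_SV <- 1    # half-normal

#' Fit the hierarchical Bayesian accuracy-coded DDM regression
#'
#' Fits RT distributions of correct and incorrect trials jointly for all
#' subjects, with drift rate, non-decision time and boundary separation
#' regressed on drug, cue validity and their interaction under the coding in
#' `spec`, and subject-level parameters constrained by group-level
#' distributions. Models are intended to be fitted separately per active
#' drug (placebo + one drug), mirroring the pairwise design.
#'
#' @param data Trial tibble with columns `subject`, `drug`, `validity`,
#'   `rt` (s) and `accuracy` (0/1). At least 2 subjects.
#' @param spec A [regression_spec()].
#' @param mcmc List of sampler settings: `chains` (default 2), `draws` kept
#'   per chain after burn-in (default 1000), `burn_in` (default 500),
#'   `seed` (default 1), `fit_sv` (default TRUE, group-level).
#' @return An object of class `ddm_fit`: posterior draws
#'   (chains x draws x parameters array), a summary tibble (mean, sd,
#'   2.5/97.5\% quantiles, split-Rhat, one-sided posterior tail probability),
#'   and convergence flags. Non-convergence (any Rhat > 1.1) is flagged in
#'   `$converged`, never silently dropped.
#' @seealso [posterior_probability()], [tidy.ddm_fit()], [glance.ddm_fit()]
#' @export
fit_hierarchical_ddm <- function(data, spec = regression_spec(),
                                 mcmc = list()) {
  mc <- utils::modifyList(
    list(chains = 2L, draws = 1000L, burn_in = 500L, seed = 1L,
         fit_sv = TRUE),
    mcmc
  )
  stopifnot(all(c("subject", "drug", "validity", "rt", "accuracy") %in%
                  names(data)))
  if (any(data$rt <= 0)) stop("all rt must be positive", call. = FALSE)
  subjects <- sort(unique(data$subject))
  S <- length(subjects)
  if (S < 2) stop("need at least 2 subjects for a hierarchical fit",
                  call. = FALSE)
  one_outcome <- data |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(both = dplyr::n_distinct(.data$accuracy) == 2L) |>
    dplyr::filter(!.data$both)
  if (nrow(one_outcome)) {
    warning("subject(s) with a single accuracy outcome: ",
            paste(one_outcome$subject, collapse = ", "), call. = FALSE)
  }

  X <- build_design_matrix(data, spec)[, c("drug", "validity",
                                           "drug:validity"), drop = FALSE]
  subj_idx <- match(data$subject, subjects)
  trials_of <- split(seq_len(nrow(data)), subj_idx)
  rt <- data$rt
  resp <- as.integer(data$accuracy)

  chains <- lapply(seq_len(mc$chains), function(ch) {
    .run_ddm_chain(rt, resp, X, subj_idx, trials_of, S,
                   n_draws = mc$draws, burn_in = mc$burn_in,
                   seed = mc$seed * 1000L + ch, fit_sv = mc$fit_sv)
  })

  par_names <- colnames(chains[[1]])
  draws <- array(
    unlist(chains),
    dim = c(mc$draws, length(par_names), mc$chains),
    dimnames = list(NULL, par_names, NULL)
  )
  draws <- aperm(draws, c(3, 1, 2)) # chains x draws x params

  rhat <- apply(draws, 3, .split_rhat)
  flat <- apply(draws, 3, c) # (chains*draws) x params
  qs <- apply(flat, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  summary <- tibble::tibble(
    parameter = par_names,
    mean = colMeans(flat),
    sd = apply(flat, 2, sd),
    q2.5 = qs[1, ],
    q97.5 = qs[2, ],
    rhat = rhat
  )
  summary$p_posterior <- vapply(par_names, function(p) {
    .tail_probability(flat[, p])
  }, numeric(1))

  out <- list(
    draws = draws,
    summary = summary,
    spec = spec,
    mcmc = mc,
    subjects = subjects,
    n_trials = nrow(data),
    converged = all(is.finite(rhat)) && max(rhat, na.rm = TRUE) <= 1.1
  )
  class(out) <- "ddm_fit"
  if (!out$converged) {
    warning("sampler flagged non-convergence: max split-Rhat = ",
            sprintf("%.3f", max(rhat, na.rm = TRUE)), call. = FALSE)
  }
  out
}

# one MCMC chain; returns draws matrix (n_draws x params)
.run_ddm_chain <- function(rt, resp, X, subj_idx, trials_of, S,
                           n_draws, burn_in, seed, fit_sv) {
  old <- .Random.seed_exists()
  on.exit(old$restore(), add = TRUE)
  set.seed(seed)

  P <- ncol(X) # 3 regression columns

  # crude, jittered initialization
  min_rt_s <- vapply(trials_of, function(ix) min(rt[ix]), numeric(1))
  acc_s <- vapply(trials_of, function(ix) mean(resp[ix]), numeric(1))
  a_s <- rep(1.5, S) + rnorm(S, 0, 0.05)
  acc_clip <- pmin(pmax(acc_s, 0.55), 0.95)
  v_s <- log(acc_clip / (1 - acc_clip)) / a_s + rnorm(S, 0, 0.05)
  t0_s <- pmax(0.6 * min_rt_s + rnorm(S, 0, 0.01), 0.01)
  beta_v <- rnorm(P, 0, 0.01)
  beta_a <- rnorm(P, 0, 0.01)
  beta_t0 <- rnorm(P, 0, 0.002)
  sv <- if (fit_sv) 0.3 else 0
  mu <- c(v = mean(v_s), a = mean(a_s), t0 = mean(t0_s))
  sigma <- c(v = 0.3, a = 0.2, t0 = 0.05)

  trial_par <- function(v_s, a_s, t0_s, beta_v, beta_a, beta_t0) {
    list(v = v_s[subj_idx] + X %*% beta_v,
         a = a_s[subj_idx] + X %*% beta_a,
         t0 = t0_s[subj_idx] + X %*% beta_t0)
  }
  ll_subject <- function(ix, tp, sv) {
    .ddm_loglik_cpp(rt[ix], resp[ix], tp$v[ix], tp$a[ix], tp$t0[ix], sv)
  }

  tp <- trial_par(v_s, a_s, t0_s, beta_v, beta_a, beta_t0)
  ll_s <- vapply(seq_len(S), function(s) ll_subject(trials_of[[s]], tp, sv),
                 numeric(1))
  if (!all(is.finite(ll_s))) {
    # push t0 down until the start state is feasible
    t0_s <- pmin(t0_s, 0.5 * min_rt_s)
    tp <- trial_par(v_s, a_s, t0_s, beta_v, beta_a, beta_t0)
    ll_s <- vapply(seq_len(S), function(s) ll_subject(trials_of[[s]], tp, sv),
                   numeric(1))
  }

  # adaptive proposal scales
  sc_subj <- matrix(c(0.15, 0.1, 0.02), nrow = S, ncol = 3, byrow = TRUE)
  sc_beta <- c(v = 0.05, a = 0.03, t0 = 0.01)
  sc_sv <- 0.05
  sc_sigma <- c(v = 0.3, a = 0.3, t0 = 0.3)
  acc_ct <- list(subj = matrix(0, S, 1), beta = c(v = 0, a = 0, t0 = 0),
                 sv = 0, sigma = c(v = 0, a = 0, t0 = 0))
  adapt_every <- 50L

  n_iter <- burn_in + n_draws
  par_names <- c(
    paste0("v_subj[", seq_len(S), "]"),
    paste0("a_subj[", seq_len(S), "]"),
    paste0("t0_subj[", seq_len(S), "]"),
    paste0("v_", colnames(X)), paste0("a_", colnames(X)),
    paste0("t0_", colnames(X)),
    "sv", "mu_v", "sigma_v", "mu_a", "sigma_a", "mu_t0", "sigma_t0"
  )
  out <- matrix(NA_real_, n_draws, length(par_names),
                dimnames = list(NULL, par_names))

  hyper_lp <- function(th, m, s) sum(dnorm(th, m, s, log = TRUE))

  for (it in seq_len(n_iter)) {
    ## subject blocks
    for (s in seq_len(S)) {
      prop <- c(v_s[s], a_s[s], t0_s[s]) + rnorm(3) * sc_subj[s, ]
      if (prop[2] <= 0 || prop[3] < 0) next
      ix <- trials_of[[s]]
      tpv <- prop[1] + X[ix, , drop = FALSE] %*% beta_v
      tpa <- prop[2] + X[ix, , drop = FALSE] %*% beta_a
      tpt <- prop[3] + X[ix, , drop = FALSE] %*% beta_t0
      ll_new <- .ddm_loglik_cpp(rt[ix], resp[ix], tpv, tpa, tpt, sv)
      lp_new <- dnorm(prop[1], mu["v"], sigma["v"], log = TRUE) +
        dnorm(prop[2], mu["a"], sigma["a"], log = TRUE) +
        dnorm(prop[3], mu["t0"], sigma["t0"], log = TRUE)
      lp_old <- dnorm(v_s[s], mu["v"], sigma["v"], log = TRUE) +
        dnorm(a_s[s], mu["a"], sigma["a"], log = TRUE) +
        dnorm(t0_s[s], mu["t0"], sigma["t0"], log = TRUE)
      if (log(runif(1)) < ll_new + lp_new - ll_s[s] - lp_old) {
        v_s[s] <- prop[1]; a_s[s] <- prop[2]; t0_s[s] <- prop[3]
        ll_s[s] <- ll_new
        acc_ct$subj[s] <- acc_ct$subj[s] + 1
      }
    }

    ## group regression coefficient blocks
    for (par in c("v", "a", "t0")) {
      bold <- switch(par, v = beta_v, a = beta_a, t0 = beta_t0)
      bnew <- bold + rnorm(P) * sc_beta[par]
      bv <- if (par == "v") bnew else beta_v
      ba <- if (par == "a") bnew else beta_a
      bt <- if (par == "t0") bnew else beta_t0
      tp <- trial_par(v_s, a_s, t0_s, bv, ba, bt)
      ll_new_s <- vapply(seq_len(S),
                         function(s) ll_subject(trials_of[[s]], tp, sv),
                         numeric(1))
      lr <- sum(ll_new_s) - sum(ll_s) +
        hyper_lp(bnew, 0, PRIOR_SD_BETA) - hyper_lp(bold, 0, PRIOR_SD_BETA)
      if (is.finite(lr) && log(runif(1)) < lr) {
        if (par == "v") beta_v <- bnew
        if (par == "a") beta_a <- bnew
        if (par == "t0") beta_t0 <- bnew
        ll_s <- ll_new_s
        acc_ct$beta[par] <- acc_ct$beta[par] + 1
      }
    }

    ## sv (reflected random walk, half-normal prior)
    if (fit_sv) {
      svn <- abs(sv + rnorm(1) * sc_sv)
      tp <- trial_par(v_s, a_s, t0_s, beta_v, beta_a, beta_t0)
      ll_new_s <- vapply(seq_len(S),
                         function(s) ll_subject(trials_of[[s]], tp, svn),
                         numeric(1))
      lr <- sum(ll_new_s) - sum(ll_s) +
        dnorm(svn, 0, PRIOR_SD_SV, log = TRUE) -
        dnorm(sv, 0, PRIOR_SD_SV, log = TRUE)
      if (is.finite(lr) && log(runif(1)) < lr) {
        sv <- svn
        ll_s <- ll_new_s
        acc_ct$sv <- acc_ct$sv + 1
      }
    }

    ## group means: conjugate Gibbs
    for (par in c("v", "a", "t0")) {
      th <- switch(par, v = v_s, a = a_s, t0 = t0_s)
      prec <- S / sigma[par]^2 + 1 / PRIOR_SD_MU^2
      m <- (sum(th) / sigma[par]^2) / prec
      mu[par] <- rnorm(1, m, sqrt(1 / prec))
    }

    ## group SDs: MH on log scale, half-normal prior
    for (par in c("v", "a", "t0")) {
      th <- switch(par, v = v_s, a = a_s, t0 = t0_s)
      sn <- sigma[par] * exp(rnorm(1) * sc_sigma[par] * 0.2)
      lr <- sum(dnorm(th, mu[par], sn, log = TRUE)) -
        sum(dnorm(th, mu[par], sigma[par], log = TRUE)) +
        dnorm(sn, 0, PRIOR_SD_SIGMA, log = TRUE) -
        dnorm(sigma[par], 0, PRIOR_SD_SIGMA, log = TRUE) +
        log(sn) - log(sigma[par]) # log-scale proposal Jacobian
      if (is.finite(lr) && log(runif(1)) < lr) {
        sigma[par] <- sn
        acc_ct$sigma[par] <- acc_ct$sigma[par] + 1
      }
    }

    ## proposal adaptation during burn-in only
    if (it <= burn_in && it %% adapt_every == 0L) {
      rate_s <- acc_ct$subj / adapt_every
      sc_subj <- sc_subj * exp(pmin(pmax(rate_s - 0.25, -0.5), 0.5))[, 1]
      rate_b <- acc_ct$beta / adapt_every
      sc_beta <- sc_beta * exp(pmin(pmax(rate_b - 0.25, -0.5), 0.5))
      sc_sv <- sc_sv * exp(min(max(acc_ct$sv / adapt_every - 0.35, -0.5), 0.5))
      sc_sigma <- sc_sigma * exp(pmin(pmax(acc_ct$sigma / adapt_every - 0.4,
                                           -0.5), 0.5))
      acc_ct$subj[] <- 0; acc_ct$beta[] <- 0; acc_ct$sv <- 0
      acc_ct$sigma[] <- 0
    }

    if (it > burn_in) {
      out[it - burn_in, ] <- c(
        v_s, a_s, t0_s, beta_v, beta_a, beta_t0, sv,
        mu["v"], sigma["v"], mu["a"], sigma["a"], mu["t0"], sigma["t0"]
      )
    }
  }
  out
}

# split-Rhat over a chains x draws matrix (or vector from one chain)
.split_rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  half <- n %/% 2L
  pieces <- lapply(seq_len(nrow(x)), function(ch) {
    list(x[ch, seq_len(half)], x[ch, (n - half + 1):n])
  })
  segs <- do.call(rbind, lapply(pieces, function(p) rbind(p[[1]], p[[2]])))
  m <- nrow(segs); len <- ncol(segs)
  means <- rowMeans(segs)
  vars <- apply(segs, 1, var)
  W <- mean(vars)
  B <- len * var(means)
  if (W < 1e-12) return(1)
  sqrt(((len - 1) / len * W + B / len) / W)
}

# one-sided posterior tail mass: fraction of draws on the opposite side of
# zero from the posterior mean, bounded below by 1/n
.tail_probability <- function(draws, two_sided = FALSE) {
  m <- mean(draws)
  p <- if (m >= 0) mean(draws < 0) else mean(draws > 0)
  p <- max(p, 1 / length(draws))
  if (two_sided) p <- min(2 * p, 1)
  p
}

#' Posterior tail probability of a regression coefficient
#'
#' Returns the fraction of posterior draws on the opposite side of zero from
#' the posterior mean -- the one-sided posterior "p-value" convention used to
#' report diffusion-model regression effects -- bounded below by 1/n draws.
#'
#' @param fit A `ddm_fit` object (or a `PosteriorDraws`-like named draws
#'   matrix with parameters in columns).
#' @param coefficient Parameter name, e.g. `"v_validity"`, `"v_drug"`.
#' @param two_sided If `TRUE`, double the tail mass (capped at 1).
#' @return A probability.
#' @export
posterior_probability <- function(fit, coefficient, two_sided = FALSE) {
  draws <- if (inherits(fit, "ddm_fit")) {
    if (!coefficient %in% dimnames(fit$draws)[[3]]) {
      stop("unknown coefficient: ", coefficient, call. = FALSE)
    }
    as.vector(fit$draws[, , coefficient])
  } else if (is.matrix(fit)) {
    if (!coefficient %in% colnames(fit)) {
      stop("unknown coefficient: ", coefficient, call. = FALSE)
    }
    fit[, coefficient]
  } else {
    stop("`fit` must be a ddm_fit or a draws matrix", call. = FALSE)
  }
  if (!length(draws)) stop("no posterior draws", call. = FALSE)
  .tail_probability(draws, two_sided = two_sided)
}

#' Extract posterior draws for selected parameters
#'
#' @param fit A `ddm_fit`.
#' @param parameters Character vector of parameter names (default: all
#'   group-level parameters).
#' @return A tibble with columns `chain`, `draw`, `parameter`, `value`.
#' @export
posterior_draws <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "ddm_fit"))
  all_pars <- dimnames(fit$draws)[[3]]
  if (is.null(parameters)) {
    parameters <- grep("_subj\\[", all_pars, value = TRUE, invert = TRUE)
  }
  purrr::map_dfr(parameters, function(p) {
    tibble::tibble(
      chain = rep(seq_len(dim(fit$draws)[1]), each = dim(fit$draws)[2]),
      draw = rep(seq_len(dim(fit$draws)[2]), times = dim(fit$draws)[1]),
      parameter = p,
      value = as.vector(t(fit$draws[, , p]))
    )
  })
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "<ddm_fit> %d subjects, %d trials, %d chains x %d draws%s\n",
    length(x$subjects), x$n_trials, x$mcmc$chains, x$mcmc$draws,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  print(tidy.ddm_fit(x), n = 12)
  invisible(x)
}

#' Tidy a hierarchical DDM fit
#'
#' @param x A `ddm_fit`.
#' @param ... Unused.
#' @return A tibble of group-level parameters with posterior mean, sd, 95\%
#'   credible interval, split-Rhat and one-sided posterior tail probability.
#' @importFrom generics tidy
#' @export
tidy.ddm_fit <- function(x, ...) {
  x$summary |>
    dplyr::filter(!grepl("_subj\\[", .data$parameter)) |>
    dplyr::rename(term = "parameter", estimate = "mean", std.error = "sd",
                  conf.low = "q2.5", conf.high = "q97.5")
}

#' Fit-level summary of a hierarchical DDM fit
#'
#' @param x A `ddm_fit`.
#' @param ... Unused.
#' @return One-row tibble: subjects, trials, chains, draws, max Rhat,
#'   convergence flag.
#' @importFrom generics glance
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$subjects),
    n_trials = x$n_trials,
    chains = x$mcmc$chains,
    draws = x$mcmc$draws,
    max_rhat = max(x$summary$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' Write a CSV summary of a DDM fit
#'
#' @param fit A `ddm_fit`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ddm_summary <- function(fit, path) {
  readr::write_csv(fit$summary, path)
  invisible(path)
}

#' Maximum a posteriori single-condition DDM estimate
#'
#' Point estimate of (v, a, t0) for one RT/accuracy sample by direct
#' optimization of the Wiener first-passage likelihood (flat priors within
#' the feasible region). Used for parameter-recovery diagnostics.
#'
#' @param rt,accuracy Trial vectors.
#' @param sv Fixed drift variability (default 0).
#' @return A named vector `c(v, a, t0)`.
#' @export
fit_ddm_map <- function(rt, accuracy, sv = 0) {
  resp <- as.integer(accuracy)
  nll <- function(par) {
    v <- par[1]; a <- exp(par[2]); t0 <- min(rt) * plogis(par[3])
    n <- length(rt)
    -.ddm_loglik_cpp(rt, resp, rep(v, n), rep(a, n), rep(t0, n), sv)
  }
  acc <- pmin(pmax(mean(resp), 0.55), 0.95)
  init <- c(log(acc / (1 - acc)) / 1.5, log(1.5), 0)
  fit <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-9))
  c(v = fit$par[1], a = exp(fit$par[2]),
    t0 = min(rt) * plogis(fit$par[3]))
}
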