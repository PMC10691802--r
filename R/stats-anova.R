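#' Partial eta squared from a t-statistic
#'
#' `eta_p^2 = t^2 / (t^2 + df)`. Monotone increasing in |t| and decreasing
#' in df; rounding happens only at presentation.
#'
#' @param t t-statistic.
#' @param df Degrees of freedom (> 0).
#' @return Partial eta squared in \[0, 1\].
#' @examples
#' eta_p_from_t(4.33, 27) # ~0.41
#' @export
eta_p_from_t <- function(t, df) {
  if (any(df <= 0)) stop("`df` must be positive", call. = FALSE)
  t^2 / (t^2 + df)
}

# ---- vectorized balanced within-subject ANOVA -------------------------------
# Y: subjects x cells x samples array; cell_levels: data.frame mapping cell
# index -> factor levels. For each effect (subset of factors) the pure
# interaction component per subject is obtained by centering the collapsed
# cell means along every factor in the effect; subject-by-effect variation is
# the error term.
.rm_anova_engine <- function(Y, cell_levels, factors) {
  stopifnot(length(dim(Y)) == 3L)
  n_subj <- dim(Y)[1]
  n_samp <- dim(Y)[3]
  lvls <- lapply(factors, function(f) sort(unique(cell_levels[[f]])))
  names(lvls) <- factors
  n_lev <- vapply(lvls, length, integer(1))
  n_cells <- dim(Y)[2]
  stopifnot(prod(n_lev) == n_cells)

  # reshape to subjects x L1 x L2 x ... x samples (factor 1 varying fastest)
  cell_order <- do.call(order, cell_levels[rev(factors)])
  Yf <- array(Y[, cell_order, , drop = FALSE],
              c(n_subj, n_lev, n_samp))

  effects <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, simplify = FALSE)
  }), recursive = FALSE)

  center_dim <- function(A, d) sweep(A, seq_along(dim(A))[-d],
                                     apply(A, seq_along(dim(A))[-d], mean), `-`)

  res <- purrr::map(effects, function(eff) {
    keep_f <- match(eff, factors) # factor dims are 1+keep_f in Yf
    drop_f <- setdiff(seq_along(factors), keep_f)
    # collapse over factors not in the effect
    M <- apply(Yf, c(1, 1 + keep_f, length(dim(Yf))), mean)
    # M: subjects x levels(eff...) x samples
    for (d in seq_along(keep_f) + 1) M <- center_dim(M, d)
    r <- prod(n_lev[drop_f]) # cells averaged per collapsed mean
    if (!length(drop_f)) r <- 1
    # subject mean across effect cells is already 0 by centering
    dims <- dim(M)
    grand <- apply(M, seq_along(dims)[-1], mean) # over subjects
    ss_eff <- n_subj * r * apply(grand^2, length(dim(grand)), sum)
    dev <- sweep(M, seq_along(dims)[-1], grand, `-`)
    ss_err <- r * apply(dev^2, length(dims), sum)
    df_eff <- prod(n_lev[keep_f] - 1)
    df_err <- (n_subj - 1) * df_eff
    f_stat <- (ss_eff / df_eff) / (ss_err / df_err)
    tibble::tibble(
      effect = paste(eff, collapse = ":"),
      sample = seq_len(n_samp),
      F = f_stat,
      df_num = df_eff,
      df_den = df_err,
      ss_effect = ss_eff,
      ss_error = ss_err
    )
  })
  dplyr::bind_rows(res)
}

# long tibble -> (Y array, cell_levels); requires complete balanced cells
.rm_long_to_array <- function(data, factors, value = "value",
                              sample = NULL) {
  stopifnot("subject" %in% names(data), all(factors %in% names(data)))
  subjects <- sort(unique(data$subject))
  cells <- data |>
    dplyr::distinct(dplyr::across(dplyr::all_of(factors))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(factors)))
  full <- do.call(tidyr::expand_grid,
                  lapply(factors, function(f) sort(unique(data[[f]]))))
  names(full) <- factors
  if (nrow(cells) != nrow(full)) {
    miss <- dplyr::anti_join(full, cells, by = factors)
    stop("missing condition cell(s): ",
         paste(apply(miss, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  samples <- if (is.null(sample)) 1 else sort(unique(data[[sample]]))
  row_key <- do.call(paste, c(data[factors], sep = "\r"))
  cell_key <- do.call(paste, c(cells, sep = "\r"))
  ci <- match(row_key, cell_key)
  si <- match(data$subject, subjects)
  ti <- if (is.null(sample)) rep(1L, nrow(data)) else
    match(data[[sample]], samples)
  Y <- array(NA_real_, c(length(subjects), nrow(cells), length(samples)))
  Y[cbind(si, ci, ti)] <- data[[value]]
  if (anyNA(Y)) {
    stop("incomplete subject x cell (x sample) table", call. = FALSE)
  }
  list(Y = Y, cell_levels = as.data.frame(cells), subjects = subjects,
       samples = samples)
}

#' Repeated-measures ANOVA on cell means
#'
#' Balanced fully within-subject ANOVA for 1-3 factors (one value per
#' subject and cell), returning F, degrees of freedom, p and partial eta
#' squared (`SS_effect / (SS_effect + SS_error)`) for every main effect and
#' interaction. No sphericity correction is applied by default (matching the
#' convention of reporting uncorrected dfs); Greenhouse-Geisser-corrected
#' p-values are available via `gg_correction = TRUE`.
#'
#' @param data Long tibble with columns `subject`, the factor columns, and
#'   `value`.
#' @param factors Character vector of 1-3 within-subject factor columns.
#' @param gg_correction Apply Greenhouse-Geisser correction to the p-values.
#' @return A tibble: `effect`, `F`, `df_num`, `df_den`, `p`, `eta_p2`.
#' @examples
#' d <- tidyr::expand_grid(subject = 1:6, validity = c("valid", "invalid"))
#' d$value <- rnorm(nrow(d)) + (d$validity == "valid")
#' rm_anova(d, "validity")
#' @export
rm_anova <- function(data, factors, gg_correction = FALSE) {
  arr <- .rm_long_to_array(data, factors)
  res <- .rm_anova_engine(arr$Y, arr$cell_levels, factors) |>
    dplyr::select(-"sample")
  res$p <- pf(res$F, res$df_num, res$df_den, lower.tail = FALSE)
  res$eta_p2 <- res$ss_effect / (res$ss_effect + res$ss_error)
  if (gg_correction) {
    res$p_gg <- purrr::pmap_dbl(
      res[c("effect", "F", "df_num", "df_den")],
      function(effect, F, df_num, df_den) {
        eps <- .gg_epsilon(arr$Y[, , 1], arr$cell_levels,
                           strsplit(effect, ":", fixed = TRUE)[[1]], factors)
        pf(F, eps * df_num, eps * df_den, lower.tail = FALSE)
      }
    )
  }
  dplyr::select(res, "effect", "F", "df_num", "df_den", "p", "eta_p2",
                dplyr::any_of("p_gg"))
}

# Greenhouse-Geisser epsilon from the covariance of effect-collapsed scores
.gg_epsilon <- function(Ymat, cell_levels, eff, factors) {
  # collapse cells onto the effect's levels
  key <- interaction(cell_levels[eff], drop = TRUE)
  M <- sapply(levels(key), function(l) {
    rowMeans(Ymat[, key == l, drop = FALSE])
  })
  k <- ncol(M)
  if (k < 2) return(1)
  S <- stats::cov(M)
  # centered covariance
  Sc <- S - outer(rowMeans(S), colMeans(S), `+`) + mean(S)
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc^2)
  max(min(num / den, 1), 1 / (k - 1))
}

#' Two-proportion z-test (pooled variance)
#'
#' @param k1,n1 Successes and size of sample 1.
#' @param k2,n2 Successes and size of sample 2.
#' @return A tibble with `z` and two-sided `p`.
#' @examples
#' proportion_z_test(20, 28, 10, 28)
#' @export
proportion_z_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' BIC-approximated Bayes factor for a null finding
#'
#' `BF01 = exp((BIC_alt - BIC_null) / 2)`: evidence for the null model over
#' the model including the effect. This is an explicit approximation to
#' default-prior Bayesian ANOVA Bayes factors (which depend on the prior
#' choice and are not reproduced exactly); values > 1 favor the null.
#'
#' @param data Long tibble with `subject`, factor columns, `value`.
#' @param factors Within-subject factors of the full model.
#' @param effect The effect tested (an element of `factors` or an
#'   interaction `"a:b"`); the null model drops exactly this term.
#' @return A tibble with `effect`, `bic_null`, `bic_alt`, `bf01`, and
#'   `approximation = TRUE`.
#' @export
bf01_approx <- function(data, factors, effect) {
  terms_all <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, FUN = paste, collapse = ":")
  }))
  if (!effect %in% terms_all) {
    stop("`effect` must be a main effect or interaction of `factors` (models must nest)",
         call. = FALSE)
  }
  rhs_alt <- paste(c("factor(subject)", terms_all), collapse = " + ")
  rhs_null <- paste(c("factor(subject)", setdiff(terms_all, effect)),
                    collapse = " + ")
  fit_alt <- lm(stats::as.formula(paste("value ~", rhs_alt)), data = data)
  fit_null <- lm(stats::as.formula(paste("value ~", rhs_null)), data = data)
  tibble::tibble(
    effect = effect,
    bic_null = stats::BIC(fit_null),
    bic_alt = stats::BIC(fit_alt),
    bf01 = exp((stats::BIC(fit_alt) - stats::BIC(fit_null)) / 2),
    approximation = TRUE
  )
}

#' Bayes factor from two BIC values
#' @param bic_null,bic_alt BIC of the null and alternative model.
#' @return BF01.
#' @export
bf01_from_bic <- function(bic_null, bic_alt) exp((bic_alt - bic_null) / 2)
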