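#' Regression coding for condition effects on diffusion parameters
#'
#' Defines the (weighted) effect-coding scheme used by the hierarchical
#' accuracy-coded regression model. Drug is coded -1 (placebo) / +1 (active
#' drug); cue validity is weighted by the 80/20 trial proportions (-0.8 for
#' invalid, +0.2 for valid) so that the coded column has exactly zero mean
#' over a balanced session, and the coefficient equals the valid-minus-invalid
#' difference. The interaction regressor is the elementwise product.
#'
#' @param drug_levels Character vector of length 2, reference (placebo)
#'   first, e.g. `c("PLC", "ATX")`.
#' @param validity_weights Named numeric weights for `invalid` and `valid`
#'   trials. Default `c(invalid = -0.8, valid = 0.2)` (weighted effect
#'   coding); use `c(invalid = -1, valid = 1)` for unweighted coding.
#' @param parameters Diffusion parameters regressed on the design
#'   (default `c("v", "t0", "a")`).
#' @return A list of class `ddm_regression_spec`.
#' @examples
#' regression_spec(c("PLC", "ATX"))
#' @export
regression_spec <- function(drug_levels = c("PLC", "ATX"),
                            validity_weights = c(invalid = -0.8, valid = 0.2),
                            parameters = c("v", "t0", "a")) {
  stopifnot(length(drug_levels) == 2L,
            all(c("invalid", "valid") %in% names(validity_weights)))
  parameters <- match.arg(parameters, c("v", "t0", "a", "sv"),
                          several.ok = TRUE)
  structure(
    list(
      drug_levels = drug_levels,
      drug_weights = setNames(c(-1, 1), drug_levels),
      validity_weights = validity_weights[c("invalid", "valid")],
      parameters = parameters
    ),
    class = "ddm_regression_spec"
  )
}

#' Build the trial-level design matrix
#'
#' Maps trial covariates to the regression columns `intercept`, `drug`,
#' `validity` and `drug:validity` under the coding in `spec`.
#'
#' @param trials A trial table with columns `drug` and `validity`.
#' @param spec A [regression_spec()].
#' @return A numeric matrix, one row per trial.
#' @examples
#' tr <- tibble::tibble(drug = c("PLC", "ATX"), validity = c("valid", "invalid"))
#' build_design_matrix(tr, regression_spec(c("PLC", "ATX")))
#' @export
build_design_matrix <- function(trials, spec) {
  stopifnot(inherits(spec, "ddm_regression_spec"))
  bad_drug <- setdiff(unique(trials$drug), names(spec$drug_weights))
  if (length(bad_drug)) {
    stop("unknown drug level(s): ", paste(bad_drug, collapse = ", "),
         call. = FALSE)
  }
  bad_val <- setdiff(unique(trials$validity), names(spec$validity_weights))
  if (length(bad_val)) {
    stop("unknown validity level(s): ", paste(bad_val, collapse = ", "),
         call. = FALSE)
  }
  drug <- unname(spec$drug_weights[trials$drug])
  validity <- unname(spec$validity_weights[trials$validity])
  cbind(intercept = 1, drug = drug, validity = validity,
        `drug:validity` = drug * validity)
}

#' Read and write trial tables
#'
#' Trial tables are TSV with columns `subject`, `drug`, `validity`, `rt`
#' (seconds) and `accuracy` (0/1), plus any design columns.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `read_trials_tsv()` returns a tibble.
#' @export
write_trials_tsv <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname write_trials_tsv
#' @export
read_trials_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
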