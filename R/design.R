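#' Generate a balanced cued orientation-discrimination session design
#'
#' Builds the trial list for one session of a Posner-style cued orientation
#' discrimination task. Cue side, stimulus side and stimulus orientation are
#' each balanced to occur on exactly half of the trials; the spatial cue is
#' valid (cue side equals stimulus side) on a fixed proportion of trials
#' (80\% in the reference protocol). Balance is enforced exactly by
#' constructing the full factorial cell list and shuffling it with the seed,
#' so the printed proportions hold at any admissible trial count.
#'
#' @param n_blocks Number of blocks (reference protocol: 2).
#' @param trials_per_block Trials per block (reference protocol: 280).
#' @param validity Proportion of validly cued trials (default 0.8).
#' @param drug Session label, one of `"PLC"`, `"ATX"`, `"DNP"`.
#' @param seed Integer seed controlling the trial order.
#'
#' @return A tibble of class `session_design` with columns `block`, `trial`,
#'   `cue_side`, `stim_side`, `orientation`, `validity` and `drug`, one row
#'   per trial in presentation order.
#'
#' @details The requested counts must be exactly satisfiable: the total trial
#'   count times `validity` must be an integer, and the valid and invalid
#'   subsets must each split evenly over the 2 (cue side) x 2 (orientation)
#'   cells. An unsatisfiable request errors rather than approximating.
#'
#' @examples
#' d <- generate_session_design(2, 280, validity = 0.8, drug = "PLC", seed = 1)
#' table(d$validity)
#' @export
generate_session_design <- function(n_blocks, trials_per_block,
                                    validity = 0.8, drug = "PLC",
                                    seed = 1L) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1)
  drug <- match.arg(drug, c("PLC", "ATX", "DNP"))
  n_total <- n_blocks * trials_per_block

  n_valid <- validity * n_total
  if (abs(n_valid - round(n_valid)) > 1e-9) {
    stop(sprintf(
      "cannot balance design: validity %.3g x %d trials = %.2f valid trials (not an integer)",
      validity, n_total, n_valid
    ), call. = FALSE)
  }
  n_valid <- as.integer(round(n_valid))
  n_invalid <- n_total - n_valid
  # each validity stratum crosses cue side (2) x orientation (2) exactly
  if (n_valid %% 4L != 0L || n_invalid %% 4L != 0L) {
    stop(sprintf(
      paste0("cannot balance design: %d valid / %d invalid trials do not split ",
             "evenly over cue side x orientation cells (counts must be multiples of 4)"),
      n_valid, n_invalid
    ), call. = FALSE)
  }

  cells <- function(n, valid) {
    tidyr::expand_grid(
      cue_side = c("left", "right"),
      orientation = c("cw", "ccw")
    ) |>
      dplyr::slice(rep(seq_len(4L), each = n %/% 4L)) |>
      dplyr::mutate(
        validity = if (valid) "valid" else "invalid",
        stim_side = if (valid) .data$cue_side else
          ifelse(.data$cue_side == "left", "right", "left")
      )
  }

  trials <- dplyr::bind_rows(cells(n_valid, TRUE), cells(n_invalid, FALSE))
  trials <- local({
    old <- .Random.seed_exists()
    on.exit(old$restore(), add = TRUE)
    set.seed(seed)
    trials[sample.int(nrow(trials)), ]
  })

  out <- trials |>
    dplyr::mutate(
      block = rep(seq_len(n_blocks), each = trials_per_block),
      trial = rep(seq_len(trials_per_block), times = n_blocks),
      drug = drug
    ) |>
    dplyr::select("block", "trial", "cue_side", "stim_side", "orientation",
                  "validity", "drug")
  class(out) <- c("session_design", class(out))
  out
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's stream
.Random.seed_exists <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  list(restore = function() {
    if (had) {
      assign(".Random.seed", saved, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
}

#' Write or read a session design as TSV
#'
#' Round-trips a design table (optionally with `subject` and `session`
#' columns) through tab-separated text.
#'
#' @param design A `session_design` tibble (or any trial table).
#' @param path File path.
#' @return `read_design_tsv()` returns a tibble; `write_design_tsv()`
#'   invisibly returns `path`.
#' @export
write_design_tsv <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
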