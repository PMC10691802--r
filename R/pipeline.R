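#' Pipeline run configuration
#'
#' Assembles the configuration for [run_pipeline()]: either a `simulate`
#' block (a [generative_config()] plus how many subjects' EEG to synthesize)
#' or paths to existing trial tables, stage toggles, seeds and stage
#' parameters.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed recorded in the manifest and used for every stage.
#' @param stages Character subset of `c("behavior", "ddm", "eeg", "stats")`.
#' @param simulate A [generative_config()] (or NULL to use `trials_path`).
#' @param trials_path TSV of trials when not simulating.
#' @param eeg_subjects How many subjects get synthetic EEG (EEG stages are
#'   memory-heavy; default 8).
#' @param eeg_sessions Sessions to synthesize EEG for (default PLC and ATX).
#' @param mcmc Sampler settings passed to [fit_hierarchical_ddm()].
#' @param n_perm Permutations for the cluster tests (default 1000).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("behavior", "ddm", "eeg", "stats"),
                            simulate = generative_config(),
                            trials_path = NULL,
                            eeg_subjects = 8L,
                            eeg_sessions = c("PLC", "ATX"),
                            mcmc = list(chains = 2L, draws = 500L,
                                        burn_in = 300L),
                            n_perm = 1000L) {
  stages <- match.arg(stages, c("behavior", "ddm", "eeg", "stats"),
                      several.ok = TRUE)
  if (is.null(simulate) && is.null(trials_path)) {
    stop("either `simulate` or `trials_path` is required", call. = FALSE)
  }
  if (!is.null(trials_path) && !file.exists(trials_path)) {
    stop("trials_path does not exist: ", trials_path, call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, seed = seed, stages = stages,
         simulate = simulate, trials_path = trials_path,
         eeg_subjects = eeg_subjects, eeg_sessions = eeg_sessions,
         mcmc = mcmc, n_perm = n_perm),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order -- simulate (or ingest) trials,
#' behavioral summaries, hierarchical DDM fit, EEG decision markers, cluster
#' statistics -- writing each stage's tables to `out_dir` (TSV/CSV/JSON) plus
#' a manifest recording the seed, a configuration hash, stage provenance and
#' exclusion counts. Stage interfaces are files, so stages can be re-run
#' independently; a stage failure aborts with a stage-named error and keeps
#' the outputs written so far.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      "out_dir")]),
    stages = list(),
    exclusions = list()
  )
  finish <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      finish()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      completed = TRUE,
      outputs = res,
      seed = config$seed
    )
    res
  }

  ## trials
  trials_file <- file.path(config$out_dir, "trials.tsv")
  trials <- run_stage("trials", function() {
    tr <- if (!is.null(config$trials_path)) {
      read_trials_tsv(config$trials_path)
    } else {
      generate_behavior(config$simulate, seed = config$seed)
    }
    write_trials_tsv(tr, trials_file)
    "trials.tsv"
  })
  trials <- read_trials_tsv(trials_file)
  n_all <- nrow(trials)
  trials_kept <- trials |> dplyr::filter(!is.na(.data$rt), .data$rt <= 1.4)
  manifest$exclusions$trials_rt_filtered <- n_all - nrow(trials_kept)

  if ("behavior" %in% config$stages) {
    run_stage("behavior", function() {
      summ <- condition_summary(trials, extra_groups = "subject")
      readr::write_tsv(summ, file.path(config$out_dir,
                                       "behavior_summary.tsv"))
      "behavior_summary.tsv"
    })
  }

  if ("ddm" %in% config$stages) {
    run_stage("ddm", function() {
      dat <- trials_kept |> dplyr::filter(.data$drug %in% c("PLC", "ATX"))
      fit <- fit_hierarchical_ddm(
        dat, regression_spec(c("PLC", "ATX")),
        mcmc = utils::modifyList(config$mcmc, list(seed = config$seed))
      )
      write_ddm_summary(fit, file.path(config$out_dir, "ddm_summary.csv"))
      "ddm_summary.csv"
    })
  }

  eeg_outputs <- NULL
  if ("eeg" %in% config$stages) {
    eeg_outputs <- run_stage("eeg", function() {
      subs <- head(unique(trials$subject), config$eeg_subjects)
      cpp_all <- list()
      alpha_all <- list()
      for (su in subs) {
        for (dr in intersect(config$eeg_sessions, unique(trials$drug))) {
          ep <- generate_eeg(config$simulate, trials, subject = su,
                             drug = dr,
                             seed = config$seed + match(su, subs) * 100L +
                               match(dr, config$eeg_sessions))
          ep_csd <- csd_transform(ep)
          resp <- epoch_and_baseline(ep_csd, lock = "response",
                                     window = c(-0.6, 0.2))
          cpp <- cpp_metrics(resp) |>
            dplyr::mutate(subject = su, drug = dr)
          cpp_all[[paste(su, dr)]] <- cpp

          occ <- select_channels(ep, roi_channels(roi_spec("occipital")))
          tfr <- morlet_tfr(occ, freqs = seq(6, 14, by = 2))
          tfr_db <- db_normalize(tfr, baseline_window = c(-1.55, -1.35),
                                 baseline_by = "average")
          lat <- alpha_lateralization(tfr_db) |>
            dplyr::group_by(.data$time) |>
            dplyr::summarise(lateralization = mean(.data$lateralization)) |>
            dplyr::mutate(subject = su, drug = dr)
          alpha_all[[paste(su, dr)]] <- lat
        }
      }
      cpp_tbl <- dplyr::bind_rows(cpp_all)
      alpha_tbl <- dplyr::bind_rows(alpha_all)
      readr::write_tsv(cpp_tbl, file.path(config$out_dir, "cpp.tsv"))
      readr::write_tsv(alpha_tbl, file.path(config$out_dir, "alpha.tsv"))
      c("cpp.tsv", "alpha.tsv")
    })
  }

  if ("stats" %in% config$stages) {
    run_stage("stats", function() {
      outs <- character()
      summ <- condition_summary(trials, extra_groups = "subject")
      an <- rm_anova(
        summ |> dplyr::select("subject", "drug", "validity",
                              value = "dprime"),
        factors = c("drug", "validity")
      )
      readr::write_tsv(an, file.path(config$out_dir, "anova_dprime.tsv"))
      outs <- c(outs, "anova_dprime.tsv")
      alpha_path <- file.path(config$out_dir, "alpha.tsv")
      if (file.exists(alpha_path)) {
        alpha_tbl <- readr::read_tsv(alpha_path, show_col_types = FALSE)
        wide <- alpha_tbl |>
          dplyr::group_by(.data$subject, .data$time) |>
          dplyr::summarise(lateralization = mean(.data$lateralization),
                           .groups = "drop") |>
          tidyr::pivot_wider(names_from = "time",
                             values_from = "lateralization")
        mat <- as.matrix(wide[, -1])
        cl <- cluster_perm_ttest_vs_zero(mat, n_perm = config$n_perm,
                                         seed = config$seed)
        write_clusters_json(cl, file.path(config$out_dir, "clusters.json"),
                            times = as.numeric(colnames(mat)))
        outs <- c(outs, "clusters.json")
      }
      outs
    })
  }

  finish()
  invisible(manifest)
}
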