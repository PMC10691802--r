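# Cluster-corrected permutation tests over time (or time x frequency).
# Multiple comparisons are controlled by comparing the observed
# supra-threshold cluster mass to the permutation distribution of the
# maximal cluster mass. The cluster-forming threshold is the parametric
# critical value at `cluster_alpha`; under that convention cluster p-values
# are invariant to monotone rescaling of the data.

# contiguous clusters of TRUE; 1D run-lengths or 2D 4-connectivity on a grid
.find_clusters <- function(supra, grid = NULL) {
  if (is.null(grid)) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    lapply(keep, function(k) seq(starts[k], ends[k]))
  } else {
    stopifnot(prod(grid) == length(supra))
    lab <- matrix(0L, grid[1], grid[2])
    mask <- matrix(supra, grid[1], grid[2])
    cur <- 0L
    for (j in seq_len(grid[2])) {
      for (i in seq_len(grid[1])) {
        if (!mask[i, j] || lab[i, j] > 0L) next
        cur <- cur + 1L
        queue <- list(c(i, j))
        lab[i, j] <- cur
        while (length(queue)) {
          p <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            q <- p + d
            if (q[1] >= 1 && q[1] <= grid[1] && q[2] >= 1 && q[2] <= grid[2] &&
                mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
              lab[q[1], q[2]] <- cur
              queue[[length(queue) + 1L]] <- q
            }
          }
        }
      }
    }
    if (cur == 0L) return(list())
    lapply(seq_len(cur), function(k) which(as.vector(lab) == k))
  }
}

.max_cluster_mass <- function(stat, supra, grid) {
  cl <- .find_clusters(supra, grid)
  if (!length(cl)) return(0)
  max(vapply(cl, function(ix) sum(stat[ix]), numeric(1)))
}

#' Cluster-corrected permutation repeated-measures ANOVA over samples
#'
#' Computes the within-subject ANOVA F statistic at every sample (time point
#' or time-frequency bin), forms clusters of contiguous samples exceeding the
#' parametric F critical value at `cluster_alpha`, and evaluates each
#' cluster's summed F against the permutation distribution of the maximal
#' cluster mass obtained by re-shuffling condition labels within subjects.
#' Each effect (main effects and interactions) is tested against its own
#' null distribution.
#'
#' @param data Long tibble with `subject`, factor columns, `sample` (integer
#'   or time index) and `value`; every subject needs every cell at every
#'   sample.
#' @param factors 1-3 within-subject factor column names.
#' @param n_perm Number of permutations (default 10000; a warning is issued
#'   below 100).
#' @param cluster_alpha Cluster-forming alpha on the parametric F
#'   distribution (default 0.05).
#' @param seed Integer seed; same seed gives bit-identical results.
#' @param grid Optional `c(n_freq, n_time)` for 2D clustering with
#'   4-connectivity; samples must then be ordered frequency-fastest.
#' @param exhaustive Enumerate all within-subject label swaps instead of
#'   sampling (exact p-values; only available for 2-cell designs, where the
#'   permutation group is the 2^subjects condition swaps).
#' @return A tibble of clusters: `effect`, `cluster`, `start`, `end`
#'   (sample indices), `samples` (list column), `mass`, `p_perm`,
#'   `n_permutations`. Effects without supra-threshold samples yield no rows;
#'   attribute `"f_map"` carries the samplewise F values.
#' @export
cluster_perm_rm_anova <- function(data, factors, n_perm = 10000,
                                  cluster_alpha = 0.05, seed = 1L,
                                  grid = NULL, exhaustive = FALSE) {
  if (!exhaustive && n_perm < 100) {
    warning("n_perm < 100 gives a very coarse null", call. = FALSE)
  }
  arr <- .rm_long_to_array(data, factors, sample = "sample")
  Y <- arr$Y
  zero_var <- apply(Y, 3, function(m) all(abs(m - mean(m)) < 1e-300))
  if (any(zero_var)) {
    message(sum(zero_var), " zero-variance sample(s) excluded")
    Y <- Y[, , !zero_var, drop = FALSE]
  }

  obs <- .rm_anova_engine(Y, arr$cell_levels, factors)
  effects <- unique(obs$effect)
  thr <- obs |>
    dplyr::distinct(.data$effect, .data$df_num, .data$df_den) |>
    dplyr::mutate(crit = qf(1 - cluster_alpha, .data$df_num, .data$df_den))

  obs_clusters <- purrr::map(effects, function(eff) {
    o <- obs[obs$effect == eff, ]
    crit <- thr$crit[thr$effect == eff]
    cl <- .find_clusters(o$F > crit, grid)
    list(F = o$F, crit = crit, clusters = cl,
         mass = vapply(cl, function(ix) sum(o$F[ix]), numeric(1)))
  })
  names(obs_clusters) <- effects

  old <- .Random.seed_exists()
  on.exit(old$restore(), add = TRUE)
  set.seed(seed)
  n_subj <- dim(Y)[1]
  n_cells <- dim(Y)[2]
  if (exhaustive) {
    if (n_cells != 2L) {
      stop("exhaustive enumeration is implemented for 2-cell designs only",
           call. = FALSE)
    }
    n_perm <- 2L^n_subj
    perm_sets <- lapply(seq_len(n_perm) - 1L, function(code) {
      as.logical(bitwAnd(bitwShiftR(code, seq_len(n_subj) - 1L), 1L))
    })
  }
  null_max <- matrix(0, n_perm, length(effects),
                     dimnames = list(NULL, effects))
  if (!exhaustive && n_cells == 2L && length(effects) == 1L) {
    # two-cell designs: a within-subject label swap is a sign flip of the
    # paired difference, and F = t^2 closes over colSums, so the whole
    # permutation null is one matrix product
    D <- Y[, 1, ] - Y[, 2, ] # subjects x samples
    if (is.null(dim(D))) D <- matrix(D, nrow = n_subj)
    ssq <- colSums(D^2)
    crit <- thr$crit[1]
    flips <- matrix(sample(c(-1, 1), n_perm * n_subj, replace = TRUE),
                    n_perm, n_subj)
    M <- (flips %*% D) / n_subj # n_perm x samples
    Fmat <- n_subj * M^2 /
      ((matrix(ssq, n_perm, length(ssq), byrow = TRUE) - n_subj * M^2) /
         (n_subj - 1))
    for (p in seq_len(n_perm)) {
      fv <- Fmat[p, ]
      null_max[p, 1] <- .max_cluster_mass(fv, fv > crit, grid)
    }
  } else {
    for (p in seq_len(n_perm)) {
      Yp <- Y
      if (exhaustive) {
        swap <- perm_sets[[p]]
        Yp[swap, , ] <- Y[swap, 2:1, , drop = FALSE]
      } else {
        for (s in seq_len(n_subj)) {
          Yp[s, , ] <- Y[s, sample.int(n_cells), ]
        }
      }
      fp <- .rm_anova_engine(Yp, arr$cell_levels, factors)
      for (eff in effects) {
        crit <- thr$crit[thr$effect == eff]
        fv <- fp$F[fp$effect == eff]
        null_max[p, eff] <- .max_cluster_mass(fv, fv > crit, grid)
      }
    }
  }

  out <- purrr::map_dfr(effects, function(eff) {
    oc <- obs_clusters[[eff]]
    if (!length(oc$clusters)) return(tibble::tibble())
    tibble::tibble(
      effect = eff,
      cluster = seq_along(oc$clusters),
      start = vapply(oc$clusters, min, integer(1)),
      end = vapply(oc$clusters, max, integer(1)),
      samples = oc$clusters,
      mass = oc$mass,
      p_perm = vapply(oc$mass, function(m) {
        max(mean(null_max[, eff] >= m), 1 / n_perm)
      }, numeric(1)),
      n_permutations = n_perm
    )
  })
  attr(out, "f_map") <- obs
  attr(out, "thresholds") <- thr
  class(out) <- c("cluster_result", class(out))
  out
}

#' Cluster-corrected one-sample permutation t-test against zero
#'
#' Per-sample one-sample t statistics are thresholded two-sidedly at the
#' parametric critical value; positive and negative clusters are formed
#' separately and each cluster's absolute summed t is compared with the
#' permutation distribution of the maximal absolute cluster mass under
#' random per-subject sign flips.
#'
#' @param data Numeric matrix, subjects x samples.
#' @param n_perm Number of permutations (default 10000).
#' @param cluster_alpha Cluster-forming alpha (two-sided, default 0.05).
#' @param seed Integer seed.
#' @param grid Optional `c(n_freq, n_time)` for 2D clustering.
#' @param exhaustive Enumerate all 2^subjects sign-flip patterns (exact p).
#' @return Tibble of clusters: `sign`, `cluster`, `start`, `end`, `samples`,
#'   `mass` (signed), `p_perm`, `n_permutations`; attribute `"t_map"`.
#' @export
cluster_perm_ttest_vs_zero <- function(data, n_perm = 10000,
                                       cluster_alpha = 0.05, seed = 1L,
                                       grid = NULL, exhaustive = FALSE) {
  stopifnot(is.matrix(data))
  if (!exhaustive && n_perm < 100) {
    warning("n_perm < 100 gives a very coarse null", call. = FALSE)
  }
  n <- nrow(data)
  tstat <- function(m) {
    mu <- colMeans(m)
    se <- apply(m, 2, sd) / sqrt(n)
    ifelse(se > 0, mu / se, 0)
  }
  crit <- qt(1 - cluster_alpha / 2, n - 1)
  tobs <- tstat(data)

  both_clusters <- function(tv) {
    pos <- .find_clusters(tv > crit, grid)
    neg <- .find_clusters(tv < -crit, grid)
    list(pos = pos, neg = neg)
  }
  max_abs_mass <- function(tv) {
    cl <- both_clusters(tv)
    masses <- c(
      vapply(cl$pos, function(ix) sum(tv[ix]), numeric(1)),
      vapply(cl$neg, function(ix) abs(sum(tv[ix])), numeric(1))
    )
    if (!length(masses)) 0 else max(masses)
  }

  old <- .Random.seed_exists()
  on.exit(old$restore(), add = TRUE)
  set.seed(seed)
  if (exhaustive) n_perm <- 2L^n
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    flips <- if (exhaustive) {
      ifelse(bitwAnd(bitwShiftR(p - 1L, seq_len(n) - 1L), 1L) == 1L, -1, 1)
    } else {
      sample(c(-1, 1), n, replace = TRUE)
    }
    null_max[p] <- max_abs_mass(tstat(data * flips))
  }

  ocl <- both_clusters(tobs)
  rows <- function(cl, sign_lab) {
    if (!length(cl)) return(tibble::tibble())
    mass <- vapply(cl, function(ix) sum(tobs[ix]), numeric(1))
    tibble::tibble(
      sign = sign_lab,
      cluster = seq_along(cl),
      start = vapply(cl, min, integer(1)),
      end = vapply(cl, max, integer(1)),
      samples = cl,
      mass = mass,
      p_perm = vapply(abs(mass), function(m) {
        max(mean(null_max >= m), 1 / n_perm)
      }, numeric(1)),
      n_permutations = n_perm
    )
  }
  out <- dplyr::bind_rows(rows(ocl$pos, "positive"), rows(ocl$neg, "negative"))
  attr(out, "t_map") <- tobs
  attr(out, "threshold") <- crit
  class(out) <- c("cluster_result", class(out))
  out
}

#' Export cluster results as JSON
#'
#' @param clusters A `cluster_result` tibble.
#' @param path Output path.
#' @param times Optional vector mapping sample indices to times (ms or s).
#' @return Invisibly, `path`.
#' @export
write_clusters_json <- function(clusters, path, times = NULL) {
  lst <- purrr::pmap(clusters, function(...) {
    row <- list(...)
    if (!is.null(times)) {
      row$start_time <- times[row$start]
      row$end_time <- times[row$end]
    }
    row$samples <- NULL
    row
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
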