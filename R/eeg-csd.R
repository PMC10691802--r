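# Spherical-spline surface Laplacian (current source density).
# Spline order m, regularization lambda, Legendre series truncation order
# follow the classical scalp CSD formulation; the transform is linear,
# reference-free, and maps uV to uV/cm^2 (up to the head-radius scale).

# Legendre polynomials P_1..P_n evaluated at every element of matrix x;
# returns a list of matrices
.legendre_series <- function(x, n_max) {
  out <- vector("list", n_max)
  p_prev <- matrix(1, nrow(x), ncol(x)) # P_0
  p_cur <- x                            # P_1
  out[[1]] <- p_cur
  for (n in 1:(n_max - 1)) {
    p_next <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
    out[[n + 1]] <- p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  out
}

.csd_gh <- function(cosang, m, n_legendre) {
  P <- .legendre_series(cosang, n_legendre)
  G <- matrix(0, nrow(cosang), ncol(cosang))
  H <- matrix(0, nrow(cosang), ncol(cosang))
  for (n in seq_len(n_legendre)) {
    fac <- (2 * n + 1)
    den <- (n * (n + 1))
    G <- G + fac / den^m * P[[n]]
    H <- H + fac / den^(m - 1) * P[[n]]
  }
  list(G = G / (4 * pi), H = H / (4 * pi))
}

#' Surface-Laplacian current source density transform
#'
#' Applies the spherical-spline surface Laplacian to every trial and time
#' sample, sharpening topographies and removing the dependence on the
#' reference: the CSD of a spatially uniform potential is zero, and adding a
#' constant to all channels leaves the output unchanged. Requires valid
#' spherical channel positions for at least 32 channels.
#'
#' @param epochs An `eeg_epochs` with position columns `x`, `y`, `z`.
#' @param m Spline rigidity order (default 4).
#' @param lambda Ridge regularization (default 1e-5).
#' @param n_legendre Legendre series truncation (default 50).
#' @param head_radius Head radius in cm (default 10); output scales with
#'   `1 / head_radius^2`.
#' @return An `eeg_epochs` in uV/cm^2.
#' @export
csd_transform <- function(epochs, m = 4, lambda = 1e-5, n_legendre = 50,
                          head_radius = 10) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ch <- epochs$channels
  if (!all(c("x", "y", "z") %in% names(ch)) ||
      anyNA(ch$x) || anyNA(ch$y) || anyNA(ch$z)) {
    missing <- if (all(c("x", "y", "z") %in% names(ch))) {
      ch$channel[is.na(ch$x) | is.na(ch$y) | is.na(ch$z)]
    } else ch$channel
    stop("missing spherical positions for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(ch) < 32) {
    stop("CSD needs at least 32 channels with positions", call. = FALSE)
  }

  pos <- as.matrix(ch[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  cosang <- pmin(pmax(tcrossprod(pos), -1), 1)
  gh <- .csd_gh(cosang, m = m, n_legendre = n_legendre)

  Ginv <- solve(gh$G + diag(lambda, nrow(gh$G)))
  TC <- rowSums(Ginv) # = colSums: Ginv is symmetric
  sgi <- sum(TC)

  # CSD = H (Ginv Z - TC (TC' Z) / sgi) = M Z - h1 (TC' Z) / sgi with the
  # spline coefficients constrained to sum to zero
  M <- gh$H %*% Ginv
  h1 <- as.vector(gh$H %*% TC)
  nd <- dim(epochs$data)
  Z <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = nd[2])
  CSD <- (M %*% Z - h1 %o% (as.vector(TC %*% Z) / sgi)) / head_radius^2
  epochs$data <- aperm(array(CSD, c(nd[2], nd[1], nd[3])), c(2, 1, 3))
  epochs$units <- "uV/cm^2"
  epochs
}
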