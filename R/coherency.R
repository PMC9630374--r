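#' @importFrom stats rnorm runif sd
NULL

# Pauli basis in the conventional polarimetric order:
# sigma0 = identity, sigma1 = diag(1,-1), sigma2 = antidiag(1,1),
# sigma3 = [[0,-i],[i,0]].
pauli_basis <- function() {
  list(
    diag(2) + 0i,
    matrix(c(1, 0, 0, -1), 2, 2) + 0i,
    matrix(c(0, 1, 1, 0), 2, 2) + 0i,
    matrix(c(0, 1i, -1i, 0), 2, 2)
  )
}

# 16 x 16 complex matrix mapping the 16 Mueller elements (row-major
# m00..m33) of a pixel to the 16 entries (column-major) of its coherency
# matrix H.  Precomputed once at load time; H_vec = coherency_map %*% m_vec.
coherency_map <- local({
  s <- pauli_basis()
  B <- matrix(0+0i, 16L, 16L)
  for (a in 1:4) {
    for (b in 1:4) {
      B[, 4L * (a - 1L) + b] <- as.vector(s[[a]] %x% Conj(s[[b]])) / 4
    }
  }
  B
})

#' Cloude coherency (covariance) matrix of a Mueller matrix
#'
#' Builds the 4x4 Hermitian coherency matrix `H(M)` whose eigenvalues carry
#' the statistical weights of the Cloude decomposition of `M` into a convex
#' sum of non-depolarizing components.  The construction is the standard
#' Pauli-basis sum `H = (1/4) sum_{a,b} m_ab (sigma_a %x% Conj(sigma_b))`,
#' which maps a pure (non-depolarizing) Mueller matrix to a rank-one `H` and
#' the ideal depolarizer `diag(1,0,0,0)` to `I/4`.
#'
#' @param pixel_matrix A finite 4x4 real Mueller matrix.
#' @return A 4x4 complex Hermitian positive-semidefinite (up to numerical
#'   noise) matrix with trace equal to `m00`.
#' @examples
#' H <- mueller_coherency(diag(4))
#' Re(sum(diag(H)))  # trace = m00 = 1
#' @export
mueller_coherency <- function(pixel_matrix) {
  if (!is.matrix(pixel_matrix) || !all(dim(pixel_matrix) == c(4L, 4L))) {
    stop("'pixel_matrix' must be a 4x4 matrix", call. = FALSE)
  }
  if (!all(is.finite(pixel_matrix))) {
    stop("'pixel_matrix' must be finite", call. = FALSE)
  }
  mvec <- as.vector(t(pixel_matrix))  # row-major m00..m33
  H <- coherency_map %*% mvec
  dim(H) <- c(4L, 4L)
  H
}

#' Sorted, clamped, trace-normalized coherency eigen-spectrum
#'
#' Computes the eigenvalues of a coherency matrix, sorts them in descending
#' order, clamps small negative values caused by measurement noise to zero,
#' and normalizes them by their sum.  Eigenvalues below `-eps_rel * trace`
#' indicate a matrix that is non-physical beyond noise tolerance; they are
#' still clamped but the pixel is flagged via a realizability warning.
#'
#' @param H 4x4 Hermitian matrix (within tolerance).
#' @param eps_rel Relative clamping tolerance; eigenvalues in
#'   `[-eps_rel * trace, 0)` are set to 0 silently.  Default `1e-8`.
#' @param warn Emit a warning when the realizability tolerance is exceeded.
#' @return A list of class `coherency_spectrum` with fields `lambda_raw`
#'   (clamped, sorted descending, original scale), `lambda_hat` (normalized,
#'   summing to 1), `flagged` (realizability flag) and `valid` (`FALSE` when
#'   the trace is not positive).
#' @examples
#' sp <- coherency_spectrum(mueller_coherency(diag(c(1, 0, 0, 0))))
#' sp$lambda_hat  # four equal weights 1/4
#' @export
coherency_spectrum <- function(H, eps_rel = 1e-8, warn = TRUE) {
  if (max(abs(H - Conj(t(H)))) > 1e-6 * max(1, max(abs(H)))) {
    stop("'H' is not Hermitian within tolerance", call. = FALSE)
  }
  lam <- eigen(H, symmetric = TRUE, only.values = TRUE)$values  # descending
  tr <- sum(lam)
  if (!(tr > 0)) {
    return(structure(
      list(lambda_raw = rep(NA_real_, 4L), lambda_hat = rep(NA_real_, 4L),
           flagged = FALSE, valid = FALSE),
      class = "coherency_spectrum"
    ))
  }
  eps <- eps_rel * tr
  flagged <- any(lam < -eps)
  if (flagged && warn) {
    warning(sprintf(
      "coherency eigenvalue %.3g below realizability tolerance -%.3g; clamped and flagged",
      min(lam), eps), call. = FALSE)
  }
  lam[lam < 0] <- 0
  structure(
    list(lambda_raw = lam, lambda_hat = lam / sum(lam),
         flagged = flagged, valid = TRUE),
    class = "coherency_spectrum"
  )
}

#' @export
print.coherency_spectrum <- function(x, ...) {
  cat("<coherency_spectrum>\n")
  cat("  lambda_hat:", format(x$lambda_hat, digits = 6), "\n")
  if (x$flagged) cat("  flagged: realizability tolerance exceeded\n")
  invisible(x)
}
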