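#' Indices of polarimetric purity
#'
#' Combines the sorted, normalized coherency eigenvalues into the three
#' indices of polarimetric purity:
#' `P1 = l0 - l1`, `P2 = l0 + l1 - 2*l2`, `P3 = l0 + l1 + l2 - 3*l3`,
#' with `l0 >= l1 >= l2 >= l3 >= 0` and `sum(l) = 1`, so that
#' `0 <= P1 <= P2 <= P3 <= 1`.  `P1 = P2 = P3 = 1` characterizes a pure
#' (non-depolarizing) system; all three vanish for the ideal depolarizer.
#'
#' @param spectrum A `coherency_spectrum`, or a numeric vector of four
#'   normalized eigenvalues sorted in descending order.
#' @return Named numeric vector `c(P1, P2, P3)`.
#' @examples
#' ipps(c(1, 0, 0, 0))           # pure: (1, 1, 1)
#' ipps(rep(1 / 4, 4))           # ideal depolarizer: (0, 0, 0)
#' @export
ipps <- function(spectrum) {
  l <- if (inherits(spectrum, "coherency_spectrum")) spectrum$lambda_hat else spectrum
  if (length(l) != 4L || anyNA(l)) {
    stop("'spectrum' must supply four normalized eigenvalues", call. = FALSE)
  }
  if (is.unsorted(rev(l), strictly = FALSE) || abs(sum(l) - 1) > 1e-8 || any(l < -1e-12)) {
    stop("eigen-spectrum must be sorted descending, non-negative and sum to 1",
         call. = FALSE)
  }
  c(P1 = l[1] - l[2],
    P2 = l[1] + l[2] - 2 * l[3],
    P3 = l[1] + l[2] + l[3] - 3 * l[4])
}

#' Components of purity
#'
#' Diattenuation, polarizance and degree of spherical purity of a Mueller
#' matrix, all computed on the `m00`-normalized matrix so they are invariant
#' to the overall intensity scale:
#' `D = sqrt(m01^2 + m02^2 + m03^2) / m00`,
#' `P = sqrt(m10^2 + m20^2 + m30^2) / m00`,
#' `P_S = ||m||_F / (sqrt(3) * m00)` with `m` the lower-right 3x3 submatrix
#' and `||.||_F` the Frobenius norm.  All three lie in `[0, 1]` for physically
#' realizable matrices.
#'
#' @param pixel_matrix 4x4 real Mueller matrix with `m00 > 0`.
#' @return Named numeric vector `c(D, P, P_S)`.
#' @examples
#' purity_components(diag(4))  # D = P = 0, P_S = 1
#' @export
purity_components <- function(pixel_matrix) {
  m00 <- pixel_matrix[1L, 1L]
  if (!(m00 > 0)) stop("'pixel_matrix' must have m00 > 0", call. = FALSE)
  D <- sqrt(sum(pixel_matrix[1L, 2:4]^2)) / m00
  P <- sqrt(sum(pixel_matrix[2:4, 1L]^2)) / m00
  PS <- sqrt(sum(pixel_matrix[2:4, 2:4]^2)) / (sqrt(3) * m00)
  c(D = D, P = P, P_S = PS)
}

#' Depolarization index
#'
#' Overall depolarization metric in `[0, 1]` (0 = ideal depolarizer, 1 = pure
#' system).  It admits two equivalent forms, one on the components of purity
#' and one on the indices of polarimetric purity:
#' `P_Delta = sqrt(D^2 + P^2 + 3*P_S^2) / sqrt(3)
#'          = sqrt(2*P1^2 + (2/3)*P2^2 + (1/3)*P3^2) / sqrt(3)`.
#' When both triplets are supplied the two forms are cross-checked; a
#' discrepancy beyond `tol` flags numerical or realizability problems (for
#' example eigenvalue clamping of a noisy, slightly non-physical matrix) with
#' a consistency warning.
#'
#' @param cp Numeric vector `c(D, P, P_S)`, or `NULL`.
#' @param ipp Numeric vector `c(P1, P2, P3)`, or `NULL`.  At least one of
#'   `cp`, `ipp` must be given.
#' @param tol Consistency tolerance for the two forms.  Default `1e-9`.
#' @return The depolarization index, a number in `[0, 1]`.
#' @examples
#' depolarization_index(cp = c(0, 0, 1))       # pure: 1
#' depolarization_index(ipp = c(0, 0, 0))      # ideal depolarizer: 0
#' @export
depolarization_index <- function(cp = NULL, ipp = NULL, tol = 1e-9) {
  from_cp <- if (!is.null(cp)) {
    sqrt(cp[[1]]^2 + cp[[2]]^2 + 3 * cp[[3]]^2) / sqrt(3)
  }
  from_ipp <- if (!is.null(ipp)) {
    sqrt(2 * ipp[[1]]^2 + (2 / 3) * ipp[[2]]^2 + (1 / 3) * ipp[[3]]^2) / sqrt(3)
  }
  if (is.null(from_cp) && is.null(from_ipp)) {
    stop("supply at least one of 'cp', 'ipp'", call. = FALSE)
  }
  if (!is.null(from_cp) && !is.null(from_ipp) && abs(from_cp - from_ipp) > tol) {
    warning(sprintf(
      "depolarization index forms disagree by %.3g (numerical or realizability problem)",
      abs(from_cp - from_ipp)), call. = FALSE)
  }
  unname(if (is.null(from_cp)) from_ipp else from_cp)
}

observable_names <- c("m00", "D", "P", "P_S", "P1", "P2", "P3", "P_Delta")

#' Channel names of an observable triplet
#'
#' @param triplet `"ipp"` for `(P1, P2, P3)` or `"cp"` for `(P, D, P_S)`.
#' @return Character vector of three channel names.
#' @export
triplet_channels <- function(triplet = c("ipp", "cp")) {
  triplet <- match.arg(triplet)
  if (triplet == "ipp") c("P1", "P2", "P3") else c("P", "D", "P_S")
}

#' Compute the full depolarization observable stack of a Mueller image
#'
#' Applies, per pixel, the coherency construction, eigen-spectrum and indices
#' of polarimetric purity, together with the components of purity and the
#' depolarization index, producing the eight channels `m00`, `D`, `P`, `P_S`,
#' `P1`, `P2`, `P3`, `P_Delta`.  Invalid pixels (`m00 <= 0`, or a coherency
#' trace that is not positive) propagate as `NA` under the mask; pixels whose
#' spectrum needed clamping beyond the realizability tolerance are recorded in
#' the `flagged` matrix (a single summary warning is emitted).
#'
#' @param image A [mueller_image].
#' @param eps_rel Relative eigenvalue clamping tolerance (see
#'   [coherency_spectrum]).  Default `1e-8`.
#' @return An object of class `observable_stack`: list with `channels` (named
#'   list of `height x width` matrices), `mask`, `flagged`, `height`, `width`.
#' @examples
#' el <- array(0, c(2, 2, 4, 4))
#' for (a in 1:4) el[, , a, a] <- 1
#' st <- compute_observables(mueller_image(el))
#' st$channels$P_Delta
#' @export
compute_observables <- function(image, eps_rel = 1e-8) {
  stopifnot(inherits(image, "mueller_image"))
  h <- image$height
  w <- image$width
  n <- h * w
  mv <- flatten_elements(image)
  mask <- as.vector(image$mask)

  m00 <- mv[, 1L]
  safe <- ifelse(mask, m00, NA_real_)
  D  <- sqrt(mv[, 2L]^2 + mv[, 3L]^2 + mv[, 4L]^2) / safe
  P  <- sqrt(mv[, 5L]^2 + mv[, 9L]^2 + mv[, 13L]^2) / safe
  sub <- c(6L, 7L, 8L, 10L, 11L, 12L, 14L, 15L, 16L)
  PS <- sqrt(rowSums(mv[, sub, drop = FALSE]^2)) / (sqrt(3) * safe)

  # coherency entries for all pixels at once, then a per-pixel eigen solve
  Hflat <- mv %*% t(coherency_map)
  P1 <- P2 <- P3 <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (i in which(mask)) {
    Hp <- Hflat[i, ]
    dim(Hp) <- c(4L, 4L)
    lam <- eigen(Hp, symmetric = TRUE, only.values = TRUE)$values
    tr <- sum(lam)
    if (!(tr > 0)) {
      mask[i] <- FALSE
      next
    }
    if (any(lam < -eps_rel * tr)) flagged[i] <- TRUE
    lam[lam < 0] <- 0
    lh <- lam / sum(lam)
    P1[i] <- lh[1L] - lh[2L]
    P2[i] <- lh[1L] + lh[2L] - 2 * lh[3L]
    P3[i] <- lh[1L] + lh[2L] + lh[3L] - 3 * lh[4L]
  }
  if (any(flagged)) {
    warning(sprintf(
      "%d pixel(s) exceeded the realizability tolerance; eigenvalues clamped",
      sum(flagged)), call. = FALSE)
  }

  PDelta <- sqrt(D^2 + P^2 + 3 * PS^2) / sqrt(3)
  bad <- !mask
  for (v in c("D", "P", "PS", "P1", "P2", "P3", "PDelta")) {
    x <- get(v)
    x[bad] <- NA_real_
    assign(v, x)
  }
  as_mat <- function(x) matrix(x, h, w)
  structure(
    list(
      channels = list(
        m00 = as_mat(m00), D = as_mat(D), P = as_mat(P), P_S = as_mat(PS),
        P1 = as_mat(P1), P2 = as_mat(P2), P3 = as_mat(P3),
        P_Delta = as_mat(PDelta)
      ),
      mask = as_mat(mask),
      flagged = as_mat(flagged),
      height = h, width = w
    ),
    class = "observable_stack"
  )
}

#' @export
print.observable_stack <- function(x, ...) {
  cat(sprintf("<observable_stack> %d x %d pixels (%d valid, %d flagged)\n",
              x$height, x$width, sum(x$mask), sum(x$flagged)))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]][x$mask]
    if (length(ch)) {
      cat(sprintf("  %-8s [%.4f, %.4f]\n", nm, min(ch), max(ch)))
    }
  }
  invisible(x)
}

#' @export
dim.observable_stack <- function(x) c(x$height, x$width)

# n_valid x 3 matrix of one triplet's values plus the index of those pixels
triplet_matrix <- function(stack, triplet) {
  chans <- triplet_channels(triplet)
  idx <- which(as.vector(stack$mask))
  p <- vapply(chans, function(nm) as.vector(stack$channels[[nm]])[idx],
              numeric(length(idx)))
  if (length(idx) == 1L) p <- matrix(p, 1L, 3L, dimnames = list(NULL, chans))
  list(p = p, idx = idx)
}
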