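# 4x4 Mueller rotation block for an element rotated by theta (physical angle)
mueller_rotator <- function(psi) {
  c2 <- cos(psi); s2 <- sin(psi)
  matrix(c(1, 0, 0, 0,
           0, c2, -s2, 0,
           0, s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Textbook non-depolarizing Mueller elements
#'
#' Builds a pure (non-depolarizing) Mueller matrix of one of three kinds:
#' * `"identity"` — free space;
#' * `"linear_diattenuator"` — partial linear polarizer with diattenuation
#'   `d` at azimuth `theta` (`d = 1` is the ideal polarizer);
#' * `"linear_retarder"` — linear retarder with retardance `delta` at azimuth
#'   `theta` (`delta = pi/2` is a quarter-wave, `pi` a half-wave plate).
#'
#' All returned matrices are normalized to `m00 = 1` and pass the
#' non-depolarizing check (coherency spectrum `(1, 0, 0, 0)`).
#'
#' @param kind One of `"identity"`, `"linear_diattenuator"`,
#'   `"linear_retarder"`.
#' @param d Diattenuation in `[0, 1]` (diattenuator only).
#' @param delta Retardance in `[0, 2*pi)` (retarder only).
#' @param theta Azimuth of the element's axis in `[0, pi)`.
#' @return A 4x4 Mueller matrix.
#' @examples
#' pure_element("linear_retarder", delta = pi / 2, theta = 0)
#' @export
pure_element <- function(kind = c("identity", "linear_diattenuator",
                                  "linear_retarder"),
                         d = 1, delta = pi / 2, theta = 0) {
  kind <- match.arg(kind)
  if (kind == "identity") return(diag(4))
  if (theta < 0 || theta >= pi) {
    stop("'theta' must lie in [0, pi)", call. = FALSE)
  }
  R <- mueller_rotator(2 * theta)
  M0 <- if (kind == "linear_diattenuator") {
    if (d < 0 || d > 1) stop("'d' must lie in [0, 1]", call. = FALSE)
    q <- sqrt(1 - d^2)
    matrix(c(1, d, 0, 0,
             d, 1, 0, 0,
             0, 0, q, 0,
             0, 0, 0, q), 4, 4, byrow = TRUE)
  } else {
    if (delta < 0 || delta >= 2 * pi) {
      stop("'delta' must lie in [0, 2*pi)", call. = FALSE)
    }
    cd <- cos(delta); sd_ <- sin(delta)
    matrix(c(1, 0, 0, 0,
             0, 1, 0, 0,
             0, 0, cd, sd_,
             0, 0, -sd_, cd), 4, 4, byrow = TRUE)
  }
  R %*% M0 %*% t(R)
}

#' Mueller matrix of a Jones matrix
#'
#' Converts a (possibly complex) 2x2 Jones matrix to its 4x4 real Mueller
#' matrix.  Any Jones-derived Mueller matrix is non-depolarizing, which makes
#' this the natural source of random pure components for Cloude mixtures.
#'
#' @param J Complex 2x2 Jones matrix.
#' @param normalize Scale the result to `m00 = 1` (requires a nonzero `J`).
#'   Default `TRUE`.
#' @return A 4x4 real Mueller matrix.
#' @export
jones_to_mueller <- function(J, normalize = TRUE) {
  stopifnot(is.matrix(J), all(dim(J) == c(2L, 2L)))
  A <- matrix(c(1, 1, 0, 0,
                0, 0, 1, 1i,
                0, 0, 1, -1i,
                1, -1, 0, 0), 4, 4)
  M <- Re(A %*% (J %x% Conj(J)) %*% solve(A))
  if (normalize) {
    if (!(M[1L, 1L] > 0)) stop("'J' must be nonzero to normalize", call. = FALSE)
    M <- M / M[1L, 1L]
  }
  M
}

#' Random non-depolarizing Mueller matrix
#'
#' Draws a random complex Jones matrix (standard normal real and imaginary
#' parts) and converts it with [jones_to_mueller]; the result is a generic
#' pure element (elliptical diattenuating retarder) normalized to `m00 = 1`.
#'
#' @return A 4x4 pure Mueller matrix.
#' @export
rand_pure_mueller <- function() {
  repeat {
    J <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2L, 2L)
    if (sum(Mod(J)^2) > 1e-6) break
  }
  jones_to_mueller(J)
}

#' Check that a Mueller matrix is non-depolarizing
#'
#' @param M 4x4 Mueller matrix.
#' @param tol Tolerance on the coherency spectrum distance from `(1,0,0,0)`.
#'   Default `1e-8`.
#' @return `TRUE` if the normalized coherency spectrum is `(1, 0, 0, 0)`
#'   within `tol`.
#' @export
is_pure_mueller <- function(M, tol = 1e-8) {
  sp <- coherency_spectrum(mueller_coherency(M), warn = FALSE)
  isTRUE(sp$valid) && max(abs(sp$lambda_hat - c(1, 0, 0, 0))) < tol
}

#' Convex (Cloude) mixture of pure Mueller components
#'
#' Builds `M = m00 * sum_i w_i * M_i` from convex weights and
#' non-depolarizing components, the parallel (incoherent) combination
#' underlying the Cloude decomposition.  The result is physically realizable
#' by construction: its coherency eigenvalues are non-negative.
#'
#' @param weights Four convex coefficients (non-negative, summing to 1
#'   within `1e-9`).
#' @param components List of four pure Mueller matrices (checked with
#'   [is_pure_mueller] unless `check = FALSE`); each is used
#'   `m00`-normalized.
#' @param m00 Overall intensity scale.  Default 1.
#' @param check Verify that each component is pure.  Default `TRUE`.
#' @return A 4x4 Mueller matrix.
#' @examples
#' cloude_mixture(c(0.5, 0.5, 0, 0),
#'                list(pure_element("identity"),
#'                     pure_element("linear_retarder", delta = pi),
#'                     pure_element("identity"), pure_element("identity")))
#' @export
cloude_mixture <- function(weights, components, m00 = 1, check = TRUE) {
  weights <- as.numeric(weights)
  if (length(weights) != 4L || any(weights < -1e-12) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("'weights' must be four non-negative coefficients summing to 1",
         call. = FALSE)
  }
  if (length(components) != 4L) {
    stop("'components' must list four pure Mueller matrices", call. = FALSE)
  }
  if (check && !all(vapply(components, is_pure_mueller, logical(1L)))) {
    stop("every component must be non-depolarizing (pure)", call. = FALSE)
  }
  M <- matrix(0, 4L, 4L)
  for (i in 1:4) {
    Mi <- components[[i]] / components[[i]][1L, 1L]
    M <- M + weights[i] * Mi
  }
  m00 * M
}

#' The four Pauli-eigenstate pure components
#'
#' The pure Mueller matrices of the Jones matrices `sigma_0..sigma_3`
#' (identity and the half-wave retarder family `diag(1,1,-1,-1)`,
#' `diag(1,-1,1,-1)`, `diag(1,-1,-1,1)`).  Their equal-weight Cloude mixture
#' is the ideal depolarizer `diag(1, 0, 0, 0)`.
#'
#' @return List of four 4x4 pure Mueller matrices.
#' @export
pauli_pure_set <- function() {
  list(diag(4),
       diag(c(1, 1, -1, -1)),
       diag(c(1, -1, 1, -1)),
       diag(c(1, -1, -1, 1)))
}

#' Random physically realizable Mueller matrix
#'
#' Draws Dirichlet(1,1,1,1) convex weights and four random pure components
#' and returns their Cloude mixture — a generic depolarizing but realizable
#' Mueller matrix, useful for property tests.
#'
#' @param m00 Intensity scale.  Default 1.
#' @return A 4x4 Mueller matrix.
#' @export
rand_cloude_mixture <- function(m00 = 1) {
  w <- -log(runif(4))
  cloude_mixture(w / sum(w), replicate(4, rand_pure_mueller(), simplify = FALSE),
                 m00 = m00, check = FALSE)
}

# label maps for the built-in layouts (values 1..k)
layout_labels <- function(layout, height, width, k, n_stripes = 2L * k) {
  x <- matrix(rep(seq_len(width), each = height), height, width)
  y <- matrix(rep(seq_len(height), times = width), height, width)
  switch(layout,
    halfplane = {
      if (k != 2L) stop("'halfplane' layout needs exactly 2 classes", call. = FALSE)
      ifelse(x <= width / 2, 1L, 2L) + 0L * y
    },
    stripes = {
      band <- ceiling(y / (height / n_stripes))
      ((band - 1L) %% k) + 1L
    },
    disks = {
      lab <- matrix(1L, height, width)
      if (k > 1L) {
        centers <- cbind(
          row = height * (seq_len(k - 1L)) / k,
          col = width * (seq_len(k - 1L)) / k
        )
        r <- min(height, width) / (2L * k)
        for (i in seq_len(k - 1L)) {
          d2 <- (y - centers[i, "row"])^2 + (x - centers[i, "col"])^2
          lab[d2 <= r^2] <- i + 1L
        }
      }
      lab
    },
    stop(sprintf("unknown layout '%s'", layout), call. = FALSE)
  )
}

#' Generate a synthetic labeled Mueller-matrix scene
#'
#' Builds a piecewise-constant Mueller image from per-class ground-truth
#' matrices on one of three layouts — `"halfplane"` (left/right split,
#' 2 classes), `"stripes"` (horizontal bands cycling through the classes,
#' emulating ring-like structures) or `"disks"` (class disks on a background,
#' emulating lesions) — and perturbs every element with additive Gaussian
#' noise of standard deviation `noise_sd * m00`.  The generator is
#' deterministic under a fixed seed.  Noisy pixels may be slightly
#' non-physical; the observable pipeline's eigenvalue clamping handles them.
#'
#' @param class_matrices List of `k` ground-truth 4x4 Mueller matrices.
#' @param layout `"halfplane"`, `"stripes"` or `"disks"`.
#' @param height,width Raster size in pixels.  Default 128.
#' @param noise_sd Element-wise noise scale relative to `m00`.  Default 0.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param n_stripes Number of bands for the `"stripes"` layout.
#' @return List with `image` (a [mueller_image]) and `scene` (class
#'   `synthetic_scene`: `label_map`, `class_matrices`, `noise_sd`, `seed`).
#' @examples
#' sc <- generate_scene(list(diag(4), diag(c(1, 0, 0, 0))),
#'                      layout = "halfplane", height = 8, width = 8,
#'                      noise_sd = 0.005, seed = 1)
#' table(sc$scene$label_map)
#' @export
generate_scene <- function(class_matrices, layout = c("halfplane", "stripes",
                                                      "disks"),
                           height = 128L, width = 128L, noise_sd = 0,
                           seed = NULL, n_stripes = NULL) {
  layout <- match.arg(layout)
  if (length(class_matrices) < 1L) {
    stop("at least one class matrix is required", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  k <- length(class_matrices)
  if (is.null(n_stripes)) n_stripes <- 2L * k
  if (!is.null(seed)) set.seed(as.integer(seed))
  lab <- layout_labels(layout, height, width, k, n_stripes)
  el <- array(0, c(height, width, 4L, 4L))
  for (i in seq_len(k)) {
    Mi <- class_matrices[[i]]
    sel <- lab == i
    for (a in 1:4) for (b in 1:4) {
      plane <- el[, , a, b]
      plane[sel] <- Mi[a, b]
      el[, , a, b] <- plane
    }
  }
  if (noise_sd > 0) {
    m00 <- el[, , 1L, 1L]
    noise <- array(rnorm(length(el)), dim(el)) * noise_sd *
      array(rep(as.vector(m00), 16L), dim(el))
    el <- el + noise
  }
  list(
    image = mueller_image(el),
    scene = structure(
      list(label_map = lab, class_matrices = class_matrices,
           noise_sd = noise_sd, seed = seed),
      class = "synthetic_scene"
    )
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d class(es), noise_sd = %g, seed = %s\n",
              length(x$class_matrices), x$noise_sd,
              if (is.null(x$seed)) "none" else x$seed))
  print(table(class = x$label_map))
  invisible(x)
}
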