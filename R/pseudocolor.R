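#' Euclidean-distance class weights for a two-class pixel
#'
#' For a pixel with observable triplet `p` and two classes with means `m^1`,
#' `m^2`, the normalized distance to class `i` is
#' `d_i = sqrt(sum_j ((m_j^i - p_j) / (m_j^1 - m_j^2))^2)` and the color
#' weight is `R_i = 1 - d_i / (d_1 + d_2)`, so the weights are in `[0, 1]`
#' and sum to 1.  A pixel far from both classes has `d_1 ~ d_2`, hence
#' weights near 1/2 and an equal mixture of the two class colors: the method
#' enhances contrast but is not a classifier.
#'
#' If some observable has (numerically) equal class means its per-observable
#' scaling is undefined; that observable is dropped with a warning.  If every
#' observable is degenerate the two classes are indistinguishable and an
#' error is raised.
#'
#' @param p Numeric vector of 3 observable values (or an `n x 3` matrix of
#'   pixels).
#' @param class1,class2 [class_model] objects on the same triplet.
#' @param mean_tol Two means closer than this are treated as degenerate.
#'   Default `1e-9`.
#' @return For a single pixel, a list of class `euclidean_weights` with
#'   `d_norm` (length 2), `d_total` and `weights` (length 2, summing to 1).
#'   For a matrix input, an `n x 2` matrix of weights.
#' @examples
#' c1 <- class_model("a", c(0.8, 0.9, 1.0), rep(0.05, 3), "yellow")
#' c2 <- class_model("b", c(0.2, 0.3, 0.4), rep(0.05, 3), "blue")
#' euclidean_weights(c(0.5, 0.6, 0.7), c1, c2)$weights  # (1/2, 1/2)
#' @export
euclidean_weights <- function(p, class1, class2, mean_tol = 1e-9) {
  stopifnot(inherits(class1, "class_model"), inherits(class2, "class_model"))
  if (class1$triplet != class2$triplet) {
    stop("the two classes use different observable triplets", call. = FALSE)
  }
  den <- class1$means - class2$means
  keep <- abs(den) > mean_tol
  if (!any(keep)) {
    stop("all observables have equal class means; classes are indistinguishable",
         call. = FALSE)
  }
  if (!all(keep)) {
    warning(sprintf(
      "observable(s) %s have equal class means and are dropped from the distance",
      paste(names(den)[!keep], collapse = ", ")), call. = FALSE)
  }
  single <- is.null(dim(p))
  pm <- if (single) matrix(p, 1L, 3L) else as.matrix(p)
  if (ncol(pm) != 3L) stop("'p' must have 3 observables", call. = FALSE)

  z1 <- sweep(pm[, keep, drop = FALSE], 2L, class1$means[keep]) /
    rep(den[keep], each = nrow(pm))
  z2 <- sweep(pm[, keep, drop = FALSE], 2L, class2$means[keep]) /
    rep(den[keep], each = nrow(pm))
  d1 <- sqrt(rowSums(z1^2))
  d2 <- sqrt(rowSums(z2^2))
  d <- d1 + d2
  w1 <- ifelse(d > 0, 1 - d1 / d, 0.5)  # p on both means at once: split evenly
  W <- cbind(w1, 1 - w1)
  colnames(W) <- c(class1$name, class2$name)
  if (single) {
    structure(
      list(d_norm = c(d1, d2), d_total = d, weights = W[1L, ]),
      class = "euclidean_weights"
    )
  } else {
    W
  }
}

# shared clipping + masking for rendered color planes
finish_rgb <- function(rgbflat, mask, h, w) {
  rgbflat[!mask, ] <- 0
  rgbflat[rgbflat < 0] <- 0
  rgbflat[rgbflat > 1] <- 1
  array(rgbflat, c(h, w, 3L))
}

#' Two-class Euclidean-distance pseudo-colored image
#'
#' Renders `R^1 * C^1 + R^2 * C^2` per pixel, where the weights come from
#' [euclidean_weights] on the chosen observable triplet and `C^i` are the
#' class colors.  The result is clipped to `[0, 1]`; masked pixels are black.
#' The method is restricted to exactly two classes; with more classes use the
#' Normal-probability method ([normal_pseudocolor]).
#'
#' @param stack An [observable_stack].
#' @param class1,class2 [class_model] objects on the same triplet.
#' @param unclipped Also return the unclipped color planes.  Default `FALSE`.
#' @return Object of class `pseudocolor_image`: list with `rgb`
#'   (`height x width x 3` array in `[0,1]`), `weights` (`height x width x 2`),
#'   `method = "euclidean"`, `classes`, and optionally `raw`.
#' @export
euclidean_pseudocolor <- function(stack, class1, class2, unclipped = FALSE) {
  stopifnot(inherits(stack, "observable_stack"))
  tm <- triplet_matrix(stack, class1$triplet)
  n <- stack$height * stack$width
  W <- matrix(NA_real_, n, 2L)
  W[tm$idx, ] <- euclidean_weights(tm$p, class1, class2)
  raw <- matrix(0, n, 3L)
  raw[tm$idx, ] <- W[tm$idx, 1L] %o% class1$color + W[tm$idx, 2L] %o% class2$color
  mask <- rep(FALSE, n)
  mask[tm$idx] <- TRUE
  out <- list(
    rgb = finish_rgb(raw, mask, stack$height, stack$width),
    weights = array(W, c(stack$height, stack$width, 2L)),
    method = "euclidean",
    classes = list(class1, class2)
  )
  if (unclipped) out$raw <- array(raw, c(stack$height, stack$width, 3L))
  structure(out, class = "pseudocolor_image")
}

#' Gaussian class-membership probability
#'
#' Probability-like score of a pixel belonging to a class, the product over
#' observables of unnormalized Gaussians:
#' `P = prod_j exp(-((p_j - m_j) / s_j)^2)`.
#' The exponent is the squared z-score (no factor 1/2, no normalizing
#' constant), so the score is exactly 1 at the class means and decays to 0
#' far from them; it always lies in `[0, 1]`.
#'
#' @param p Numeric vector of 3 observable values, or an `n x 3` matrix.
#' @param class A [class_model] (its standard deviations are floored, so the
#'   score is always finite).
#' @return Probability value(s) in `[0, 1]`.
#' @examples
#' cl <- class_model("a", rep(0.5, 3), rep(0.1, 3), "pink")
#' normal_probability(rep(0.5, 3), cl)  # 1 at the means
#' normal_probability(rep(0.6, 3), cl)  # exp(-3)
#' @export
normal_probability <- function(p, class) {
  stopifnot(inherits(class, "class_model"))
  single <- is.null(dim(p))
  pm <- if (single) matrix(p, 1L, 3L) else as.matrix(p)
  if (ncol(pm) != 3L) stop("'p' must have 3 observables", call. = FALSE)
  z <- sweep(pm, 2L, class$means) / rep(class$stds, each = nrow(pm))
  out <- exp(-rowSums(z^2))
  if (single) out[[1L]] else out
}

#' k-class Normal-probability pseudo-colored image
#'
#' Renders `sum_i P^i * C^i` per pixel, where `P^i` is the Gaussian
#' class-membership score of [normal_probability] and `C^i` the class colors.
#' Channel sums above 1 (overlapping classes with non-complementary colors)
#' are clipped; pixels far from every class have all `P^i ~ 0` and come out
#' black with no explicit threshold.  Any number of classes `k >= 1` is
#' supported, and the returned per-class probability maps make the result
#' usable for classification (see [classify_pixels]).
#'
#' @param stack An [observable_stack].
#' @param classes List of [class_model] objects, all on the same triplet.
#' @param unclipped Also return the unclipped color planes.  Default `FALSE`.
#' @return Object of class `pseudocolor_image`: list with `rgb`, `prob`
#'   (`height x width x k` array), `method = "normal"`, `classes`, and
#'   optionally `raw`.
#' @export
normal_pseudocolor <- function(stack, classes, unclipped = FALSE) {
  stopifnot(inherits(stack, "observable_stack"))
  if (inherits(classes, "class_model")) classes <- list(classes)
  k <- length(classes)
  if (k < 1L) stop("at least one class is required", call. = FALSE)
  triplet <- classes[[1L]]$triplet
  if (!all(vapply(classes, function(cl) cl$triplet == triplet, logical(1L)))) {
    stop("all classes must use the same observable triplet", call. = FALSE)
  }
  tm <- triplet_matrix(stack, triplet)
  n <- stack$height * stack$width
  prob <- matrix(NA_real_, n, k)
  raw <- matrix(0, n, 3L)
  for (i in seq_len(k)) {
    prob[tm$idx, i] <- normal_probability(tm$p, classes[[i]])
    raw[tm$idx, ] <- raw[tm$idx, ] + prob[tm$idx, i] %o% classes[[i]]$color
  }
  mask <- rep(FALSE, n)
  mask[tm$idx] <- TRUE
  out <- list(
    rgb = finish_rgb(raw, mask, stack$height, stack$width),
    prob = array(prob, c(stack$height, stack$width, k)),
    method = "normal",
    classes = classes
  )
  if (unclipped) out$raw <- array(raw, c(stack$height, stack$width, 3L))
  structure(out, class = "pseudocolor_image")
}

#' @export
print.pseudocolor_image <- function(x, ...) {
  cat(sprintf("<pseudocolor_image> %s method, %d x %d pixels, classes: %s\n",
              x$method, dim(x$rgb)[1L], dim(x$rgb)[2L],
              paste(vapply(x$classes, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' Hard class labels from a Normal-probability pseudo-color result
#'
#' Assigns each pixel to the class with the highest Gaussian membership
#' score; pixels whose best score falls below `threshold` (or that are
#' masked) are left unassigned (label 0).  Only the Normal method supports
#' classification — the Euclidean weights of pixels outside both classes tend
#' to 1/2 and carry no class identity.
#'
#' @param pc A `pseudocolor_image` produced by [normal_pseudocolor].
#' @param threshold Minimum best-class probability for assignment.  Default
#'   `1e-3`.
#' @return Integer `height x width` matrix; 0 = unassigned, `i` = index into
#'   `pc$classes`.
#' @export
classify_pixels <- function(pc, threshold = 1e-3) {
  stopifnot(inherits(pc, "pseudocolor_image"))
  if (!identical(pc$method, "normal")) {
    stop("classification requires the Normal-probability method", call. = FALSE)
  }
  d <- dim(pc$prob)
  pm <- matrix(pc$prob, d[1L] * d[2L], d[3L])
  best <- max.col(replace(pm, is.na(pm), -Inf), ties.method = "first")
  bestp <- pm[cbind(seq_len(nrow(pm)), best)]
  best[is.na(bestp) | bestp < threshold] <- 0L
  matrix(best, d[1L], d[2L])
}
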