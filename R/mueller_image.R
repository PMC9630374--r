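#' Mueller-matrix image container
#'
#' Bundles an `(height, width, 4, 4)` array of per-pixel real Mueller matrices
#' with a per-pixel validity mask.  The raster is row-major with 0-based pixel
#' indices and the origin at the top-left corner; element `[y, x, a, b]` is the
#' Mueller element `m_{a-1,b-1}` of the pixel in row `y`, column `x`.
#'
#' Pixels where no light was detected (`m00 <= 0`) carry no polarimetric
#' information (every observable divides by `m00`), so they are marked invalid
#' in the mask and rendered black downstream.
#'
#' @param elements Numeric array of shape `(height, width, 4, 4)`, all finite.
#' @param mask Optional logical `height x width` matrix of valid pixels.
#'   Pixels with `m00 <= 0` are forced invalid regardless of `mask`.
#' @return An object of class `mueller_image`: a list with fields `elements`,
#'   `mask`, `height`, `width`.
#' @examples
#' m <- array(0, c(2, 3, 4, 4))
#' m[, , 1, 1] <- 1
#' img <- mueller_image(m)
#' img$height
#' @export
mueller_image <- function(elements, mask = NULL) {
  if (!is.array(elements) || length(dim(elements)) != 4L ||
      !all(dim(elements)[3:4] == c(4L, 4L))) {
    stop("'elements' must be a (height, width, 4, 4) numeric array", call. = FALSE)
  }
  if (!all(is.finite(elements))) {
    stop("Mueller elements must all be finite", call. = FALSE)
  }
  h <- dim(elements)[1L]
  w <- dim(elements)[2L]
  m00 <- elements[, , 1L, 1L, drop = TRUE]
  dim(m00) <- c(h, w)
  if (is.null(mask)) {
    mask <- matrix(TRUE, h, w)
  } else {
    mask <- matrix(as.logical(mask), h, w)
  }
  mask <- mask & (m00 > 0)
  structure(
    list(elements = elements, mask = mask, height = h, width = w),
    class = "mueller_image"
  )
}

#' @export
print.mueller_image <- function(x, ...) {
  cat(sprintf("<mueller_image> %d x %d pixels (%d valid)\n",
              x$height, x$width, sum(x$mask)))
  m00 <- x$elements[, , 1L, 1L]
  cat(sprintf("  m00 range: [%.4g, %.4g]\n", min(m00), max(m00)))
  invisible(x)
}

#' @export
dim.mueller_image <- function(x) c(x$height, x$width)

# Flatten the per-pixel matrices to an (n_pixels x 16) matrix in row-major
# element order m00, m01, ..., m33.  Pixel order is column-within-row raster
# order consistent with matrix indexing used throughout.
flatten_elements <- function(image) {
  h <- image$height
  w <- image$width
  el <- image$elements
  out <- matrix(0, h * w, 16L)
  for (a in 1:4) {
    for (b in 1:4) {
      out[, 4L * (a - 1L) + b] <- as.vector(el[, , a, b])
    }
  }
  out
}
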