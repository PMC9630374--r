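#' Color presets used for tissue classes
#'
#' Named RGB triplets in `[0,1]`: `yellow`, `blue`, `pink`, `lime_green`.
#' Complementary pairs (yellow/blue, pink/lime-green) keep two-class color
#' sums inside the RGB cube.
#'
#' @format Named list of length-3 numeric vectors.
#' @export
class_colors <- list(
  yellow     = c(1, 1, 0),
  blue       = c(0, 0, 1),
  pink       = c(1, 0, 0.5),
  lime_green = c(0, 1, 0.5)
)

#' Tissue-class model for pseudo-coloring
#'
#' A class is characterized by the per-observable means and standard
#' deviations of a chosen observable triplet, estimated from one or more
#' regions of interest, plus the RGB color the class contributes to the
#' pseudo-colored image.
#'
#' @param name Class label.
#' @param means Numeric vector of 3 per-observable means.
#' @param stds Numeric vector of 3 per-observable standard deviations;
#'   floored at `sigma_floor`.
#' @param color RGB triplet, each component in `[0, 1]`, or the name of a
#'   preset in [class_colors].
#' @param triplet Observable triplet the statistics refer to (`"ipp"` or
#'   `"cp"`).
#' @param sigma_floor Minimum admissible standard deviation (a constant ROI
#'   would otherwise produce zero and break the Gaussian model).  Default
#'   `1e-6`.
#' @param n_pixels Optional number of pixels the statistics came from.
#' @return An object of class `class_model`.
#' @examples
#' class_model("ring", c(0.14, 0.27, 0.37), c(0.02, 0.03, 0.03), "yellow")
#' @export
class_model <- function(name, means, stds, color, triplet = c("ipp", "cp"),
                        sigma_floor = 1e-6, n_pixels = NA_integer_) {
  triplet <- match.arg(triplet)
  if (is.character(color)) {
    if (!color %in% names(class_colors)) {
      stop(sprintf("unknown color preset '%s'", color), call. = FALSE)
    }
    color <- class_colors[[color]]
  }
  color <- as.numeric(color)
  if (length(color) != 3L || any(color < 0) || any(color > 1)) {
    stop("'color' must be an RGB triplet with components in [0, 1]", call. = FALSE)
  }
  means <- as.numeric(means)
  stds <- as.numeric(stds)
  if (length(means) != 3L || length(stds) != 3L || anyNA(means) || anyNA(stds)) {
    stop("'means' and 'stds' must be numeric vectors of length 3", call. = FALSE)
  }
  if (sigma_floor <= 0) stop("'sigma_floor' must be positive", call. = FALSE)
  chans <- triplet_channels(triplet)
  names(means) <- names(stds) <- chans
  structure(
    list(name = as.character(name), means = means,
         stds = pmax(stds, sigma_floor), color = color, triplet = triplet,
         sigma_floor = sigma_floor, n_pixels = n_pixels),
    class = "class_model"
  )
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("<class_model> '%s' (%s triplet, color [%s])\n",
              x$name, x$triplet, paste(format(x$color), collapse = ", ")))
  tab <- rbind(mean = x$means, sd = x$stds)
  print(round(tab, 5))
  if (!is.na(x$n_pixels)) cat(sprintf("  estimated from %d pixels\n", x$n_pixels))
  invisible(x)
}

# validate one rectangle list(x0, y0, x1, y1), 0-based half-open
check_rect <- function(r, height, width) {
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(r))) {
    stop("ROI rectangle needs fields x0, y0, x1, y1", call. = FALSE)
  }
  r <- lapply(r[need], as.integer)
  if (r$x1 <= r$x0 || r$y1 <= r$y0) {
    stop("ROI rectangle is empty (half-open bounds require x1 > x0, y1 > y0)",
         call. = FALSE)
  }
  if (r$x0 < 0 || r$y0 < 0 || r$x1 > width || r$y1 > height) {
    stop(sprintf("ROI rectangle [%d,%d)x[%d,%d) outside %dx%d image",
                 r$x0, r$x1, r$y0, r$y1, width, height), call. = FALSE)
  }
  r
}

# linear indices (into an h x w matrix) covered by a list of rectangles
roi_indices <- function(rects, height, width) {
  if (length(rects) == 0L) stop("ROI has no rectangles", call. = FALSE)
  idx <- unlist(lapply(rects, function(r) {
    r <- check_rect(r, height, width)
    rows <- (r$y0 + 1L):r$y1          # 0-based half-open -> 1-based rows
    cols <- (r$x0 + 1L):r$x1
    as.vector(outer(rows, cols, function(i, j) (j - 1L) * height + i))
  }))
  sort(unique(idx))
}

#' Estimate class statistics from regions of interest
#'
#' Pools all pixels in the union of the given rectangles and computes the
#' per-observable mean and sample standard deviation of the chosen triplet,
#' yielding a [class_model].  Masked (invalid) pixels are excluded.
#'
#' @param stack An [observable_stack].
#' @param rois List of rectangles `list(x0, y0, x1, y1)` in 0-based,
#'   half-open pixel coordinates (origin top-left, `x` across columns).
#' @param name Class label.
#' @param color RGB triplet or preset name (see [class_model]).
#' @param triplet `"ipp"` or `"cp"`.
#' @param sigma_floor Standard-deviation floor.  Default `1e-6`.
#' @return A [class_model].
#' @export
roi_statistics <- function(stack, rois, name, color, triplet = c("ipp", "cp"),
                           sigma_floor = 1e-6) {
  stopifnot(inherits(stack, "observable_stack"))
  triplet <- match.arg(triplet)
  idx <- roi_indices(rois, stack$height, stack$width)
  idx <- idx[as.vector(stack$mask)[idx]]
  if (length(idx) < 2L) {
    stop("ROI must contain at least 2 valid pixels", call. = FALSE)
  }
  chans <- triplet_channels(triplet)
  vals <- vapply(chans, function(nm) as.vector(stack$channels[[nm]])[idx],
                 numeric(length(idx)))
  class_model(
    name = name,
    means = colMeans(vals),
    stds = apply(vals, 2L, sd),      # sample (n-1) standard deviation
    color = color,
    triplet = triplet,
    sigma_floor = sigma_floor,
    n_pixels = length(idx)
  )
}

#' Read a class/ROI definition file
#'
#' Parses the JSON schema
#' `{"triplet": "ipp"|"cp", "classes": [{"name": ..., "color": [r,g,b],
#' "rois": [{"x0":..,"y0":..,"x1":..,"y1":..}, ...]}, ...]}` with 0-based,
#' half-open rectangle coordinates.
#'
#' @param path Path to the JSON file.
#' @return List with `triplet` and `classes` (each class a list with `name`,
#'   `color`, `rois`).
#' @export
read_class_spec <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(spec$triplet) || !spec$triplet %in% c("ipp", "cp")) {
    stop("class file must set \"triplet\" to \"ipp\" or \"cp\"", call. = FALSE)
  }
  if (length(spec$classes) == 0L) {
    stop("class file defines no classes", call. = FALSE)
  }
  for (cl in spec$classes) {
    if (is.null(cl$name) || is.null(cl$color) || length(cl$rois) == 0L) {
      stop("each class needs 'name', 'color' and at least one ROI", call. = FALSE)
    }
  }
  spec
}

#' Build all class models listed in a class/ROI specification
#'
#' @param stack An [observable_stack].
#' @param spec Parsed specification from [read_class_spec] (or an equivalent
#'   list).
#' @param sigma_floor Standard-deviation floor.  Default `1e-6`.
#' @return List of [class_model] objects.
#' @export
build_class_models <- function(stack, spec, sigma_floor = 1e-6) {
  lapply(spec$classes, function(cl) {
    roi_statistics(stack, cl$rois, name = cl$name,
                   color = unlist(cl$color), triplet = spec$triplet,
                   sigma_floor = sigma_floor)
  })
}
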