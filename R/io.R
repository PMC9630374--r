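# Minimal multi-page uncompressed 32-bit-float TIFF writer (little-endian,
# one strip per page, SampleFormat = IEEE float).  The tiff package reads
# this sample format natively but cannot write it, so the writer lives here.
write_float_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1L))))
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")

  n_tags <- 10L
  ifd_size <- 2L + 12L * n_tags + 4L
  # layout: 8-byte header, then per page [pixel data][IFD]
  offsets <- vector("list", length(pages))
  pos <- 8L
  for (i in seq_along(pages)) {
    nbytes <- 4L * length(pages[[i]])
    offsets[[i]] <- list(data = pos, ifd = pos + nbytes)
    pos <- pos + nbytes + ifd_size
  }

  wb(charToRaw("II"), 1L)
  wb(42L, 2L)
  wb(offsets[[1L]]$ifd, 4L)

  tag <- function(id, type, count, value) {
    wb(as.integer(id), 2L)
    wb(as.integer(type), 2L)
    wb(as.integer(count), 4L)
    if (type == 3L) {            # SHORT: value in the low bytes
      wb(as.integer(value), 2L)
      wb(0L, 2L)
    } else {
      wb(as.integer(value), 4L)
    }
  }

  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    h <- nrow(pg); w <- ncol(pg)
    wb(as.numeric(t(pg)), 4L)    # rows in raster order
    wb(n_tags, 2L)
    tag(256L, 4L, 1L, w)                         # ImageWidth
    tag(257L, 4L, 1L, h)                         # ImageLength
    tag(258L, 3L, 1L, 32L)                       # BitsPerSample
    tag(259L, 3L, 1L, 1L)                        # Compression: none
    tag(262L, 3L, 1L, 1L)                        # Photometric: BlackIsZero
    tag(273L, 4L, 1L, offsets[[i]]$data)         # StripOffsets
    tag(277L, 3L, 1L, 1L)                        # SamplesPerPixel
    tag(278L, 4L, 1L, h)                         # RowsPerStrip
    tag(279L, 4L, 1L, 4L * h * w)                # StripByteCounts
    tag(339L, 3L, 1L, 3L)                        # SampleFormat: IEEE float
    wb(if (i < length(pages)) offsets[[i + 1L]]$ifd else 0L, 4L)
  }
  invisible(path)
}

#' Read a Mueller-matrix image file
#'
#' Two formats are supported, selected by extension:
#' * `.tif` / `.tiff` — a multi-page TIFF with exactly 16 float pages in
#'   row-major element order `m00, m01, ..., m33`;
#' * `.rds` — an array archive holding a `(height, width, 4, 4)` numeric
#'   array, either directly or as the element `mueller` of a list.
#'
#' @param path Input file.
#' @return A [mueller_image].
#' @export
read_mueller <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.array(pages) && !is.list(pages)) pages <- list(pages)
    if (length(pages) != 16L) {
      stop(sprintf(
        "expected a 16-page Mueller TIFF (row-major m00..m33), found %d page(s) in %s",
        length(pages), path), call. = FALSE)
    }
    if (!all(vapply(pages, function(p) length(dim(p)) == 2L, logical(1L)))) {
      stop("each Mueller TIFF page must be single-channel (grayscale)", call. = FALSE)
    }
    h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
    el <- array(0, c(h, w, 4L, 4L))
    for (a in 1:4) for (b in 1:4) {
      pg <- pages[[4L * (a - 1L) + b]]
      if (!all(dim(pg) == c(h, w))) {
        stop("Mueller TIFF pages have inconsistent shapes", call. = FALSE)
      }
      el[, , a, b] <- pg
    }
  } else if (ext == "rds") {
    obj <- readRDS(path)
    if (is.list(obj) && !is.null(obj$mueller)) obj <- obj$mueller
    if (!is.array(obj) || length(dim(obj)) != 4L ||
        !all(dim(obj)[3:4] == c(4L, 4L))) {
      stop("array archive must hold a (height, width, 4, 4) array named 'mueller'",
           call. = FALSE)
    }
    el <- obj
  } else {
    stop(sprintf("unsupported Mueller input format '.%s' (use .tif/.tiff or .rds)",
                 ext), call. = FALSE)
  }
  mueller_image(el)
}

#' Write a Mueller-matrix image file
#'
#' Writes the 16-page float TIFF (`.tif`/`.tiff`) or array-archive (`.rds`)
#' format read by [read_mueller], with pages in row-major element order
#' `m00..m33`.
#'
#' @param image A [mueller_image].
#' @param path Output file; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mueller <- function(image, path) {
  stopifnot(inherits(image, "mueller_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- vector("list", 16L)
    for (a in 1:4) for (b in 1:4) {
      pages[[4L * (a - 1L) + b]] <- image$elements[, , a, b]
    }
    write_float_tiff(pages, path)
  } else if (ext == "rds") {
    saveRDS(list(mueller = image$elements), path)
  } else {
    stop(sprintf("unsupported Mueller output format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Write an observable stack as a float TIFF plus channel sidecar
#'
#' Pages are ordered `m00, D, P, P_S, P1, P2, P3, P_Delta`; a JSON sidecar
#' (`<path>.channels.json`) lists the channel names in page order.  Masked
#' pixels are stored as NaN.
#'
#' @param stack An [observable_stack].
#' @param path Output TIFF path.
#' @return Named list of the files written, invisibly.
#' @export
write_observables <- function(stack, path) {
  stopifnot(inherits(stack, "observable_stack"))
  pages <- lapply(observable_names, function(nm) {
    pg <- stack$channels[[nm]]
    pg[is.na(pg)] <- NaN
    pg
  })
  write_float_tiff(pages, path)
  sidecar <- paste0(path, ".channels.json")
  jsonlite::write_json(list(channels = observable_names), sidecar,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(list(tiff = path, channels = sidecar))
}

#' Read an observable stack written by [write_observables]
#'
#' @param path TIFF path (the `.channels.json` sidecar is consulted when
#'   present).
#' @return An [observable_stack].
#' @export
read_observables <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.array(pages) && !is.list(pages)) pages <- list(pages)
  nms <- observable_names
  sidecar <- paste0(path, ".channels.json")
  if (file.exists(sidecar)) {
    nms <- unlist(jsonlite::fromJSON(sidecar)$channels)
  }
  if (length(pages) != length(nms)) {
    stop(sprintf("expected %d observable pages, found %d", length(nms),
                 length(pages)), call. = FALSE)
  }
  channels <- stats::setNames(lapply(pages, function(p) {
    p[is.nan(p)] <- NA_real_
    p
  }), nms)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  mask <- Reduce(`&`, lapply(channels[nms != "m00"], function(p) !is.na(p)))
  structure(
    list(channels = channels, mask = mask,
         flagged = matrix(FALSE, h, w), height = h, width = w),
    class = "observable_stack"
  )
}

#' Write an RGB image (or label map) as an 8-bit PNG
#'
#' Components are quantized as `round(255 * c)`, so a round-trip changes a
#' channel by at most `1/255`.
#'
#' @param rgb `height x width x 3` array in `[0, 1]`, or a `pseudocolor_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  if (inherits(rgb, "pseudocolor_image")) rgb <- rgb$rgb
  png::writePNG(round(255 * rgb) / 255, path)
  invisible(path)
}

#' Write a label map as an 8-bit grayscale PNG
#'
#' Label `i` is stored as gray level `i` (0 = unassigned/black), so up to
#' 255 classes are representable; read back with
#' `round(255 * png::readPNG(path))`.
#'
#' @param labels Integer matrix of class labels (0 = unassigned).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(labels, path) {
  if (max(labels) > 255L) stop("label PNG supports at most 255 classes", call. = FALSE)
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Write run metadata (configuration and class statistics) as JSON
#'
#' Records enough to reproduce a rendering: the method, triplet, options,
#' and each class's name, color, means, standard deviations (sample,
#' `n - 1`) and pixel count.  [class_models_from_metadata] rebuilds the
#' class models from such a file, bypassing ROI statistics.
#'
#' @param classes List of [class_model] objects.
#' @param path Output JSON path.
#' @param config Named list of extra configuration to record.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(classes, path, config = list()) {
  meta <- list(
    software = list(
      package = "muellerpc",
      version = as.character(utils::packageVersion("muellerpc"))
    ),
    config = config,
    std_estimator = "sample (n-1)",
    triplet = classes[[1L]]$triplet,
    classes = lapply(classes, function(cl) {
      list(name = cl$name, color = cl$color,
           means = unname(cl$means), stds = unname(cl$stds),
           sigma_floor = cl$sigma_floor, n_pixels = cl$n_pixels)
    })
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Rebuild class models from a run-metadata JSON file
#'
#' @param path Metadata file written by [write_run_metadata].
#' @return List of [class_model] objects.
#' @export
class_models_from_metadata <- function(path) {
  meta <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  lapply(meta$classes, function(cl) {
    class_model(cl$name, unlist(cl$means), unlist(cl$stds), unlist(cl$color),
                triplet = meta$triplet,
                sigma_floor = cl$sigma_floor %||% 1e-6,
                n_pixels = cl$n_pixels %||% NA_integer_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
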