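# Movie ingestion: convert a multi-page TIFF or a directory of per-frame
# images into an ordered stack of 2D grayscale matrices in [0, 1].

#' Construct a frame stack
#'
#' @param frames list of 2D numeric matrices sharing one shape, values in
#'   `[0, 1]`, ordered in time.
#' @param source optional provenance string (file path or "synthetic").
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, source = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  shp <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!is.matrix(frames[[i]]) || !identical(dim(frames[[i]]), shp)) {
      stopf("frame %d does not match the stack shape (%d x %d)",
            i, shp[1], shp[2])
    }
  }
  structure(list(frames = frames, shape = shp,
                 n_frames = length(frames), source = source),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frames of %d x %d px (source: %s)\n",
              x$n_frames, x$shape[1], x$shape[2],
              if (is.null(x$source)) "<none>" else x$source))
  invisible(x)
}

# ITU-R BT.601 luma conversion for h x w x 3 (or 4) arrays.
.to_gray <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3) {
      return(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
    }
    return(a[, , 1])
  }
  stopf("unsupported image dimensionality: %s",
        paste(dim(a), collapse = " x "))
}

.read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::readTIFF(path, all = FALSE)
    } else if (ext == "png") {
      png::readPNG(path)
    } else {
      stopf("unsupported frame format '%s'", ext)
    }
  }, error = function(e) {
    stopf("failed to read frame '%s': %s", path, conditionMessage(e))
  })
  .to_gray(img)
}

#' Load a movie as a normalized frame stack
#'
#' Accepts a multi-page TIFF or a directory of single-frame PNG/TIFF images
#' whose lexicographic file order is the temporal order.  Color frames are
#' converted to grayscale with ITU-R BT.601 luma weights.  Intensities are
#' rescaled to `[0, 1]` by the global minimum and maximum over the whole
#' stack (per-frame scaling would distort intensity dynamics across the
#' beat).
#'
#' @param path TIFF file or frame directory.
#' @param format_hint optional `"tiff"` or `"dir"`; inferred when `NULL`.
#' @return a [frame_stack()].
#' @export
load_movie <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stopf("path does not exist: %s", path)
  is_dir <- if (is.null(format_hint)) dir.exists(path) else
    identical(format_hint, "dir")
  frames <- if (is_dir) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0) stopf("no frame images found in %s", path)
    lapply(sort(files), .read_frame_file)
  } else {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) {
                        stopf("failed to read TIFF '%s': %s", path,
                              conditionMessage(e))
                      })
    if (is.array(pages) && !is.list(pages)) pages <- list(pages)
    lapply(pages, .to_gray)
  }
  shp <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), shp)) {
      stopf("inconsistent frame shapes: frame %d is %s, expected %s",
            i, paste(dim(frames[[i]]), collapse = "x"),
            paste(shp, collapse = "x"))
    }
  }
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  if (hi > lo) {
    frames <- lapply(frames, function(f) (f - lo) / (hi - lo))
  } else {
    frames <- lapply(frames, function(f) f * 0)
  }
  frame_stack(frames, source = path)
}

#' Write a frame stack as a multi-page float TIFF
#'
#' @param stack a [frame_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  tiff::writeTIFF(stack$frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
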