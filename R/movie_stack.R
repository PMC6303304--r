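#' Time-lapse movie container
#'
#' A `movie_stack` holds an ordered set of 2D grayscale frames together with
#' the acquisition metadata needed downstream: the frame interval in hours,
#' the channel name and the pixel size. Frames are numeric matrices indexed
#' `[row, col]`; intensities are kept as floating point on the 16-bit scale
#' (0..65535) regardless of file bit depth.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param frame_interval frame interval in hours.
#' @param channel `"phase"` or `"fluor"`.
#' @param pixel_size um per pixel.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames, frame_interval, channel = c("phase", "fluor"),
                        pixel_size = 1) {
  channel <- match.arg(channel)
  if (length(frames) == 0L) stop("a movie needs at least one frame")
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
               logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical dimensions")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(list(frames = frames, frame_interval = frame_interval,
                 channel = channel, pixel_size = pixel_size),
            class = "movie_stack")
}

#' @export
length.movie_stack <- function(x) length(x$frames)

#' @export
dim.movie_stack <- function(x) c(dim(x$frames[[1]]), length(x$frames))

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("movie_stack: %d frames of %d x %d px, %s channel, %.3g h/frame\n",
              d[3], d[1], d[2], x$channel, x$frame_interval))
  invisible(x)
}

#' Acquisition time of a frame
#' @param stack a [movie_stack()].
#' @param frame 1-based frame index (vectorized).
#' @return time in hours since the start of imaging (frame 1 is t = 0).
#' @export
frame_time <- function(stack, frame) (frame - 1) * stack$frame_interval

#' Read / write a multi-page 16-bit TIFF movie
#'
#' `write_stack()` stores the frames as a multi-page 16-bit grayscale TIFF
#' (values clamped to 0..65535) plus a JSON sidecar (`<path>.json`) holding
#' the frame interval, channel and pixel size. `read_stack()` restores the
#' stack losslessly for 16-bit input; 8-bit input is promoted to the 16-bit
#' scale with a warning. A missing sidecar falls back to the supplied
#' defaults with a warning.
#'
#' @param stack a [movie_stack()].
#' @param path TIFF file path.
#' @param frame_interval,channel,pixel_size defaults used when the sidecar
#'   is absent.
#' @return `read_stack()` returns a [movie_stack()]; `write_stack()` returns
#'   `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  imgs <- lapply(stack$frames, function(f) clip(round(f), 0, 65535) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L, compression = "none")
  meta <- list(frame_interval = stack$frame_interval, channel = stack$channel,
               pixel_size = stack$pixel_size)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, frame_interval = 1 / 6, channel = "phase",
                       pixel_size = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    storage.mode(p) <- "double"
    p
  })
  mx <- max(vapply(frames, max, numeric(1)), 1)
  is_8bit <- if (!is.null(bits)) bits == 8L else mx <= 255
  if (is_8bit) {
    warning("8-bit TIFF promoted to the internal 16-bit intensity scale")
    frames <- lapply(frames, function(f) f * 257)
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    frame_interval <- meta$frame_interval %||% frame_interval
    channel <- meta$channel %||% channel
    pixel_size <- meta$pixel_size %||% pixel_size
  } else {
    warning("no sidecar metadata found for ", path, "; using defaults")
  }
  movie_stack(frames, frame_interval, channel, pixel_size)
}

#' Read / write a labeled trench-mask image
#'
#' The mask is stored as a 16-bit TIFF whose pixel values are the integer
#' trench labels (0 = background).
#'
#' @param mask integer matrix of labels.
#' @param path file path.
#' @return `read_mask()` returns the integer label matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(clip(mask, 0, 65535) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  p <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  m <- round(p * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Read / write a CSV table
#'
#' Thin wrappers with a lossless numeric round-trip (15 significant digits)
#' and ragged-row detection on read.
#'
#' @param df data frame.
#' @param path file path.
#' @return `read_table_csv()` returns a data frame.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  n_fields <- utils::count.fields(path, sep = ",")
  if (length(unique(n_fields)) > 1L) stop("ragged CSV: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
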