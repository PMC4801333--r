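#' Construct a canalogram stack
#'
#' A canalogram stack holds the raw fluorescein time-lapse as a
#' time x row x col intensity array together with its acquisition cadence.
#' Frame times are synthesized as `t0_s + (i - 1) * frame_interval_s` for
#' frame `i`; timestamps embedded in image files are ignored because the
#' acquisition cadence is fixed.
#'
#' @param frames numeric array, time x row x col, non-negative intensities.
#' @param frame_interval_s seconds between consecutive frames (default 30).
#' @param t0_s acquisition start time in seconds (default 0).
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param source optional path string recording where the frames came from.
#' @param bit_depth 8 or 16; intensity count depth.
#' @return An object of class `canalogram_stack`.
#' @export
canalogram_stack <- function(frames, frame_interval_s = 30, t0_s = 0,
                             laterality = c("OD", "OS"), source = NA_character_,
                             bit_depth = 16) {
  laterality <- match.arg(laterality)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a 3-D array (time x row x col)")
  if (dim(frames)[1] < 2L)
    stop("a canalogram stack needs at least 2 frames")
  if (any(!is.finite(frames)))
    stop("non-finite intensities in stack")
  if (any(frames < 0))
    stop("negative intensities in stack")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0)
    stop("'frame_interval_s' must be a single positive number")
  if (!bit_depth %in% c(8L, 16L))
    stop("'bit_depth' must be 8 or 16")
  structure(
    list(frames = frames,
         frame_interval_s = as.numeric(frame_interval_s),
         t0_s = as.numeric(t0_s),
         laterality = laterality,
         source = source,
         bit_depth = as.integer(bit_depth)),
    class = "canalogram_stack")
}

#' Number of frames and frame times of a stack
#'
#' @param stack a `canalogram_stack`.
#' @return `n_frames()` the frame count; `frame_times()` the vector of frame
#'   times in seconds.
#' @export
n_frames <- function(stack) dim(stack$frames)[1]

#' @rdname n_frames
#' @export
frame_times <- function(stack) {
  stack$t0_s + (seq_len(n_frames(stack)) - 1L) * stack$frame_interval_s
}

#' @export
print.canalogram_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("Canalogram stack:", d[1], "frames of", d[2], "x", d[3], "px\n")
  cat(sprintf("  interval %g s, duration %g s (%.1f min), laterality %s\n",
              x$frame_interval_s, (d[1] - 1) * x$frame_interval_s,
              (d[1] - 1) * x$frame_interval_s / 60, x$laterality))
  if (!is.na(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

# read one grayscale frame from a TIFF or PNG file; RGB is averaged over
# channels (monochrome camera assumption; channel average is a safe degrade)
read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
                png = png::readPNG(path),
                stop("unsupported image format: ", path))
  collapse_channels(img)
}

collapse_channels <- function(img) {
  if (length(dim(img)) == 3L) {
    # drop alpha if present, average remaining channels
    nc <- dim(img)[3]
    if (nc == 4L) img <- img[, , 1:3, drop = FALSE]
    img <- apply(img, c(1, 2), mean)
  }
  img
}

#' Load a canalogram time-lapse stack
#'
#' Reads either a multi-page grayscale TIFF or a directory (or glob) of
#' same-shaped single-frame TIFF/PNG images taken in lexicographic filename
#' order. Frame order is page/filename order; no reordering heuristics are
#' applied. RGB frames are converted to grayscale by averaging channels.
#'
#' @param path multi-page TIFF file, a directory of frames, or a glob pattern.
#' @param frame_interval_s seconds between frames. If omitted the default of
#'   30 s is used with a warning.
#' @param laterality `"OD"` or `"OS"`.
#' @param t0_s start time in seconds.
#' @return A [canalogram_stack()].
#' @export
load_stack <- function(path, frame_interval_s = NULL,
                       laterality = c("OD", "OS"), t0_s = 0) {
  laterality <- match.arg(laterality)
  if (is.null(frame_interval_s)) {
    warning("frame_interval_s not given; assuming 30 s cadence")
    frame_interval_s <- 30
  }
  if (length(path) == 1L && dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
  } else if (length(path) == 1L && file.exists(path)) {
    files <- path
  } else {
    files <- sort(Sys.glob(path))
  }
  if (length(files) == 0L) stop("no readable frames at: ", paste(path, collapse = ", "))

  frames_list <- list()
  for (f in files) {
    ext <- tolower(tools::file_ext(f))
    if (ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      frames_list <- c(frames_list, lapply(pages, collapse_channels))
    } else {
      frames_list <- c(frames_list, list(read_frame_file(f)))
    }
  }
  if (length(frames_list) < 2L) stop("fewer than 2 frames in stack")
  shapes <- vapply(frames_list, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent frame geometry: found shapes ",
         paste(unique(shapes), collapse = ", "))

  d <- dim(frames_list[[1]])
  arr <- array(0, dim = c(length(frames_list), d[1], d[2]))
  for (i in seq_along(frames_list)) arr[i, , ] <- frames_list[[i]]
  # readPNG returns [0,1]; readTIFF(as.is) returns integer counts
  mx <- max(arr)
  bit_depth <- if (mx > 255) 16L else 8L
  canalogram_stack(arr, frame_interval_s = frame_interval_s, t0_s = t0_s,
                   laterality = laterality,
                   source = if (length(files) == 1L) files else dirname(files[1]),
                   bit_depth = bit_depth)
}

#' Write a canalogram stack as a multi-page TIFF
#'
#' Intensities are stored as 8- or 16-bit grayscale according to the stack's
#' bit depth; values are clipped to the representable range.
#'
#' @param stack a `canalogram_stack`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  maxval <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    m <- stack$frames[i, , ]
    pmin(pmax(round(m), 0), maxval) / maxval
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  invisible(path)
}
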