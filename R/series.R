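#' Time-lapse image series with physical calibration
#'
#' Container for a FRAP stack.  Frames are stored as a numeric array of
#' dimension `(ny, nx, nt)` (y down, x right, time last); `bleach_frame` is
#' the 1-based index of the first post-bleach frame, so the conventional
#' 6-pre-bleach acquisition has `bleach_frame = 7`.  File sidecars use the
#' equivalent 0-based `bleach_frame_index`.
#'
#' @param frames numeric array (ny, nx, nt), intensities >= 0.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @param bleach_frame 1-based index of the first post-bleach frame.
#' @param metadata free-form provenance list.
#' @return object of class `frap_series`.
#' @export
frap_series <- function(frames, pixel_size, frame_interval, bleach_frame,
                        metadata = list()) {
  stopifnot(length(dim(frames)) == 3, pixel_size > 0, frame_interval > 0)
  nt <- dim(frames)[3]
  if (bleach_frame < 2 || bleach_frame > nt)
    stop("bleach_frame must lie in [2, nt]", call. = FALSE)
  if (min(frames) < 0)
    stop("intensities must be >= 0", call. = FALSE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 bleach_frame = as.integer(bleach_frame),
                 metadata = metadata),
            class = "frap_series")
}

#' @export
print.frap_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "FRAP series: %d frames of %dx%d px, %.4f um/px, dt = %.4f s, bleach at frame %d\n",
    d[3], d[1], d[2], x$pixel_size, x$frame_interval, x$bleach_frame))
  invisible(x)
}

#' Frame times
#'
#' Frame acquisition times in seconds, with t = 0 at the first post-bleach
#' frame (pre-bleach frames carry negative times).
#'
#' @param series a `frap_series`.
#' @return numeric vector of length nt.
#' @export
frame_times <- function(series) {
  nt <- dim(series$frames)[3]
  (seq_len(nt) - series$bleach_frame) * series$frame_interval
}
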