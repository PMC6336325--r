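#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule holds the start and end time (seconds post injection) of
#' every frame of a dynamic acquisition. Frames must be sorted, non-empty and
#' non-overlapping; durations and mid-times are derived, never stored.
#'
#' @param start_s numeric vector of frame start times in seconds.
#' @param end_s numeric vector of frame end times in seconds.
#' @return An object of class `frame_schedule`.
#' @examples
#' sched <- frame_schedule(c(0, 10, 20), c(10, 20, 50))
#' frame_mid_s(sched)
#' @export
frame_schedule <- function(start_s, end_s) {
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  if (length(start_s) != length(end_s) || length(start_s) < 1L)
    stop("start_s and end_s must be non-empty vectors of equal length")
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)))
    stop("frame times must be finite")
  if (any(end_s <= start_s))
    stop("every frame must satisfy end_s > start_s")
  n <- length(start_s)
  if (n > 1L) {
    if (is.unsorted(start_s, strictly = TRUE))
      stop("frames must be sorted by start time")
    if (any(start_s[-1L] < end_s[-n] - 1e-9))
      stop("frames must not overlap")
  }
  structure(list(start_s = start_s, end_s = end_s), class = "frame_schedule")
}

#' @rdname frame_schedule
#' @param x a `frame_schedule`.
#' @export
frame_duration_s <- function(x) x$end_s - x$start_s

#' @rdname frame_schedule
#' @export
frame_mid_s <- function(x) (x$start_s + x$end_s) / 2

#' @rdname frame_schedule
#' @export
n_frames <- function(x) length(x$start_s)

#' Default 60-minute dynamic PIB frame schedule
#'
#' The 23-frame schedule used throughout the package: 7 x 10 s, 3 x 30 s,
#' 2 x 60 s, 2 x 120 s, 2 x 180 s, 5 x 300 s and 2 x 600 s, covering
#' 0--3580 s from tracer injection.
#'
#' @return A `frame_schedule` with 23 frames.
#' @export
pib_frame_schedule <- function() {
  dur <- c(rep(10, 7), rep(30, 3), rep(60, 2), rep(120, 2),
           rep(180, 2), rep(300, 5), rep(600, 2))
  end <- cumsum(dur)
  frame_schedule(end - dur, end)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.0f-%.0f s\n",
              n_frames(x), x$start_s[1L], x$end_s[n_frames(x)]))
  invisible(x)
}

#' Read / write a frame-timing JSON sidecar
#'
#' The sidecar follows the BIDS-PET dialect: a JSON object with
#' `FrameTimesStart` and `FrameDuration` arrays, both in seconds.
#'
#' @param schedule a `frame_schedule`.
#' @param path path to the JSON file.
#' @return `read_frame_sidecar` returns a `frame_schedule`;
#'   `write_frame_sidecar` returns `path` invisibly.
#' @export
write_frame_sidecar <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  jsonlite::write_json(
    list(FrameTimesStart = schedule$start_s,
         FrameDuration = frame_duration_s(schedule)),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_frame_sidecar
#' @export
read_frame_sidecar <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$FrameTimesStart) || is.null(j$FrameDuration))
    stop("sidecar must contain FrameTimesStart and FrameDuration")
  frame_schedule(j$FrameTimesStart, j$FrameTimesStart + j$FrameDuration)
}
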