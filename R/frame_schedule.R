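#' PET frame schedule
#'
#' The acquisition framing: contiguous, non-overlapping frames starting at
#' t = 0. The default is the 33-frame dynamic protocol
#' 18 x 10 s, 2 x 30 s, 1 x 60 s, 2 x 120 s, 10 x 300 s (3540 s total),
#' with a 3-min "short scale" (the first 18 frames) and the full 60-min
#' "long scale".
#'
#' @param durations_s frame durations in seconds, in order.
#' @param short_cutoff_min end of the short-scale window, min.
#' @return a `frame_schedule`: data frame with columns `start_s`,
#'   `duration_s`, `start_min`, `duration_min`, `mid_min`.
#' @examples
#' sch <- frame_schedule()
#' nrow(sch)                         # 33
#' sum(sch$duration_s)               # 3540
#' nrow(schedule_frames(sch, "short"))  # 18
#' @export
frame_schedule <- function(durations_s = c(rep(10, 18), rep(30, 2), 60,
                                           rep(120, 2), rep(300, 10)),
                           short_cutoff_min = 3) {
  durations_s <- as.numeric(durations_s)
  if (length(durations_s) < 1L || any(durations_s <= 0))
    stop("frame durations must be positive")
  start_s <- cumsum(c(0, durations_s[-length(durations_s)]))
  out <- data.frame(
    start_s = start_s,
    duration_s = durations_s,
    start_min = start_s / 60,
    duration_min = durations_s / 60
  )
  out$mid_min <- out$start_min + out$duration_min / 2
  attr(out, "short_cutoff_min") <- short_cutoff_min
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Select the frames of a time scale
#'
#' @param schedule a [frame_schedule].
#' @param scale `"short"` (frames ending at or before the short-scale
#'   cutoff, default 3 min) or `"long"` (all frames).
#' @return the subset of schedule rows for that scale.
#' @export
schedule_frames <- function(schedule, scale = c("long", "short")) {
  scale <- match.arg(scale)
  stopifnot(inherits(schedule, "frame_schedule"))
  if (scale == "long") return(schedule)
  cutoff <- attr(schedule, "short_cutoff_min")
  schedule[schedule$start_min + schedule$duration_min <= cutoff + 1e-9, ,
           drop = FALSE]
}
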