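#' Construct a gaze trace
#'
#' One recording of one subject at one occasion for one pursuit task:
#' horizontal eye position over time plus a validity mask (FALSE during
#' blinks / track loss). Times must be strictly increasing at a nominally
#' constant sampling interval.
#'
#' @param times_ms Sample times in ms, strictly increasing.
#' @param x Horizontal gaze position in degrees (rightward positive).
#' @param valid Logical validity mask, same length as `x` (default all TRUE).
#' @param subject,occasion,task Optional identifiers carried along.
#' @return An object of class `gaze_trace`.
#' @export
gaze_trace <- function(times_ms, x, valid = rep(TRUE, length(x)),
                       subject = NA, occasion = NA_integer_,
                       task = NA_character_) {
  n <- length(times_ms)
  stopifnot(length(x) == n, length(valid) == n)
  if (n > 1) {
    dt <- diff(times_ms)
    if (any(dt <= 0)) stop("`times_ms` must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-9) {
      stop("`times_ms` must have a constant sampling interval", call. = FALSE)
    }
  }
  if (any(!is.finite(x[valid]))) {
    stop("gaze position must be finite where `valid` is TRUE", call. = FALSE)
  }
  structure(list(times_ms = as.numeric(times_ms), x = as.numeric(x),
                 valid = as.logical(valid), subject = subject,
                 occasion = occasion, task = task),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> subject %s, occasion %s, task %s: %d samples, %.1f s, %.1f%% valid\n",
              format(x$subject), format(x$occasion), format(x$task),
              length(x$x), diff(range(x$times_ms)) / 1000,
              100 * mean(x$valid)))
  invisible(x)
}

#' Read / write gaze sample files
#'
#' Gaze CSV files have columns `time_ms`, `x_deg`, `valid` (0/1); noise mask
#' files have columns `start_ms`, `end_ms` (closed-open intervals).
#'
#' @param trace A [gaze_trace].
#' @param path File path.
#' @return `read_gaze_csv` returns a [gaze_trace]; `read_mask_csv` returns a
#'   data frame of intervals (zero rows if the file does not exist).
#' @export
write_gaze_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_ms = trace$times_ms, x_deg = trace$x,
               valid = as.integer(trace$valid)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @param subject,occasion,task Identifiers attached to the trace on read.
#' @export
read_gaze_csv <- function(path, subject = NA, occasion = NA_integer_,
                          task = NA_character_) {
  d <- utils::read.csv(path)
  gaze_trace(d$time_ms, d$x_deg, d$valid != 0,
             subject = subject, occasion = occasion, task = task)
}

#' @rdname write_gaze_csv
#' @param intervals Data frame with `start_ms`, `end_ms`.
#' @export
write_mask_csv <- function(intervals, path) {
  utils::write.csv(intervals[, c("start_ms", "end_ms")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_mask_csv <- function(path) {
  if (!file.exists(path)) {
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  }
  utils::read.csv(path)
}

# logical mask of samples falling inside any closed-open [start, end) interval
mask_from_intervals <- function(times_ms, intervals) {
  m <- rep(FALSE, length(times_ms))
  if (is.null(intervals) || nrow(intervals) == 0) return(m)
  for (j in seq_len(nrow(intervals))) {
    m <- m | (times_ms >= intervals$start_ms[j] & times_ms < intervals$end_ms[j])
  }
  m
}
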