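#' Force trace
#'
#' Timestamped samples of the force applied by a tracked instrument, in
#' Newtons.
#'
#' @param time_s Numeric vector of sample times, strictly increasing.
#' @param force_N Non-negative forces, one per sample.
#' @return `data.frame` of class `"force_trace"` with columns `time_s`,
#'   `force_N`.
#' @export
force_trace <- function(time_s, force_N) {
  if (length(time_s) != length(force_N))
    abort_rt("`time_s` and `force_N` must have equal length",
             "invalid_argument")
  if (length(time_s) && any(diff(time_s) <= 0))
    abort_rt("force-trace timestamps must be strictly increasing",
             "invalid_argument")
  if (any(force_N < 0) || any(!is.finite(force_N)))
    abort_rt("forces must be finite and non-negative", "invalid_argument")
  structure(data.frame(time_s = as.numeric(time_s),
                       force_N = as.numeric(force_N)),
            class = c("force_trace", "data.frame"))
}

#' Read / write a force-trace CSV (`time_s,force_N`)
#' @param path File path.
#' @return `read_force_trace` returns a [force_trace];
#'   `write_force_trace` returns `path` invisibly.
#' @export
read_force_trace <- function(path) {
  if (!file.exists(path))
    abort_rt(sprintf("force trace not found: %s", path), "io_error")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time_s", "force_N") %in% names(df)))
    abort_rt("force-trace CSV must have columns time_s,force_N",
             "parse_error")
  force_trace(df$time_s, df$force_N)
}

#' @rdname read_force_trace
#' @param trace A [force_trace].
#' @export
write_force_trace <- function(trace, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("time_s,force_N",
               sprintf("%s,%s", fmt6(trace$time_s), fmt6(trace$force_N))),
             con = con, sep = "\n")
  invisible(path)
}

#' Critical-force warning monitor
#'
#' Emits one warning event per contiguous excursion of the applied force
#' above the critical threshold, stamped at the first exceeding sample.
#' Exceeding the critical load during the rasping phase risks injuring the
#' vertebral endplate and spinal cord, so the simulator warns the trainee;
#' the default threshold of 20 N is the critical rasping force determined by
#' finite-element analysis. The comparison is strictly greater-than: a
#' sample exactly at the threshold does not warn.
#'
#' @param trace A [force_trace] (or data.frame with `time_s`, `force_N`).
#' @param threshold Critical force in Newtons, default 20.
#' @return `data.frame` of warning events with columns `timestamp`,
#'   `force`, `threshold`, `message` (0 rows when the force never exceeds
#'   the threshold).
#' @examples
#' tr <- force_trace(0:40 / 10, 0:40)   # 0 -> 40 N ramp
#' monitor_force(tr)                    # first warning at 21 N
#' @export
monitor_force <- function(trace, threshold = 20) {
  if (!is.data.frame(trace) ||
      !all(c("time_s", "force_N") %in% names(trace)))
    abort_rt("`trace` must have columns time_s and force_N",
             "invalid_argument")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    abort_rt("`threshold` must be a positive force in Newtons",
             "invalid_argument")
  empty <- data.frame(timestamp = numeric(0), force = numeric(0),
                      threshold = numeric(0), message = character(0))
  if (nrow(trace) == 0L) return(empty)
  over <- trace$force_N > threshold
  # event = up-crossing: first sample of each contiguous run above threshold
  starts <- which(over & !c(FALSE, over[-length(over)]))
  if (!length(starts)) return(empty)
  data.frame(
    timestamp = trace$time_s[starts],
    force = trace$force_N[starts],
    threshold = threshold,
    message = sprintf(
      "WARNING: applied force %.2f N exceeds the critical force %.2f N",
      trace$force_N[starts], threshold),
    stringsAsFactors = FALSE)
}
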