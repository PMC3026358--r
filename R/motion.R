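#' Motion stream
#'
#' Per-frame object poses from a capture session, replayed offline. Each row
#' holds one object's pose in one frame: translation in millimetres and
#' rotation as an exponential-map vector, plus the names of the markers the
#' cameras saw. A frame in which an object was occluded keeps its row with
#' `NA` pose fields.
#'
#' @param frames `data.frame` with columns `frame`, `time_s`, `object`,
#'   `tx_mm`, `ty_mm`, `tz_mm`, `rx`, `ry`, `rz`, `visible_markers`
#'   (semicolon-joined marker names, `""` when none).
#' @param rate Nominal capture rate in Hz (metadata; capture systems of this
#'   class typically run at 200 Hz).
#' @return Object of class `"motion_stream"`.
#' @export
motion_stream <- function(frames, rate = 200) {
  need <- c("frame", "time_s", "object", "tx_mm", "ty_mm", "tz_mm",
            "rx", "ry", "rz", "visible_markers")
  if (!is.data.frame(frames) || !all(need %in% names(frames)))
    abort_rt(paste("`frames` must be a data.frame with columns",
                   paste(need, collapse = ", ")), "invalid_argument")
  if (nrow(frames) == 0L)
    abort_rt("motion stream must contain at least one frame",
             "invalid_argument")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate <= 0)
    abort_rt("nominal rate must be a positive number", "invalid_argument")
  frames <- frames[order(frames$object, frames$frame), need, drop = FALSE]
  rownames(frames) <- NULL
  for (ob in unique(frames$object)) {
    ts <- frames$time_s[frames$object == ob]
    if (any(diff(ts) <= 0))
      abort_rt(sprintf(
        "timestamps must be strictly increasing (object '%s')", ob),
        "invalid_argument")
  }
  structure(list(frames = frames, rate = rate), class = "motion_stream")
}

#' @export
print.motion_stream <- function(x, ...) {
  obs <- unique(x$frames$object)
  cat(sprintf(
    "<motion_stream> %d frames x %d object(s) [%s] at %g Hz (%d occluded rows)\n",
    length(unique(x$frames$frame)), length(obs),
    paste(obs, collapse = ", "), x$rate, sum(is.na(x$frames$tx_mm))))
  invisible(x)
}

pose_cols <- c("tx_mm", "ty_mm", "tz_mm", "rx", "ry", "rz")

#' Read / write the capture CSV dialect
#'
#' Header `frame,time_s,object,tx_mm,ty_mm,tz_mm,rx,ry,rz,visible_markers`,
#' preceded by the version comment `# rigidtrack-capture v1` which also
#' records the nominal rate (`rate_hz=<hz>`). Rotations are exponential-map
#' vectors in radians; a missing (occluded) pose is encoded as empty fields.
#'
#' @param path File path.
#' @return `read_capture_csv` returns a [motion_stream];
#'   `write_capture_csv` returns `path` invisibly.
#' @export
read_capture_csv <- function(path) {
  if (!file.exists(path))
    abort_rt(sprintf("capture file not found: %s", path), "io_error")
  first <- readLines(path, n = 1L)
  rate <- 200
  if (grepl("^# rigidtrack-capture", first)) {
    m <- regmatches(first, regexpr("rate_hz=[0-9.]+", first))
    if (length(m)) rate <- as.numeric(sub("rate_hz=", "", m))
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(visible_markers = "character"))
  need <- c("frame", "time_s", "object", pose_cols, "visible_markers")
  if (!all(need %in% names(df)))
    abort_rt(sprintf("capture CSV is missing columns: %s",
                     paste(setdiff(need, names(df)), collapse = ", ")),
             "parse_error")
  df$visible_markers[is.na(df$visible_markers)] <- ""
  motion_stream(df, rate = rate)
}

#' @rdname read_capture_csv
#' @param stream A [motion_stream].
#' @export
write_capture_csv <- function(stream, path) {
  stopifnot(inherits(stream, "motion_stream"))
  f <- stream$frames
  num <- function(x) ifelse(is.na(x), "", fmt6(x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rigidtrack-capture v1 rate_hz=%g units=mm rotation=expmap_rad",
            stream$rate),
    "frame,time_s,object,tx_mm,ty_mm,tz_mm,rx,ry,rz,visible_markers",
    sprintf("%d,%s,%s,%s,%s,%s,%s,%s,%s,%s",
            f$frame, fmt6(f$time_s), f$object,
            num(f$tx_mm), num(f$ty_mm), num(f$tz_mm),
            num(f$rx), num(f$ry), num(f$rz), f$visible_markers)
  ), con = con, sep = "\n")
  invisible(path)
}

#' Convert captured poses to scene poses
#'
#' The per-frame conversion feeding the renderer: translations delivered in
#' millimetres are rescaled (default factor 0.1, mm to cm) and
#' exponential-map rotations are converted to unit quaternions.
#'
#' `convert_frame` converts one frame and returns a named list of scene
#' poses; `convert_stream` converts every row and returns the stream's
#' frames with scene-pose columns `sx_cm, sy_cm, sz_cm, qw, qx, qy, qz`
#' appended.
#'
#' @param stream A [motion_stream].
#' @param frame Frame index to convert.
#' @param scale Translation scale factor, default `0.1` (mm to cm).
#' @return For `convert_frame`, a named list (one entry per object) of
#'   `list(translation =, rotation =)` scene poses (`NULL` for occluded
#'   objects); for `convert_stream`, a `data.frame`.
#' @export
convert_frame <- function(stream, frame, scale = 0.1) {
  stopifnot(inherits(stream, "motion_stream"))
  rows <- stream$frames[stream$frames$frame == frame, , drop = FALSE]
  if (nrow(rows) == 0L)
    abort_rt(sprintf("frame %s not present in stream", frame),
             "invalid_argument")
  out <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    out[[r$object]] <- if (is.na(r$tx_mm)) NULL else list(
      translation = c(r$tx_mm, r$ty_mm, r$tz_mm) * scale,
      rotation = expmap_to_quaternion(c(r$rx, r$ry, r$rz))
    )
  }
  out
}

#' @rdname convert_frame
#' @export
convert_stream <- function(stream, scale = 0.1) {
  stopifnot(inherits(stream, "motion_stream"))
  f <- stream$frames
  qm <- expmap_to_quat_rows(as.matrix(f[, c("rx", "ry", "rz")]))
  cbind(f,
        data.frame(sx_cm = f$tx_mm * scale, sy_cm = f$ty_mm * scale,
                   sz_cm = f$tz_mm * scale,
                   qw = qm[, 1], qx = qm[, 2], qy = qm[, 3], qz = qm[, 4]))
}

#' Low-pass filter a motion stream
#'
#' Single-pole exponential smoother suppressing the residual camera-rig
#' vibration that leaks into captured poses:
#' `y[t] = alpha * x[t] + (1 - alpha) * y[t-1]`, applied componentwise to
#' translations. Rotations are smoothed consistently on the rotation group
#' by spherical interpolation from the previous filtered orientation toward
#' the current measurement with fraction `alpha` (componentwise filtering of
#' exponential maps is not rotation-consistent). The filter has DC gain
#' exactly 1 and `alpha = 1` is the identity; smaller `alpha` smooths more
#' at the price of latency. Occluded (`NA`) rows are passed through
#' unchanged and do not advance the filter state.
#'
#' @param stream A [motion_stream].
#' @param alpha Smoothing factor in `(0, 1]`.
#' @return A filtered [motion_stream] with identical frames, timestamps and
#'   rate.
#' @export
lowpass <- function(stream, alpha) {
  stopifnot(inherits(stream, "motion_stream"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1)
    abort_rt("`alpha` must be a single value in (0, 1]", "invalid_argument")
  f <- stream$frames
  for (ob in unique(f$object)) {
    idx <- which(f$object == ob)
    tprev <- NULL; qprev <- NULL
    for (i in idx) {
      if (is.na(f$tx_mm[i])) next
      tcur <- c(f$tx_mm[i], f$ty_mm[i], f$tz_mm[i])
      qcur <- expmap_to_quaternion(c(f$rx[i], f$ry[i], f$rz[i]))
      if (is.null(tprev)) {
        tf <- tcur; qf <- qcur
      } else {
        tf <- alpha * tcur + (1 - alpha) * tprev
        qf <- quat_slerp(qprev, qcur, alpha)
      }
      f$tx_mm[i] <- tf[1]; f$ty_mm[i] <- tf[2]; f$tz_mm[i] <- tf[3]
      r <- quaternion_to_expmap(qf)
      f$rx[i] <- r[1]; f$ry[i] <- r[2]; f$rz[i] <- r[3]
      tprev <- tf; qprev <- qf
    }
  }
  motion_stream(f, rate = stream$rate)
}

#' Theoretical magnitude response of the one-pole smoother
#'
#' `|H(omega)| = alpha / sqrt(1 + (1 - alpha)^2 - 2 (1 - alpha) cos omega)`
#' for the filter `y[t] = alpha x[t] + (1 - alpha) y[t-1]`. At DC
#' (`omega = 0`) the gain is exactly 1; at Nyquist (`omega = pi`) it is
#' `alpha / (2 - alpha)`.
#'
#' @param alpha Smoothing factor in `(0, 1]`.
#' @param omega Normalized angular frequency in radians/sample.
#' @return Gain magnitude (vectorized over `omega`).
#' @export
lowpass_gain <- function(alpha, omega) {
  alpha / sqrt(1 + (1 - alpha)^2 - 2 * (1 - alpha) * cos(omega))
}

#' Fill short occlusion gaps by interpolation
#'
#' Marker occlusion drops an object's pose for a run of frames, which shows
#' up as flicker when replayed. Interior gaps of at most `max_gap` frames
#' are reconstructed by linear interpolation of the translation and
#' spherical-linear interpolation of the rotation between the flanking
#' observed poses. Longer gaps, and gaps touching the stream boundary (no
#' extrapolation), are left unchanged and reported. Originally present
#' frames are never altered, so the operation is idempotent.
#'
#' @param stream A [motion_stream].
#' @param max_gap Longest gap (frames) to fill; `0` fills nothing.
#' @return List with `stream` (gaps filled) and `unresolved_gaps`
#'   (`data.frame` with `object`, `start_frame`, `end_frame`, `length`,
#'   `reason`).
#' @export
fill_occlusions <- function(stream, max_gap) {
  stopifnot(inherits(stream, "motion_stream"))
  if (!is.numeric(max_gap) || length(max_gap) != 1L || max_gap < 0)
    abort_rt("`max_gap` must be a non-negative frame count",
             "invalid_argument")
  f <- stream$frames
  unresolved <- list()
  for (ob in unique(f$object)) {
    idx <- which(f$object == ob)
    miss <- is.na(f$tx_mm[idx])
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      s <- starts[g]; e <- ends[g]; len <- e - s + 1L
      at_boundary <- s == 1L || e == length(idx)
      if (at_boundary || len > max_gap) {
        unresolved[[length(unresolved) + 1L]] <- data.frame(
          object = ob,
          start_frame = f$frame[idx[s]], end_frame = f$frame[idx[e]],
          length = len,
          reason = if (at_boundary) "stream boundary" else "gap too long")
        next
      }
      i0 <- idx[s - 1L]; i1 <- idx[e + 1L]
      t0 <- c(f$tx_mm[i0], f$ty_mm[i0], f$tz_mm[i0])
      t1 <- c(f$tx_mm[i1], f$ty_mm[i1], f$tz_mm[i1])
      q0 <- expmap_to_quaternion(c(f$rx[i0], f$ry[i0], f$rz[i0]))
      q1 <- expmap_to_quaternion(c(f$rx[i1], f$ry[i1], f$rz[i1]))
      for (k in seq_len(len)) {
        w <- k / (len + 1)
        i <- idx[s + k - 1L]
        tt <- (1 - w) * t0 + w * t1
        rr <- quaternion_to_expmap(quat_slerp(q0, q1, w))
        f$tx_mm[i] <- tt[1]; f$ty_mm[i] <- tt[2]; f$tz_mm[i] <- tt[3]
        f$rx[i] <- rr[1]; f$ry[i] <- rr[2]; f$rz[i] <- rr[3]
      }
    }
  }
  gaps <- if (length(unresolved)) do.call(rbind, unresolved) else
    data.frame(object = character(0), start_frame = integer(0),
               end_frame = integer(0), length = integer(0),
               reason = character(0))
  list(stream = motion_stream(f, rate = stream$rate),
       unresolved_gaps = gaps)
}

#' Detect sudden orientation flips
#'
#' Marker occlusion can reconstruct a rigid body upside down for a frame or
#' two; such frames show a near-180-degree jump in orientation. A frame is
#' flagged when the geodesic rotation distance to the previous observed
#' frame of the same object exceeds `angle_threshold`.
#'
#' @param stream A [motion_stream].
#' @param angle_threshold Threshold in radians, in `(0, pi]`; default
#'   `pi / 2`.
#' @return `data.frame` with columns `object`, `frame`, `angle` (radians).
#' @export
detect_orientation_flips <- function(stream, angle_threshold = pi / 2) {
  stopifnot(inherits(stream, "motion_stream"))
  if (!is.numeric(angle_threshold) || length(angle_threshold) != 1L ||
      angle_threshold <= 0 || angle_threshold > pi)
    abort_rt("`angle_threshold` must be in (0, pi]", "invalid_argument")
  f <- stream$frames
  hits <- list()
  for (ob in unique(f$object)) {
    idx <- which(f$object == ob & !is.na(f$tx_mm))
    if (length(idx) < 2L) next
    qprev <- expmap_to_quaternion(
      c(f$rx[idx[1]], f$ry[idx[1]], f$rz[idx[1]]))
    for (i in idx[-1L]) {
      q <- expmap_to_quaternion(c(f$rx[i], f$ry[i], f$rz[i]))
      ang <- quat_angle(qprev, q)
      if (ang > angle_threshold)
        hits[[length(hits) + 1L]] <- data.frame(
          object = ob, frame = f$frame[i], angle = ang)
      qprev <- q
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(object = character(0), frame = integer(0),
               angle = numeric(0))
}
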