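# offline replay of the acquisition -> conversion -> rendering-input chain,
# plus the force monitor, as one configurable run

#' Read captured marker positions (`marker,x,y,z` CSV)
#'
#' One row per marker: the capture-frame position (mm) of each named
#' physical marker, as exported from a sample recording.
#'
#' @param path File path.
#' @param radius Marker radius for the resulting set.
#' @return A [marker_set] in capture coordinates.
#' @export
read_captured_markers <- function(path, radius = 0.5) {
  if (!file.exists(path))
    abort_rt(sprintf("captured-marker file not found: %s", path), "io_error")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("marker", "x", "y", "z") %in% names(df)))
    abort_rt("captured-marker CSV must have columns marker,x,y,z",
             "parse_error")
  marker_set(as.matrix(df[, c("x", "y", "z")]), names = df$marker,
             radius = radius)
}

#' Pipeline run configuration
#'
#' Validates a configuration for [run_pipeline]. `capture` and `out_dir`
#' are required; `vsk`, `mesh`, `markers` + `correspondence` (enabling the
#' registration stage) and `force_trace` are optional. All referenced input
#' files must exist at validation time.
#'
#' @param capture Path to a capture CSV (see [read_capture_csv]).
#' @param out_dir Output directory (created if missing).
#' @param vsk Optional tracking-model file ([read_vsk]).
#' @param mesh Optional surface-mesh file ([read_mesh]).
#' @param markers Optional captured-marker CSV ([read_captured_markers]).
#' @param correspondence Optional correspondence CSV
#'   ([read_correspondence]); with `markers` it triggers registration.
#' @param force_trace Optional force-trace CSV ([read_force_trace]).
#' @param scale Translation scale factor (default 0.1, mm to cm).
#' @param alpha Low-pass smoothing factor in `(0, 1]` (default 0.2).
#' @param max_gap Longest occlusion gap to fill, frames (default 3).
#' @param force_threshold Critical force, N (default 20).
#' @param flip_threshold Orientation-flip threshold, rad (default `pi/2`).
#' @param seed Integer seed echoed into the report (the pipeline itself is
#'   deterministic).
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(capture, out_dir, vsk = NULL, mesh = NULL,
                       markers = NULL, correspondence = NULL,
                       force_trace = NULL, scale = 0.1, alpha = 0.2,
                       max_gap = 3L, force_threshold = 20,
                       flip_threshold = pi / 2, seed = 1L) {
  for (p in c(capture, vsk, mesh, markers, correspondence, force_trace))
    if (!file.exists(p))
      abort_rt(sprintf("configured input does not exist: %s", p),
               "config_error")
  if (!is.numeric(scale) || scale <= 0)
    abort_rt("scale must be positive", "config_error")
  if (alpha <= 0 || alpha > 1)
    abort_rt("alpha must be in (0, 1]", "config_error")
  if (max_gap < 0) abort_rt("max_gap must be >= 0", "config_error")
  if (force_threshold <= 0)
    abort_rt("force_threshold must be positive", "config_error")
  if (!is.null(correspondence) != !is.null(markers))
    abort_rt("registration needs both `markers` and `correspondence`",
             "config_error")
  structure(list(capture = capture, out_dir = out_dir, vsk = vsk,
                 mesh = mesh, markers = markers,
                 correspondence = correspondence,
                 force_trace = force_trace, scale = scale, alpha = alpha,
                 max_gap = as.integer(max_gap),
                 force_threshold = force_threshold,
                 flip_threshold = flip_threshold, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path Path to a YAML file whose keys are the arguments of
#'   [run_config]; relative input paths are resolved against the file's
#'   directory.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    abort_rt(sprintf("config file not found: %s", path), "config_error")
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("capture", "vsk", "mesh", "markers", "correspondence",
                "force_trace", "out_dir"))
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]]))
      cfg[[key]] <- file.path(base, cfg[[key]])
  do.call(run_config, cfg)
}

#' Run the offline tracking pipeline
#'
#' Replays a capture session through the full processing chain: occlusion
#' gap filling, low-pass filtering, orientation-flip detection, scale and
#' rotation conversion to scene poses, optional application of the
#' registered model-to-capture transform, and the critical-force monitor.
#' Writes `scene_poses.csv`, `warnings.csv` and a machine-readable
#' `report.json` into the output directory; on failure the partially
#' written outputs are removed and the error names the failing stage.
#'
#' @param config A `"run_config"` (or path to a YAML config).
#' @return The run report, invisibly (also written as JSON): stage counts
#'   (frames, gaps filled/unresolved, flips, force warnings), the
#'   registration residual when registration ran, and a full parameter
#'   echo.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    abort_rt("`config` must be a run_config or a YAML path", "config_error")
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  outputs <- file.path(config$out_dir,
                       c("scene_poses.csv", "warnings.csv", "report.json"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(outputs)
      abort_rt(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "pipeline_error")
    })
  }

  stream <- stage("load-capture", read_capture_csv(config$capture))
  model <- if (!is.null(config$vsk)) stage("load-vsk", {
    m <- read_vsk(config$vsk)
    bad <- validate_model(m)
    if (length(bad))
      abort_rt(paste("tracking model not trackable:",
                     paste(bad, collapse = "; ")), "trackability_error")
    m
  }) else NULL

  reg <- NULL
  if (!is.null(config$markers)) {
    reg <- stage("register", {
      cap <- read_captured_markers(config$markers)
      corr <- read_correspondence(config$correspondence)
      mesh <- if (!is.null(config$mesh)) read_mesh(config$mesh) else NULL
      register_captured(cap, corr, mesh)
    })
  }

  filled <- stage("fill-occlusions", fill_occlusions(stream, config$max_gap))
  n_missing_before <- sum(is.na(stream$frames$tx_mm))
  n_missing_after <- sum(is.na(filled$stream$frames$tx_mm))
  smoothed <- stage("lowpass", lowpass(filled$stream, config$alpha))
  flips <- stage("detect-flips",
                 detect_orientation_flips(smoothed, config$flip_threshold))
  scene <- stage("convert", convert_stream(smoothed, config$scale))

  if (!is.null(reg)) {
    # express the virtual model in the scene: captured pose composed with
    # the registered model -> capture transform, in scene units
    scene <- stage("apply-registration", {
      tr <- reg$transform
      for (i in seq_len(nrow(scene))) {
        if (is.na(scene$qw[i])) next
        pose <- rigid_transform(
          quaternion(scene$qw[i], scene$qx[i], scene$qy[i], scene$qz[i],
                     normalize = TRUE),
          c(scene$sx_cm[i], scene$sy_cm[i], scene$sz_cm[i]) / config$scale)
        comp <- compose_transform(pose, tr)
        scene$sx_cm[i] <- comp$translation[1] * config$scale
        scene$sy_cm[i] <- comp$translation[2] * config$scale
        scene$sz_cm[i] <- comp$translation[3] * config$scale
        scene$qw[i] <- comp$rotation[1]; scene$qx[i] <- comp$rotation[2]
        scene$qy[i] <- comp$rotation[3]; scene$qz[i] <- comp$rotation[4]
      }
      scene
    })
  }

  events <- if (!is.null(config$force_trace)) stage("monitor-force",
    monitor_force(read_force_trace(config$force_trace),
                  config$force_threshold))
  else data.frame(timestamp = numeric(0), force = numeric(0),
                  threshold = numeric(0), message = character(0))

  stage("write-outputs", {
    num <- function(x) ifelse(is.na(x), "", sprintf("%.9f", x))
    con <- file(outputs[1L], open = "wb")
    writeLines(c(
      "frame,time_s,object,sx_cm,sy_cm,sz_cm,qw,qx,qy,qz",
      sprintf("%d,%s,%s,%s,%s,%s,%s,%s,%s,%s",
              scene$frame, fmt6(scene$time_s), scene$object,
              num(scene$sx_cm), num(scene$sy_cm), num(scene$sz_cm),
              num(scene$qw), num(scene$qx), num(scene$qy), num(scene$qz))
    ), con = con, sep = "\n")
    close(con)
    con <- file(outputs[2L], open = "wb")
    writeLines(c("timestamp,force,threshold,message",
                 if (nrow(events))
                   sprintf("%s,%s,%s,\"%s\"", fmt6(events$timestamp),
                           fmt6(events$force), fmt6(events$threshold),
                           events$message)),
               con = con, sep = "\n")
    close(con)
  })

  report <- list(
    tool = "rigidtrack",
    seed = config$seed,
    parameters = config[c("scale", "alpha", "max_gap", "force_threshold",
                          "flip_threshold")],
    counts = list(
      frames = length(unique(stream$frames$frame)),
      objects = length(unique(stream$frames$object)),
      occluded_rows = n_missing_before,
      gaps_filled = n_missing_before - n_missing_after,
      unresolved_gaps = nrow(filled$unresolved_gaps),
      flips_detected = nrow(flips),
      force_warnings = nrow(events)),
    registration = if (!is.null(reg)) list(
      rms_residual = reg$rms_residual,
      n_pairs = length(reg$per_pair_residuals)) else NULL,
    tracking_model = if (!is.null(model)) list(
      markers = nrow(model$markers$positions),
      radius = model$markers$radius) else NULL)
  stage("write-report",
        jsonlite::write_json(report, outputs[3L], auto_unbox = TRUE,
                             pretty = TRUE, digits = NA, null = "null"))
  invisible(report)
}
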