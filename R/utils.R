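# internal helpers shared across modules

# signal a classed condition so callers can test on error class
abort_rt <- function(message, class, call = NULL) {
  stop(structure(
    class = c(class, "rigidtrack_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

warn_rt <- function(message, class) {
  warning(structure(
    class = c(class, "rigidtrack_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

# coerce a 3-vector or n x 3 matrix/data.frame of points to an n x 3 matrix
as_points_matrix <- function(p, arg = "points") {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.numeric(p) && is.null(dim(p))) {
    if (length(p) != 3L)
      abort_rt(sprintf("`%s` must be a 3-vector or an n x 3 matrix", arg),
               "invalid_argument")
    p <- matrix(p, nrow = 1L)
  }
  if (!is.matrix(p) || ncol(p) != 3L || !is.numeric(p))
    abort_rt(sprintf("`%s` must be a 3-vector or an n x 3 matrix", arg),
             "invalid_argument")
  storage.mode(p) <- "double"
  if (!all(is.finite(p)))
    abort_rt(sprintf("`%s` contains non-finite coordinates", arg),
             "invalid_argument")
  p
}

vnorm <- function(v) sqrt(sum(v * v))

# fixed 6-decimal serialization used by all golden-file writers
fmt6 <- function(x) sprintf("%.6f", x)
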