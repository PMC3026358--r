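#' Rigid transform (rotation + translation)
#'
#' A rigid transform maps points as `R p + t` where `R` is the rotation of
#' the stored unit quaternion and `t` the translation. Used throughout to map
#' capture-volume coordinates to virtual-model coordinates and back.
#'
#' @param rotation A unit [quaternion] (default identity).
#' @param translation Numeric 3-vector (default zero).
#' @return An object of class `"rigid_transform"`.
#' @examples
#' tf <- rigid_transform(expmap_to_quaternion(c(0, 0, pi / 2)), c(5, 0, 0))
#' apply_transform(tf, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = quaternion(1, 0, 0, 0),
                            translation = c(0, 0, 0)) {
  rotation <- as_quaternion(rotation)
  if (!is.numeric(translation) || length(translation) != 3L ||
      !all(is.finite(translation)))
    abort_rt("translation must be a finite numeric 3-vector",
             "invalid_argument")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  r <- quaternion_to_expmap(x$rotation)
  cat(sprintf(paste0("<rigid_transform> angle %.4g rad about (%.3g, %.3g, ",
                     "%.3g); t = (%.6g, %.6g, %.6g)\n"),
              vnorm(r),
              if (vnorm(r) > 0) r[1] / vnorm(r) else 0,
              if (vnorm(r) > 0) r[2] / vnorm(r) else 0,
              if (vnorm(r) > 0) r[3] / vnorm(r) else 1,
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform].
#' @param points A 3-vector or an `n x 3` matrix of points.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  if (!inherits(transform, "rigid_transform"))
    abort_rt("`transform` must be a rigid_transform", "invalid_argument")
  vec_in <- is.numeric(points) && is.null(dim(points))
  p <- as_points_matrix(points)
  R <- quat_to_matrix(transform$rotation)
  out <- p %*% t(R) +
    matrix(transform$translation, nrow(p), 3L, byrow = TRUE)
  if (vec_in) out <- drop(out)
  out
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a`
#' (`(a o b)(p) = a(b(p))`). `invert_transform(a)` returns the transform with
#' `invert_transform(a) o a` equal to the identity.
#'
#' @param a,b [rigid_transform] objects.
#' @return A [rigid_transform].
#' @export
compose_transform <- function(a, b) {
  if (!inherits(a, "rigid_transform") || !inherits(b, "rigid_transform"))
    abort_rt("arguments must be rigid_transform objects", "invalid_argument")
  rigid_transform(
    quat_multiply(a$rotation, b$rotation),
    drop(quat_to_matrix(a$rotation) %*% b$translation) + a$translation
  )
}

#' @rdname compose_transform
#' @export
invert_transform <- function(a) {
  if (!inherits(a, "rigid_transform"))
    abort_rt("argument must be a rigid_transform", "invalid_argument")
  qi <- quat_conjugate(a$rotation)
  rigid_transform(qi, -drop(quat_to_matrix(qi) %*% a$translation))
}
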