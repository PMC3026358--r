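#' Unit quaternion construction
#'
#' Quaternions are stored scalar-first as a named numeric vector
#' `c(w, x, y, z)` with the canonical sign convention `w >= 0` (when `w == 0`,
#' the first non-zero component is made positive). All rotations in the
#' package use a right-handed coordinate frame.
#'
#' @param w,x,y,z Quaternion components, scalar part first.
#' @param normalize Normalize to unit length (default `TRUE`). When `FALSE`
#'   the input must already be unit to within `1e-9`.
#' @return An object of class `"quaternion"`: numeric `c(w, x, y, z)`.
#' @examples
#' quaternion(1, 0, 0, 0)                   # identity
#' quaternion(sqrt(0.5), sqrt(0.5), 0, 0)   # 90 degrees about x
#' @export
quaternion <- function(w, x, y, z, normalize = TRUE) {
  q <- c(w = as.numeric(w), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z))
  if (!all(is.finite(q)))
    abort_rt("quaternion components must be finite", "invalid_argument")
  n <- vnorm(q)
  if (n == 0)
    abort_rt("zero quaternion is not a rotation", "invalid_argument")
  if (normalize) {
    q <- q / n
  } else if (abs(n - 1) > 1e-9) {
    abort_rt(sprintf("quaternion is not unit length (|q| = %.3g)", n),
             "invalid_argument")
  }
  structure(quat_canonical_sign(q), class = "quaternion")
}

quat_canonical_sign <- function(q) {
  nz <- which(abs(q) > 0)
  if (length(nz) && q[nz[1L]] < 0) q <- -q
  q
}

as_quaternion <- function(q) {
  if (inherits(q, "quaternion")) return(q)
  if (is.numeric(q) && length(q) == 4L)
    return(quaternion(q[1L], q[2L], q[3L], q[4L], normalize = FALSE))
  abort_rt("expected a quaternion (w, x, y, z)", "invalid_argument")
}

#' @export
print.quaternion <- function(x, ...) {
  cat(sprintf("<quaternion> w=%.6g x=%.6g y=%.6g z=%.6g (angle %.4g rad)\n",
              x[1L], x[2L], x[3L], x[4L],
              2 * atan2(vnorm(x[2:4]), x[1L])))
  invisible(x)
}

#' Convert an exponential-map rotation vector to a quaternion
#'
#' The exponential map encodes a rotation as a 3-vector whose direction is
#' the rotation axis and whose magnitude is the rotation angle in radians
#' (the representation optical motion-capture systems deliver per frame).
#' Angles below `1e-8` rad take a second-order series branch for
#' `sin(theta/2)/theta` so the axis scaling never divides by a vanishing
#' angle.
#'
#' @param r Numeric 3-vector `(rx, ry, rz)` in radians.
#' @return A unit [quaternion] rotating by `norm(r)` about `r / norm(r)`.
#' @examples
#' expmap_to_quaternion(c(0, 0, 0))        # identity
#' expmap_to_quaternion(c(pi / 2, 0, 0))   # 90 degrees about x
#' @seealso [quaternion_to_expmap()]
#' @export
expmap_to_quaternion <- function(r) {
  if (!is.numeric(r) || length(r) != 3L || !all(is.finite(r)))
    abort_rt("rotation vector must be a finite numeric 3-vector",
             "invalid_argument")
  theta <- vnorm(r)
  if (theta < 1e-8) {
    # series: cos(t/2) ~ 1 - t^2/8, sin(t/2)/t ~ 1/2 - t^2/48
    w <- 1 - theta^2 / 8
    s <- 0.5 - theta^2 / 48
  } else {
    w <- cos(theta / 2)
    s <- sin(theta / 2) / theta
  }
  quaternion(w, s * r[1L], s * r[2L], s * r[3L])
}

#' Convert a unit quaternion to a canonical exponential-map vector
#'
#' Inverse of [expmap_to_quaternion()]. The result is canonical: its
#' magnitude (the rotation angle) lies in `[0, pi]`.
#'
#' @param q A unit [quaternion] (checked to within `1e-6`).
#' @return Numeric 3-vector, radians.
#' @export
quaternion_to_expmap <- function(q) {
  if (!is.numeric(q) || length(q) != 4L)
    abort_rt("expected a quaternion (w, x, y, z)", "invalid_argument")
  n <- vnorm(q)
  if (!is.finite(n) || abs(n - 1) > 1e-6)
    abort_rt(sprintf("quaternion is not unit length (|q| = %.3g)", n),
             "invalid_argument")
  q <- quat_canonical_sign(q / n)
  v <- q[2:4]
  sv <- vnorm(v)
  theta <- 2 * atan2(sv, q[1L])
  if (sv < 1e-9) {
    # near identity: q ~ (1, r/2)
    r <- 2 * v
  } else {
    r <- v * (theta / sv)
  }
  unname(r)
}

#' Hamilton product of two quaternions
#'
#' `quat_multiply(a, b)` is the rotation applying `b` first, then `a`.
#' @param a,b Quaternions.
#' @return The product quaternion (canonical sign).
#' @export
quat_multiply <- function(a, b) {
  a <- as_quaternion(a); b <- as_quaternion(b)
  quaternion(
    a[1L] * b[1L] - a[2L] * b[2L] - a[3L] * b[3L] - a[4L] * b[4L],
    a[1L] * b[2L] + a[2L] * b[1L] + a[3L] * b[4L] - a[4L] * b[3L],
    a[1L] * b[3L] - a[2L] * b[4L] + a[3L] * b[1L] + a[4L] * b[2L],
    a[1L] * b[4L] + a[2L] * b[3L] - a[3L] * b[2L] + a[4L] * b[1L]
  )
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(a) {
  a <- as_quaternion(a)
  quaternion(a[1L], -a[2L], -a[3L], -a[4L])
}

#' Rotation matrix from a unit quaternion
#' @param q A unit quaternion.
#' @return A 3 x 3 proper rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- as_quaternion(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3L, byrow = TRUE)
}

#' Unit quaternion from a proper rotation matrix
#'
#' Shepperd's method: the largest of the four squared components is computed
#' first, which keeps the extraction well conditioned for any rotation.
#'
#' @param R A 3 x 3 rotation matrix (`det(R) = +1`, orthonormal to `1e-6`).
#' @return A unit [quaternion].
#' @export
matrix_to_quat <- function(R) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)))
    abort_rt("expected a 3 x 3 rotation matrix", "invalid_argument")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    abort_rt("matrix is not a proper rotation", "invalid_argument")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > max(R[1, 1], R[2, 2], R[3, 3])) {
    s <- 2 * sqrt(1 + tr)
    q <- c(s / 4,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3L + 1L
    k <- j %% 3L + 1L
    s <- 2 * sqrt(1 + R[i, i] - R[j, j] - R[k, k])
    q <- numeric(4L)
    q[1L] <- (R[k, j] - R[j, k]) / s
    q[i + 1L] <- s / 4
    q[j + 1L] <- (R[j, i] + R[i, j]) / s
    q[k + 1L] <- (R[k, i] + R[i, k]) / s
  }
  quaternion(q[1L], q[2L], q[3L], q[4L])
}

#' Geodesic angle between two rotations
#' @param a,b Unit quaternions.
#' @return Rotation angle in radians, in `[0, pi]`.
#' @export
quat_angle <- function(a, b) {
  a <- as_quaternion(a); b <- as_quaternion(b)
  bv <- unclass(b)
  if (sum(a * bv) < 0) bv <- -bv
  # chord identity |a - b| = 2 sin(theta/4): well conditioned near zero,
  # unlike the acos of the dot product
  4 * asin(min(1, vnorm(unclass(a) - bv) / 2))
}

#' Spherical linear interpolation between two unit quaternions
#'
#' Interpolates along the shorter geodesic arc (the sign of `b` is flipped
#' when the dot product is negative). Nearly parallel inputs fall back to
#' normalized linear interpolation.
#'
#' @param a,b Unit quaternions.
#' @param t Interpolation fraction in `[0, 1]`.
#' @return A unit [quaternion].
#' @export
quat_slerp <- function(a, b, t) {
  a <- as_quaternion(a); b <- as_quaternion(b)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0 || t > 1)
    abort_rt("`t` must be a single value in [0, 1]", "invalid_argument")
  d <- sum(a * b)
  bv <- unclass(b)
  if (d < 0) { bv <- -bv; d <- -d }
  if (d > 1 - 1e-12) {
    q <- (1 - t) * unclass(a) + t * bv   # nlerp fallback
  } else {
    omega <- acos(min(1, d))
    q <- (sin((1 - t) * omega) * unclass(a) + sin(t * omega) * bv) /
      sin(omega)
  }
  quaternion(q[1L], q[2L], q[3L], q[4L])
}

# row-wise expmap -> quaternion for pose streams; rv is n x 3, returns n x 4
expmap_to_quat_rows <- function(rv) {
  n <- nrow(rv)
  out <- matrix(NA_real_, n, 4L)
  ok <- stats::complete.cases(rv)
  for (i in which(ok)) out[i, ] <- unclass(expmap_to_quaternion(rv[i, ]))
  out
}

# row-wise inverse; qm is n x 4, returns n x 3
quat_to_expmap_rows <- function(qm) {
  n <- nrow(qm)
  out <- matrix(NA_real_, n, 3L)
  ok <- stats::complete.cases(qm)
  for (i in which(ok)) out[i, ] <- quaternion_to_expmap(qm[i, ])
  out
}
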