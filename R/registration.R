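#' Marker set
#'
#' An ordered, named set of retro-reflective marker positions. For a
#' tracking model the positions are expressed relative to the root segment
#' (the free 6-DOF joint at the model origin); for a captured set they are
#' capture-volume coordinates in millimetres.
#'
#' @param positions `n x 3` matrix of marker positions (mm).
#' @param names Unique marker names; default `M1..Mn`.
#' @param radius Marker radius, mm. The markers used on surgical instruments
#'   are small spheres; the tracking-model default is 0.5.
#' @return Object of class `"marker_set"`: list with `positions` (rownames =
#'   marker names) and `radius`.
#' @export
marker_set <- function(positions, names = NULL, radius = 0.5) {
  positions <- as_points_matrix(positions, "positions")
  n <- nrow(positions)
  if (is.null(names)) names <- paste0("M", seq_len(n))
  names <- as.character(names)
  if (length(names) != n)
    abort_rt("one name per marker required", "invalid_argument")
  if (anyDuplicated(names))
    abort_rt("marker names must be unique", "invalid_argument")
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    abort_rt("marker radius must be a positive number", "invalid_argument")
  rownames(positions) <- names
  structure(list(positions = positions, radius = radius),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers (radius %g mm): %s\n",
              nrow(x$positions), x$radius,
              paste(rownames(x$positions), collapse = ", ")))
  invisible(x)
}

marker_names <- function(ms) rownames(ms$positions)

# rank of the centered configuration decides whether a unique rotation
# exists: collinear (rank < 2) point sets leave one rotational DOF free
is_collinear <- function(points, rtol = 1e-9) {
  pc <- scale(points, scale = FALSE)
  sv <- svd(pc, nu = 0, nv = 0)$d
  sv[2L] < rtol * max(sv[1L], .Machine$double.xmin)
}

#' Least-squares rigid alignment of two corresponded point sets
#'
#' Finds the rotation `R` (proper, `det = +1`) and translation `t`
#' minimizing `sum_i || R src_i + t - dst_i ||^2` by the SVD (Kabsch)
#' method: the point sets are centered, the 3 x 3 cross-covariance is
#' decomposed, and a reflection (negative determinant) is corrected by
#' flipping the singular direction with the smallest singular value.
#' This is the core of marker-based registration: `src` are virtual-model
#' surface points, `dst` the captured marker positions.
#'
#' @param src,dst `n x 3` matrices of corresponding points, `n >= 3`,
#'   not collinear.
#' @return Object of class `"registration_result"`: list with `transform`
#'   (a [rigid_transform] mapping `src` coordinates into `dst` coordinates),
#'   `rms_residual`, and `per_pair_residuals`.
#' @examples
#' src <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' dst <- rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))  # 90 deg about z
#' fit_rigid_transform(src, dst)
#' @export
fit_rigid_transform <- function(src, dst) {
  src <- as_points_matrix(src, "src")
  dst <- as_points_matrix(dst, "dst")
  if (nrow(src) != nrow(dst))
    abort_rt("`src` and `dst` must have the same number of points",
             "invalid_argument")
  n <- nrow(src)
  if (n < 3L)
    abort_rt(sprintf(
      "underdetermined: %d point pair(s); at least 3 non-collinear pairs are required",
      n), "underdetermined_error")
  if (is_collinear(src))
    abort_rt("underdetermined: source points are collinear, rotation is not unique",
             "underdetermined_error")
  cs <- colMeans(src); cd <- colMeans(dst)
  sc <- sweep(src, 2L, cs)
  dc <- sweep(dst, 2L, cd)
  H <- crossprod(sc, dc)           # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cd - drop(R %*% cs)
  fitted <- src %*% t(R) + matrix(t, n, 3L, byrow = TRUE)
  res <- sqrt(rowSums((fitted - dst)^2))
  structure(list(
    transform = rigid_transform(matrix_to_quat(R), t),
    rotation_matrix = R,
    rms_residual = sqrt(mean(res^2)),
    per_pair_residuals = res
  ), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %d pairs, rms residual %.6g\n",
              length(x$per_pair_residuals), x$rms_residual))
  print(x$transform)
  invisible(x)
}

#' Correspondence between captured markers and virtual surface points
#'
#' The manual association step of semi-automatic registration: each captured
#' marker name is paired with the point on the virtual model surface where
#' that physical marker sits.
#'
#' @param marker Character vector of marker names.
#' @param points `n x 3` matrix of virtual-model surface points.
#' @return A `data.frame` with columns `marker`, `vx`, `vy`, `vz` of class
#'   `"correspondence"`.
#' @export
correspondence <- function(marker, points) {
  points <- as_points_matrix(points)
  marker <- as.character(marker)
  if (length(marker) != nrow(points))
    abort_rt("one virtual point per marker name required", "invalid_argument")
  if (anyDuplicated(marker))
    abort_rt("correspondence marker names must be unique", "invalid_argument")
  structure(data.frame(marker = marker, vx = points[, 1], vy = points[, 2],
                       vz = points[, 3], stringsAsFactors = FALSE),
            class = c("correspondence", "data.frame"))
}

#' Read / write the correspondence CSV dialect
#'
#' Plain-text format, one header line `marker,vx,vy,vz` preceded by the
#' version comment `# rigidtrack-correspondence v1`.
#'
#' @param path File path.
#' @return `read_correspondence` returns a [correspondence];
#'   `write_correspondence` returns `path` invisibly.
#' @export
read_correspondence <- function(path) {
  if (!file.exists(path))
    abort_rt(sprintf("correspondence file not found: %s", path), "io_error")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("marker", "vx", "vy", "vz")
  if (!all(need %in% names(df)))
    abort_rt("correspondence CSV must have columns marker,vx,vy,vz",
             "parse_error")
  correspondence(df$marker, as.matrix(df[, c("vx", "vy", "vz")]))
}

#' @rdname read_correspondence
#' @param corr A [correspondence].
#' @export
write_correspondence <- function(corr, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("# rigidtrack-correspondence v1", "marker,vx,vy,vz",
               sprintf("%s,%s,%s,%s", corr$marker, fmt6(corr$vx),
                       fmt6(corr$vy), fmt6(corr$vz))),
             con = con, sep = "\n")
  invisible(path)
}

#' Register a captured marker set against a virtual model
#'
#' Reverse-direction registration: marker positions measured in the capture
#' volume are aligned with user-supplied corresponding points on the virtual
#' surface by least squares ([fit_rigid_transform]). The returned transform
#' maps model coordinates into the capture frame; the per-pair residual
#' report supports quick re-registration when an association was wrong.
#'
#' @param markers A [marker_set] measured in the capture frame.
#' @param corr A [correspondence] pairing marker names with virtual points.
#' @param mesh Optional [surface_mesh]; when given, each virtual point is
#'   checked to lie near the surface (within 1% of the bounding-box
#'   diagonal).
#' @return A `"registration_result"` (see [fit_rigid_transform]).
#' @export
register_captured <- function(markers, corr, mesh = NULL) {
  stopifnot(inherits(markers, "marker_set"))
  if (!inherits(corr, "correspondence"))
    abort_rt("`corr` must be a correspondence", "invalid_argument")
  if (nrow(corr) < 3L)
    abort_rt("underdetermined: at least 3 correspondence pairs are required",
             "underdetermined_error")
  unknown <- setdiff(corr$marker, marker_names(markers))
  if (length(unknown))
    abort_rt(sprintf("correspondence references unknown marker(s): %s",
                     paste(unknown, collapse = ", ")),
             "invalid_argument")
  vpts <- as.matrix(corr[, c("vx", "vy", "vz")])
  if (!is.null(mesh)) {
    tol <- 0.01 * bbox_diagonal(mesh)
    for (i in seq_len(nrow(vpts))) {
      d <- closest_surface_point(mesh, vpts[i, ])$distance
      if (d > tol)
        abort_rt(sprintf(
          "virtual point for marker '%s' is %.3g units off the surface (tolerance %.3g)",
          corr$marker[i], d, tol), "invalid_pick_error")
    }
  }
  cpts <- markers$positions[corr$marker, , drop = FALSE]
  res <- fit_rigid_transform(vpts, cpts)
  names(res$per_pair_residuals) <- corr$marker
  res
}

#' Place virtual markers on a model surface (forward registration)
#'
#' Forward-direction registration: feature points are picked directly on the
#' virtual object and become the tracking model's marker set, expressed
#' relative to the root segment at the origin. Each pick is snapped to the
#' nearest surface point; picks farther than `snap_tol` from the surface are
#' rejected. A proximity warning is raised when two markers end up closer
#' than `min_separation` — crowded markers degrade tracking accuracy.
#'
#' @param mesh A [surface_mesh] in model coordinates (root segment at the
#'   origin).
#' @param picks `n x 3` matrix of picked points near the surface.
#' @param radius Marker radius (mm), default 0.5.
#' @param snap_tol Maximum pick-to-surface distance; default 1% of the mesh
#'   bounding-box diagonal.
#' @param min_separation Minimum recommended pairwise marker distance (same
#'   units as the mesh); default 1.
#' @param names Optional marker names.
#' @return A [marker_set] of snapped positions.
#' @export
place_virtual_markers <- function(mesh, picks, radius = 0.5,
                                  snap_tol = NULL, min_separation = 1,
                                  names = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  picks <- as_points_matrix(picks, "picks")
  if (is.null(snap_tol)) snap_tol <- 0.01 * bbox_diagonal(mesh)
  snapped <- matrix(NA_real_, nrow(picks), 3L)
  for (i in seq_len(nrow(picks))) {
    cp <- closest_surface_point(mesh, picks[i, ])
    if (cp$distance > snap_tol)
      abort_rt(sprintf(
        "pick %d is %.4g units from the surface (snap tolerance %.4g)",
        i, cp$distance, snap_tol), "invalid_pick_error")
    snapped[i, ] <- cp$point
  }
  if (nrow(snapped) >= 2L) {
    dmin <- min(stats::dist(snapped))
    if (dmin < min_separation)
      warn_rt(sprintf(
        "markers %.4g apart are closer than the minimum separation %.4g; crowded markers reduce tracking accuracy",
        dmin, min_separation), "marker_proximity_warning")
  }
  marker_set(snapped, names = names, radius = radius)
}
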