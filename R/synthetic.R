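# deterministic synthetic fixture generators: every input class the toolkit
# consumes can be produced offline, with no capture hardware

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic capture-trajectory specification
#'
#' Parameters of a simulated capture session: a smooth rigid path (multi-axis
#' sinusoidal translation plus rotation about a fixed axis), isotropic
#' Gaussian marker noise, Bernoulli frame dropout, and an explicit seed so
#' identical specs produce identical streams. Defaults emulate the
#' hand-held instrument conditions the toolkit targets: a 200 Hz capture
#' rate, a few centimetres of travel (30 mm amplitude) inside a desk-scale
#' capture volume, sub-millimetre optical noise (0.1 mm), and no dropout.
#'
#' @param n_frames Number of frames.
#' @param rate Capture rate, Hz (> 0).
#' @param amplitude_mm Translation amplitude per axis, mm.
#' @param angular_velocity Rotation speed about the fixed axis, rad/s.
#' @param noise_sigma Isotropic Gaussian noise on marker positions, mm.
#' @param dropout_rate Per-frame probability of an occlusion (pose lost), in
#'   `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return Object of class `"trajectory_spec"`.
#' @export
trajectory_spec <- function(n_frames = 200L, rate = 200,
                            amplitude_mm = 30, angular_velocity = 1,
                            noise_sigma = 0.1, dropout_rate = 0,
                            seed = 1L) {
  if (rate <= 0) abort_rt("rate must be positive", "invalid_argument")
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort_rt("dropout_rate must be in [0, 1)", "invalid_argument")
  if (n_frames < 1) abort_rt("n_frames must be >= 1", "invalid_argument")
  structure(list(n_frames = as.integer(n_frames), rate = rate,
                 amplitude_mm = amplitude_mm,
                 angular_velocity = angular_velocity,
                 noise_sigma = noise_sigma, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

# smooth ground-truth pose at time t: incommensurate sinusoids per axis,
# rotation about a fixed oblique axis
truth_pose_at <- function(t, spec) {
  A <- spec$amplitude_mm
  tr <- c(A * sin(2 * pi * 0.50 * t),
          A * sin(2 * pi * 0.35 * t + 1.0),
          A * sin(2 * pi * 0.23 * t + 2.0))
  axis <- c(0.36, 0.48, 0.80)                  # unit by construction
  q <- expmap_to_quaternion(axis * (spec$angular_velocity * t))
  rigid_transform(q, tr)
}

#' Generate a synthetic captured motion stream with ground truth
#'
#' Simulates what an optical tracker delivers for one rigid object: per
#' frame, the marker world positions are the ground-truth pose applied to
#' the root-relative marker positions plus iid Gaussian noise; the streamed
#' object pose is then re-estimated from those noisy markers by
#' least-squares rigid alignment (exactly how a real tracker computes the
#' root-segment pose). Frames are dropped (occluded) independently with the
#' spec's dropout probability. Identical seeds give identical output.
#'
#' @param spec A [trajectory_spec].
#' @param markers A trackable [marker_set] (root-relative, mm).
#' @param object Object name used in the stream.
#' @return List with `stream` (a [motion_stream]), `truth` (`data.frame`
#'   of ground-truth poses: `frame`, `time_s`, `tx_mm..tz_mm`,
#'   `qw..qz`), and `markers_world` (long `data.frame`: `frame`, `marker`,
#'   `x`, `y`, `z`, observed noisy positions; dropped frames omitted).
#' @export
gen_rigid_trajectory <- function(spec, markers, object = "object1") {
  stopifnot(inherits(spec, "trajectory_spec"),
            inherits(markers, "marker_set"))
  if (nrow(markers$positions) < 3L)
    abort_rt("marker set must be trackable (>= 3 markers)",
             "invalid_argument")
  local <- markers$positions
  nm <- rownames(local)
  n <- spec$n_frames
  with_seed(spec$seed, {
    tvec <- (seq_len(n) - 1L) / spec$rate
    dropped <- stats::runif(n) < spec$dropout_rate
    rows <- vector("list", n)
    truth <- vector("list", n)
    mw <- vector("list", n)
    for (k in seq_len(n)) {
      pose <- truth_pose_at(tvec[k], spec)
      truth[[k]] <- data.frame(
        frame = k, time_s = tvec[k],
        tx_mm = pose$translation[1], ty_mm = pose$translation[2],
        tz_mm = pose$translation[3],
        qw = pose$rotation[1], qx = pose$rotation[2],
        qy = pose$rotation[3], qz = pose$rotation[4])
      if (dropped[k]) {
        rows[[k]] <- data.frame(
          frame = k, time_s = tvec[k], object = object,
          tx_mm = NA_real_, ty_mm = NA_real_, tz_mm = NA_real_,
          rx = NA_real_, ry = NA_real_, rz = NA_real_,
          visible_markers = "")
        next
      }
      world <- apply_transform(pose, local)
      if (spec$noise_sigma > 0)
        world <- world + matrix(
          stats::rnorm(length(world), sd = spec$noise_sigma),
          nrow(world), 3L)
      est <- fit_rigid_transform(local, world)
      r <- quaternion_to_expmap(est$transform$rotation)
      rows[[k]] <- data.frame(
        frame = k, time_s = tvec[k], object = object,
        tx_mm = est$transform$translation[1],
        ty_mm = est$transform$translation[2],
        tz_mm = est$transform$translation[3],
        rx = r[1], ry = r[2], rz = r[3],
        visible_markers = paste(nm, collapse = ";"))
      mw[[k]] <- data.frame(frame = k, marker = nm,
                            x = world[, 1], y = world[, 2], z = world[, 3])
    }
    list(stream = motion_stream(do.call(rbind, rows), rate = spec$rate),
         truth = do.call(rbind, truth),
         markers_world = do.call(rbind, mw))
  })
}

# does any orthogonal map other than the identity send the centered point
# set onto a permutation of itself? distance-profile pruned automorphism
# search over the distance matrix, each candidate checked by a Procrustes
# fit (rotations and reflections both count as symmetries)
has_nontrivial_symmetry <- function(points, tol = 1e-6) {
  P <- as_points_matrix(points)
  n <- nrow(P)
  Pc <- sweep(P, 2L, colMeans(P))
  scale <- max(sqrt(rowSums(Pc^2)), 1e-12)
  D <- as.matrix(stats::dist(Pc))
  nrm <- sqrt(rowSums(Pc^2))
  # candidate images of i: points with the same centroid distance and the
  # same sorted distance profile
  prof <- apply(D, 1L, function(r) paste(round(sort(r) / scale / tol), collapse = ","))
  cand <- lapply(seq_len(n), function(i)
    which(abs(nrm - nrm[i]) < tol * scale & prof == prof[i]))
  perm <- integer(n)
  found <- FALSE
  search <- function(depth) {
    if (found) return()
    if (depth > n) {
      if (all(perm == seq_len(n))) return()
      H <- crossprod(Pc[perm, , drop = FALSE], Pc)  # maps p_i -> p_perm[i]
      sv <- svd(H)
      O <- sv$u %*% t(sv$v)
      if (max(abs(Pc %*% t(O) - Pc[perm, , drop = FALSE])) < tol * scale)
        found <<- TRUE
      return()
    }
    for (j in cand[[depth]]) {
      if (j %in% perm[seq_len(depth - 1L)]) next
      ok <- TRUE
      for (k in seq_len(depth - 1L))
        if (abs(D[depth, k] - D[j, perm[k]]) > tol * scale) { ok <- FALSE; break }
      if (!ok) next
      perm[depth] <<- j
      search(depth + 1L)
      if (found) return()
    }
    perm[depth] <<- 0L
  }
  search(1L)
  found
}

#' Generate an asymmetric random marker cloud
#'
#' Rejection-samples `n` marker positions in a cube of half-width
#' `halfwidth` until all pairwise distances are at least `min_separation`
#' and the configuration has no non-trivial point-group symmetry (no
#' rotation or reflection other than the identity maps the set onto
#' itself). Asymmetric placement is what lets a tracker tell left from
#' right — a symmetric set has indistinguishable mirror poses.
#'
#' @param n Number of markers, `>= 3`.
#' @param min_separation Minimum pairwise distance, mm (default 10).
#' @param seed Integer RNG seed.
#' @param halfwidth Sampling cube half-width, mm (default 50).
#' @param radius Marker radius for the resulting set, default 0.5.
#' @param max_attempts Attempt budget before declaring the packing
#'   infeasible.
#' @return A [marker_set].
#' @export
gen_marker_cloud <- function(n, min_separation = 10, seed = 1L,
                             halfwidth = 50, radius = 0.5,
                             max_attempts = 2000L) {
  if (n < 3L) abort_rt("need at least 3 markers", "invalid_argument")
  if (min_separation > 2 * halfwidth * sqrt(3))
    abort_rt("min_separation exceeds the sampling domain; packing infeasible",
             "feasibility_error")
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      pts <- matrix(numeric(0), 0L, 3L)
      ok <- TRUE
      tries <- 0L
      while (nrow(pts) < n) {
        p <- stats::runif(3, -halfwidth, halfwidth)
        if (nrow(pts) == 0L ||
            min(sqrt(rowSums(sweep(pts, 2L, p)^2))) >= min_separation) {
          pts <- rbind(pts, p)
        } else {
          tries <- tries + 1L
          if (tries > 200L * n) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      if (!is_collinear(pts) && !has_nontrivial_symmetry(pts))
        return(marker_set(pts, radius = radius))
    }
    abort_rt(sprintf(
      "could not place %d markers with separation %g in %d attempts",
      n, min_separation, max_attempts), "feasibility_error")
  })
}

#' Structured tetrahedral block mesh
#'
#' A `nx x ny x nz` grid of hexahedra, each split into six tetrahedra along
#' the main diagonal (Kuhn/Freudenthal subdivision, conforming across cell
#' faces). Node and element counts follow the closed forms
#' `(nx+1)(ny+1)(nz+1)` and `6 nx ny nz`; all element volumes are positive.
#'
#' @param nx,ny,nz Element counts per axis, `>= 1`.
#' @param dims Block dimensions `c(Lx, Ly, Lz)`, mm.
#' @param material A [material] (default a bone-like placeholder,
#'   E = 12000 MPa, nu = 0.3 — illustrative, not a literature value).
#' @return A [tet_mesh] with nodes on the structured grid (origin corner at
#'   `(0, 0, 0)`).
#' @export
gen_block_tetmesh <- function(nx, ny, nz, dims = c(10, 10, 10),
                              material = NULL) {
  if (any(c(nx, ny, nz) < 1L))
    abort_rt("element counts must be >= 1", "invalid_argument")
  if (is.null(material)) material <- material(12000, 0.3)
  nxn <- nx + 1L; nyn <- ny + 1L; nzn <- nz + 1L
  gx <- seq(0, dims[1], length.out = nxn)
  gy <- seq(0, dims[2], length.out = nyn)
  gz <- seq(0, dims[3], length.out = nzn)
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  nid <- function(i, j, k) i + (j - 1L) * nxn + (k - 1L) * nxn * nyn
  # Kuhn: six tets along the axis-permutation paths from corner 000 to 111
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  elems <- matrix(0L, 6L * nx * ny * nz, 4L)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    corner <- function(off) nid(i + off[1], j + off[2], k + off[3])
    for (p in perms) {
      off <- c(0L, 0L, 0L)
      tet <- integer(4L)
      tet[1L] <- corner(off)
      for (s in 1:3) {
        off[p[s]] <- 1L
        tet[s + 1L] <- corner(off)
      }
      e <- e + 1L
      elems[e, ] <- tet
    }
  }
  tet_mesh(nodes, elems, material)
}

#' Ellipsoid surface mesh (subdivided icosphere)
#'
#' An icosahedron subdivided `subdivisions` times, projected onto the unit
#' sphere and scaled by the semi-axes — the shape family of the mold that
#' fixes a vertebra model in the capture volume. Every vertex lies exactly
#' on the ellipsoid; the mesh is closed (Euler characteristic 2).
#'
#' @param a,b,c Semi-axes (positive).
#' @param subdivisions Subdivision levels, `>= 0` (0 = icosahedron).
#' @return A [surface_mesh].
#' @export
gen_ellipsoid_mesh <- function(a = 1, b = 1, c = 1, subdivisions = 2L) {
  if (any(c(a, b, c) <= 0))
    abort_rt("semi-axes must be positive", "invalid_argument")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lvl in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(midcache[[key]])) return(midcache[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / vnorm(m)
      v <<- rbind(v, m)
      midcache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      i1 <- f[t, 1]; i2 <- f[t, 2]; i3 <- f[t, 3]
      a12 <- midpoint(i1, i2); a23 <- midpoint(i2, i3); a31 <- midpoint(i3, i1)
      nf[4L * t - 3L, ] <- c(i1, a12, a31)
      nf[4L * t - 2L, ] <- c(i2, a23, a12)
      nf[4L * t - 1L, ] <- c(i3, a31, a23)
      nf[4L * t, ] <- c(a12, a23, a31)
    }
    f <- nf
  }
  v <- sweep(v, 2L, c(a, b, c), `*`)
  surface_mesh(v, f, name = "ellipsoid")
}
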