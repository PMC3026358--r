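#' Triangle surface mesh
#'
#' Container for the rigid-body surface geometry a virtual model is defined
#' on. Faces with (near) zero area are dropped at construction time, so a
#' valid `surface_mesh` never carries degenerate triangles.
#'
#' @param vertices `n x 3` numeric matrix of vertex coordinates.
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @param name Optional mesh name (carried into tracking-model files).
#' @return An object of class `"surface_mesh"`.
#' @export
surface_mesh <- function(vertices, faces, name = NULL) {
  vertices <- as_points_matrix(vertices, "vertices")
  if (is.data.frame(faces)) faces <- as.matrix(faces)
  if (!is.matrix(faces) || ncol(faces) != 3L)
    abort_rt("`faces` must be an m x 3 index matrix", "invalid_argument")
  storage.mode(faces) <- "integer"
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    abort_rt("face indices out of range", "invalid_argument")
  if (nrow(faces)) {
    a <- triangle_areas(vertices, faces)
    scale <- max(vnorm(apply(vertices, 2, function(v) diff(range(v)))), 1)
    keep <- a > 1e-12 * scale^2
    faces <- faces[keep, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "surface_mesh")
}

triangle_areas <- function(v, f) {
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh%s> %d vertices, %d triangles\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

bbox_diagonal <- function(mesh) {
  vnorm(apply(mesh$vertices, 2, function(v) diff(range(v))))
}

#' Read a triangle surface mesh from OBJ, ASCII STL or ASCII PLY
#'
#' Text formats only; quad faces in OBJ/PLY are fan-triangulated. STL
#' vertices are welded exactly (bitwise-equal coordinates share an index).
#'
#' @param path Path to a `.obj`, `.stl` or `.ply` file.
#' @return A [surface_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path))
    abort_rt(sprintf("mesh file not found: %s", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    obj = read_obj(path),
    stl = read_stl_ascii(path),
    ply = read_ply_ascii(path),
    abort_rt(sprintf("unsupported mesh format '.%s' (OBJ/STL/PLY)", ext),
             "invalid_argument")
  )
  mesh$name <- sub("\\.[^.]*$", "", basename(path))
  mesh
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(vapply(strsplit(x[-1L], "/"), `[`, "", 1L))
    if (length(idx) < 3L)
      abort_rt("OBJ face with fewer than 3 vertices", "parse_error")
    # fan-triangulate polygons
    cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  }))
  surface_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1L]))
    abort_rt("not an ASCII STL file (binary STL is unsupported)",
             "parse_error")
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  if (is.null(coords) || nrow(coords) %% 3L != 0L)
    abort_rt("ASCII STL vertex count is not a multiple of 3", "parse_error")
  key <- apply(coords, 1L, paste, collapse = ",")
  idx <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end) || trimws(lines[1L]) != "ply")
    abort_rt("not an ASCII PLY file", "parse_error")
  hdr <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format ascii", hdr)))
    abort_rt("binary PLY is unsupported", "parse_error")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)[1L]))
  body <- lines[(end + 1L):length(lines)]
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vtok, function(x) as.numeric(x[1:3])))
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(ftok, function(x) {
    k <- as.integer(x[1L])
    idx <- as.integer(x[1L + seq_len(k)]) + 1L  # PLY is 0-based
    cbind(idx[1L], idx[2:(k - 1L)], idx[3:k])
  }))
  surface_mesh(verts, faces)
}

#' Write a surface mesh as Wavefront OBJ
#' @param mesh A [surface_mesh].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("v %s %s %s", fmt6(mesh$vertices[, 1]),
            fmt6(mesh$vertices[, 2]), fmt6(mesh$vertices[, 3])),
    sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  ), con = con, sep = "\n")
  invisible(path)
}

#' Extreme vertices of a mesh along the coordinate axes
#'
#' Returns the six argmin/argmax vertices (min and max along x, y and z),
#' the visual anchors used when placing virtual markers on a model. Ties are
#' broken by the lowest vertex index.
#'
#' @param mesh A [surface_mesh].
#' @return A data frame with columns `label` (`"xmin"`, `"xmax"`, ...),
#'   `vertex` (index), and `x`, `y`, `z`.
#' @export
compute_extreme_points <- function(mesh) {
  if (!inherits(mesh, "surface_mesh") || nrow(mesh$vertices) == 0L)
    abort_rt("mesh must contain at least one vertex", "invalid_argument")
  v <- mesh$vertices
  idx <- c(which.min(v[, 1]), which.max(v[, 1]),
           which.min(v[, 2]), which.max(v[, 2]),
           which.min(v[, 3]), which.max(v[, 3]))
  data.frame(label = c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax"),
             vertex = idx,
             x = v[idx, 1], y = v[idx, 2], z = v[idx, 3],
             row.names = NULL)
}

#' Intersection of a mesh with a plane
#'
#' Computes the points where mesh edges cross the plane through `point` with
#' normal `normal` (the reference-plane cross-section overlay used during
#' interactive marker placement). Vertices lying exactly on the plane are
#' included once.
#'
#' @param mesh A [surface_mesh].
#' @param point A point on the plane (3-vector).
#' @param normal Plane normal (3-vector, any non-zero length).
#' @return `k x 3` matrix of intersection points (0 rows when no edge
#'   crosses).
#' @export
plane_cross_section <- function(mesh, point, normal) {
  stopifnot(inherits(mesh, "surface_mesh"))
  point <- as.numeric(point); normal <- as.numeric(normal)
  if (length(normal) != 3L || !all(is.finite(normal)) || vnorm(normal) == 0)
    abort_rt("plane normal must be a non-zero 3-vector", "invalid_argument")
  n <- normal / vnorm(normal)
  v <- mesh$vertices
  d <- drop((v - matrix(point, nrow(v), 3L, byrow = TRUE)) %*% n)
  f <- mesh$faces
  edges <- unique(rbind(
    cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
    cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
    cbind(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))
  ))
  d1 <- d[edges[, 1]]; d2 <- d[edges[, 2]]
  cross <- d1 * d2 < 0
  pts <- NULL
  if (any(cross)) {
    w <- d1[cross] / (d1[cross] - d2[cross])
    p1 <- v[edges[cross, 1], , drop = FALSE]
    p2 <- v[edges[cross, 2], , drop = FALSE]
    pts <- p1 + w * (p2 - p1)
  }
  on_plane <- which(d == 0)
  if (length(on_plane)) pts <- rbind(pts, v[on_plane, , drop = FALSE])
  if (is.null(pts)) matrix(numeric(0), 0L, 3L) else unname(pts)
}

# closest point on triangle (a, b, c) to p -- Ericson, Real-Time Collision
# Detection, region-based case analysis
closest_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + (d1 / (d1 - d3)) * ab)
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

#' Closest point on a mesh surface
#' @param mesh A [surface_mesh].
#' @param p Query point (3-vector).
#' @return List with `point` (3-vector on the surface), `distance`, and
#'   `face` (triangle index).
#' @export
closest_surface_point <- function(mesh, p) {
  stopifnot(inherits(mesh, "surface_mesh"))
  p <- as.numeric(p)
  best <- NULL; bestd <- Inf; bestf <- NA_integer_
  v <- mesh$vertices; f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    q <- closest_point_triangle(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])
    d <- vnorm(q - p)
    if (d < bestd) { bestd <- d; best <- q; bestf <- i }
  }
  list(point = best, distance = bestd, face = bestf)
}
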