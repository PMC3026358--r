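# tetrahedral mesh I/O: legacy ASCII VTK unstructured grids and Gmsh MSH
# v2.2 ASCII; results are written back as VTK with point displacements and
# cell von Mises scalars for external visualization

#' Read a tetrahedral mesh from legacy ASCII VTK or Gmsh MSH
#'
#' Supports VTK `DATASET UNSTRUCTURED_GRID` (cell type 10) and Gmsh MSH
#' v2.2 ASCII (element type 4); non-tet cells are ignored. Material,
#' constraints and loads are attached afterwards (they are not part of
#' either format).
#'
#' @param path Path to a `.vtk` or `.msh` file.
#' @param material A [material] to attach.
#' @return A [tet_mesh] without constraints or loads.
#' @export
read_tet_mesh <- function(path, material) {
  if (!file.exists(path))
    abort_rt(sprintf("mesh file not found: %s", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    vtk = read_vtk_tets(path, material),
    msh = read_msh_tets(path, material),
    abort_rt(sprintf("unsupported tet-mesh format '.%s' (VTK/MSH)", ext),
             "invalid_argument"))
}

read_vtk_tets <- function(path, material) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("UNSTRUCTURED_GRID", lines)))
    abort_rt("VTK file is not an unstructured grid", "parse_error")
  pi_ <- grep("^POINTS", lines)[1L]
  np <- as.integer(strsplit(trimws(lines[pi_]), "\\s+")[[1L]][2L])
  vals <- numeric(0); i <- pi_ + 1L
  while (length(vals) < 3L * np) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    i <- i + 1L
  }
  nodes <- matrix(vals[seq_len(3L * np)], ncol = 3L, byrow = TRUE)
  ci <- grep("^CELLS", lines)[1L]
  nc <- as.integer(strsplit(trimws(lines[ci]), "\\s+")[[1L]][2L])
  cells <- lapply(lines[ci + seq_len(nc)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1L]]))
  ti <- grep("^CELL_TYPES", lines)[1L]
  types <- as.integer(unlist(strsplit(trimws(
    lines[ti + seq_len(nc)]), "\\s+")))
  tets <- do.call(rbind, lapply(which(types == 10L), function(k)
    cells[[k]][2:5] + 1L))
  if (is.null(tets))
    abort_rt("VTK file contains no tetrahedral (type 10) cells",
             "parse_error")
  tet_mesh(nodes, tets, material)
}

read_msh_tets <- function(path, material) {
  lines <- readLines(path, warn = FALSE)
  nstart <- match("$Nodes", lines)
  estart <- match("$Elements", lines)
  if (is.na(nstart) || is.na(estart))
    abort_rt("MSH file is missing $Nodes or $Elements", "parse_error")
  nn <- as.integer(lines[nstart + 1L])
  ntok <- strsplit(trimws(lines[nstart + 1L + seq_len(nn)]), "\\s+")
  ids <- vapply(ntok, function(x) as.integer(x[1L]), integer(1))
  nodes <- do.call(rbind, lapply(ntok, function(x) as.numeric(x[2:4])))
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  ne <- as.integer(lines[estart + 1L])
  etok <- strsplit(trimws(lines[estart + 1L + seq_len(ne)]), "\\s+")
  tets <- do.call(rbind, lapply(etok, function(x) {
    x <- as.integer(x)
    if (x[2L] != 4L) return(NULL)
    ntags <- x[3L]
    remap[x[(4L + ntags):(7L + ntags)]]
  }))
  if (is.null(tets))
    abort_rt("MSH file contains no tetrahedral (type 4) elements",
             "parse_error")
  tet_mesh(nodes, tets, material)
}

#' Write a tet mesh (and optionally a result) as legacy ASCII VTK
#'
#' Point data: displacement vectors; cell data: von Mises scalars — the
#' fields an external viewer colors from blue (low) to red (high).
#'
#' @param mesh A [tet_mesh].
#' @param path Output path.
#' @param result Optional `"fem_result"` from [solve_static].
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, result = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  lines <- c(
    "# vtk DataFile Version 3.0",
    "rigidtrack static FEM output",
    "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", n),
    sprintf("%s %s %s", fmt6(mesh$nodes[, 1]), fmt6(mesh$nodes[, 2]),
            fmt6(mesh$nodes[, 3])),
    sprintf("CELLS %d %d", m, 5L * m),
    sprintf("4 %d %d %d %d", mesh$elements[, 1] - 1L,
            mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L,
            mesh$elements[, 4] - 1L),
    sprintf("CELL_TYPES %d", m),
    rep("10", m)
  )
  if (!is.null(result)) {
    lines <- c(lines,
      sprintf("POINT_DATA %d", n),
      "VECTORS displacement double",
      sprintf("%.9e %.9e %.9e", result$displacements[, 1],
              result$displacements[, 2], result$displacements[, 3]),
      sprintf("CELL_DATA %d", m),
      "SCALARS von_mises double 1",
      "LOOKUP_TABLE default",
      sprintf("%.9e", result$von_mises))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}
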