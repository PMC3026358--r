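#' Rigid tracking model
#'
#' The tracking model an optical motion-capture system needs before it can
#' track a rigid object: a single free root segment with six degrees of
#' freedom at the model origin, and a marker set whose coordinates are
#' expressed relative to that root.
#'
#' @param markers A [marker_set] in root-relative coordinates (mm).
#' @param root_name Name of the root segment, default `"root"`.
#' @param source_mesh Optional name of the surface mesh the markers were
#'   placed on.
#' @return Object of class `"tracking_model"`.
#' @export
tracking_model <- function(markers, root_name = "root", source_mesh = NULL) {
  stopifnot(inherits(markers, "marker_set"))
  structure(list(
    root = list(name = as.character(root_name), joint = "Free", dof = 6L),
    markers = markers,
    source_mesh = source_mesh,
    foreign = list()   # unknown elements preserved by lenient readers
  ), class = "tracking_model")
}

#' @export
print.tracking_model <- function(x, ...) {
  cat(sprintf("<tracking_model> root '%s' (%s joint, %d DOF)\n",
              x$root$name, x$root$joint, x$root$dof))
  print(x$markers)
  invisible(x)
}

#' Validate a tracking model for trackability
#'
#' Diagnostic check of the constraints a rigid tracking model must satisfy:
#' at least three markers, a non-collinear configuration, unique marker
#' names and a positive radius. Coplanar (but non-collinear) markers are
#' fine — collinearity is the only geometric degeneracy for rigid tracking.
#'
#' @param model A [tracking_model].
#' @return Character vector of violation messages; empty when the model is
#'   trackable.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "tracking_model"))
  v <- character(0)
  pos <- model$markers$positions
  if (nrow(pos) < 3L)
    v <- c(v, sprintf("insufficient markers (min 3, got %d)", nrow(pos)))
  if (anyDuplicated(rownames(pos)))
    v <- c(v, "duplicate marker names")
  if (nrow(pos) >= 3L && is_collinear(pos))
    v <- c(v, "collinear marker configuration")
  if (model$markers$radius <= 0)
    v <- c(v, "non-positive marker radius")
  if (!identical(model$root$joint, "Free") || model$root$dof != 6L)
    v <- c(v, "root segment must be a free joint with 6 degrees of freedom")
  v
}

# --- VSK dialect -----------------------------------------------------------
# <KinematicModel VERSION="1.0" UNITS="mm" [MESH="name"]>
#   <Parameters>
#     <Parameter NAME="<marker>_x" VALUE="%.6f"/> (then _y, _z)
#   </Parameters>
#   <Segments>
#     <Segment NAME="root" JOINT="Free" DOF="6"/>
#   </Segments>
#   <MarkerSet>
#     <Markers>
#       <Marker NAME="<marker>" SEGMENT="root"
#               POSITION="<marker>_x <marker>_y <marker>_z"/>
#     </Markers>
#     <Radius VALUE="%.6f"/>
#   </MarkerSet>
# </KinematicModel>
# Fixed 6-decimal numbers, LF line endings, strict element order, so
# write -> read -> write is byte-identical.

#' Write a tracking model as VSK XML
#'
#' Serializes the model in the package's documented VSK dialect: a
#' `Parameters` block naming every marker coordinate, one free 6-DOF root
#' `Segment`, a `MarkerSet` joining every marker to the root, and a `Radius`
#' element. Numbers use a fixed 6-decimal format and LF line endings so the
#' output is byte-reproducible.
#'
#' @param model A [tracking_model] with at least three markers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vsk <- function(model, path) {
  stopifnot(inherits(model, "tracking_model"))
  pos <- model$markers$positions
  if (nrow(pos) < 3L)
    abort_rt(sprintf(
      "model is not trackable: %d marker(s), minimum three markers required",
      nrow(pos)), "trackability_error")
  nm <- rownames(pos)
  mesh_attr <- if (!is.null(model$source_mesh))
    sprintf(" MESH=\"%s\"", model$source_mesh) else ""
  lines <- c(
    sprintf("<KinematicModel VERSION=\"1.0\" UNITS=\"mm\"%s>", mesh_attr),
    "  <Parameters>",
    as.vector(t(cbind(
      sprintf("    <Parameter NAME=\"%s_x\" VALUE=\"%s\"/>", nm, fmt6(pos[, 1])),
      sprintf("    <Parameter NAME=\"%s_y\" VALUE=\"%s\"/>", nm, fmt6(pos[, 2])),
      sprintf("    <Parameter NAME=\"%s_z\" VALUE=\"%s\"/>", nm, fmt6(pos[, 3]))
    ))),
    "  </Parameters>",
    "  <Segments>",
    sprintf("    <Segment NAME=\"%s\" JOINT=\"%s\" DOF=\"%d\"/>",
            model$root$name, model$root$joint, model$root$dof),
    "  </Segments>",
    "  <MarkerSet>",
    "    <Markers>",
    sprintf(
      "      <Marker NAME=\"%s\" SEGMENT=\"%s\" POSITION=\"%s_x %s_y %s_z\"/>",
      nm, model$root$name, nm, nm, nm),
    "    </Markers>",
    sprintf("    <Radius VALUE=\"%s\"/>", fmt6(model$markers$radius)),
    "  </MarkerSet>",
    "</KinematicModel>"
  )
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort_rt(
                    sprintf("cannot open '%s' for writing: %s", path,
                            conditionMessage(e)), "io_error"))
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Read a VSK tracking-model file
#'
#' Lenient reader for the documented VSK dialect (and close variants):
#' markers are taken in document order; `POSITION` tokens may reference
#' `Parameters` entries by name or be literal numbers; a missing `Radius`
#' element falls back to the documented default of 0.5 mm with a warning;
#' unknown elements are preserved (by name) in the model's `foreign` field
#' rather than rejected.
#'
#' @param path Path to a VSK XML file.
#' @return A [tracking_model].
#' @export
read_vsk <- function(path) {
  if (!file.exists(path))
    abort_rt(sprintf("VSK file not found: %s", path), "io_error")
  doc <- tryCatch(xml2::read_xml(path),
    error = function(e) abort_rt(sprintf(
      "VSK parse error in '%s' (%d bytes): %s",
      path, file.size(path), conditionMessage(e)), "vsk_parse_error"))
  root <- xml2::xml_root(doc)

  params <- xml2::xml_find_all(doc, ".//Parameter")
  pmap <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "VALUE")),
    xml2::xml_attr(params, "NAME"))

  mnodes <- xml2::xml_find_all(doc, ".//Marker")
  if (length(mnodes) == 0L)
    abort_rt(sprintf(
      "VSK schema error in '%s': no MarkerSet/Markers/Marker elements",
      path), "vsk_schema_error")
  nm <- xml2::xml_attr(mnodes, "NAME")
  seg_of <- xml2::xml_attr(mnodes, "SEGMENT")
  pos <- t(vapply(xml2::xml_attr(mnodes, "POSITION"), function(s) {
    tok <- strsplit(trimws(s), "\\s+")[[1L]]
    vapply(tok[1:3], function(t) {
      if (!is.na(pmap[t])) unname(pmap[t]) else as.numeric(t)
    }, numeric(1))
  }, numeric(3)))
  if (any(!is.finite(pos)))
    abort_rt(sprintf("VSK schema error in '%s': unresolved marker POSITION",
                     path), "vsk_schema_error")

  rnode <- xml2::xml_find_first(doc, ".//Segment")
  if (inherits(rnode, "xml_missing")) {
    root_seg <- list(name = unique(seg_of)[1L], joint = "Free", dof = 6L)
  } else {
    dof <- suppressWarnings(as.integer(xml2::xml_attr(rnode, "DOF")))
    root_seg <- list(name = xml2::xml_attr(rnode, "NAME"),
                     joint = xml2::xml_attr(rnode, "JOINT"),
                     dof = if (is.na(dof)) 6L else dof)
  }

  radnode <- xml2::xml_find_first(doc, ".//Radius")
  if (inherits(radnode, "xml_missing")) {
    warn_rt(sprintf(
      "'%s' has no Radius element; using the default marker radius 0.5 mm",
      path), "vsk_default_radius_warning")
    radius <- 0.5
  } else {
    radius <- as.numeric(xml2::xml_attr(radnode, "VALUE"))
  }

  known <- c("Parameters", "Parameter", "Segments", "Segment", "MarkerSet",
             "Markers", "Marker", "Radius")
  all_names <- xml2::xml_name(xml2::xml_find_all(doc, ".//*"))
  foreign <- setdiff(unique(all_names), known)

  model <- tracking_model(
    marker_set(unname(pos), names = nm, radius = radius),
    root_name = root_seg$name,
    source_mesh = {
      m <- xml2::xml_attr(root, "MESH")
      if (is.na(m)) NULL else m
    })
  model$root$joint <- root_seg$joint
  model$root$dof <- root_seg$dof
  model$foreign <- as.list(foreign)
  model
}
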