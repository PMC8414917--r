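# Geometry export: RSML 1.0, legacy-VTK polylines and a CSV segment table.

# Internal: per-axis polylines reconstructed from the segment buffer
# (segments of an axis are appended in growth order).
axis_polylines <- function(system) {
  sys <- system
  if (sys$nseg == 0) return(list())
  S <- sys$seg[seq_len(sys$nseg), , drop = FALSE]
  ax <- as.integer(S[, "axis"])
  lapply(seq_along(sys$axes), function(a) {
    rows <- which(ax == a)
    if (!length(rows)) return(NULL)
    rbind(S[rows[1], c("x0", "y0", "z0")],
          S[rows, c("x1", "y1", "z1"), drop = FALSE])
  })
}

#' Export a root system as RSML 1.0
#'
#' Writes a Root System Markup Language document: scene -> plant -> root
#' hierarchy with polyline geometry, root class and diameter as
#' annotations, and laterals nested under their parent axis.
#'
#' @param system a `root_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rsml <- function(system, path) {
  sys <- system
  polys <- axis_polylines(sys)
  doc <- xml2::xml_new_root("rsml", version = "1.0")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "cm")
  xml2::xml_add_child(meta, "resolution", "1")
  xml2::xml_add_child(meta, "software", "rhizoseed")
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant", id = "1")
  add_root <- function(parent_node, a) {
    poly <- polys[[a]]
    if (is.null(poly)) return(invisible())
    cls <- ROOT_CLASSES[sys$axis_class[a]]
    root <- xml2::xml_add_child(parent_node, "root", id = as.character(a),
                                label = cls)
    props <- xml2::xml_add_child(root, "properties")
    xml2::xml_add_child(props, "rootClass", cls)
    geom <- xml2::xml_add_child(root, "geometry")
    pl <- xml2::xml_add_child(geom, "polyline")
    for (i in seq_len(nrow(poly)))
      xml2::xml_add_child(pl, "point",
                          x = sprintf("%.6g", poly[i, 1]),
                          y = sprintf("%.6g", poly[i, 2]),
                          z = sprintf("%.6g", poly[i, 3]))
    kids <- which(sys$axis_parent == a)
    for (k in kids) add_root(root, k)
    invisible()
  }
  top <- which(sys$axis_parent == 0L)
  for (a in top) add_root(plant, a)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a root system as legacy-VTK polylines
#'
#' ASCII legacy VTK (`POLYDATA` with `LINES`), with the root class code as
#' a cell scalar, for quick visual inspection.
#'
#' @param system a `root_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(system, path) {
  polys <- axis_polylines(system)
  polys <- polys[!vapply(polys, is.null, TRUE)]
  keep_class <- system$axis_class[!vapply(axis_polylines(system), is.null, TRUE)]
  npts <- vapply(polys, nrow, 0L)
  all_pts <- do.call(rbind, polys)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "root system", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(all_pts))), con)
  utils::write.table(round(all_pts, 5), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("LINES %d %d", length(polys),
                     length(polys) + sum(npts)), con)
  off <- 0L
  for (i in seq_along(polys)) {
    writeLines(paste(c(npts[i], off + seq_len(npts[i]) - 1L),
                     collapse = " "), con)
    off <- off + npts[i]
  }
  writeLines(c(sprintf("CELL_DATA %d", length(polys)),
               "SCALARS root_class int 1", "LOOKUP_TABLE default",
               paste(keep_class, collapse = " ")), con)
  invisible(path)
}

#' Write the per-segment CSV table
#'
#' @param system a `root_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(system, path) {
  utils::write.csv(segment_table(system), path, row.names = FALSE)
  invisible(path)
}
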