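#' Write a mesh (and optional fields) as legacy ASCII VTK
#'
#' Plain-text legacy VTK: unstructured grid of triangles, with nodal
#' fields as point data and element fields (including the boundary-unaware
#' strain energy) as cell data. Readable by ParaView and meshio.
#'
#' @param mesh a `scar_mesh`.
#' @param path output file path (conventionally `.vtk`).
#' @param point_data named list of length-n nodal vectors.
#' @param cell_data named list of length-m element vectors.
#' @param current write the current (deformed) coordinates.
#' @return the path, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list(),
                      current = TRUE) {
  coords <- if (current) mesh$cur else mesh$X
  n <- nrow(coords); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("dermal slice")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", n, " double")
  writeLines(paste(coords[, 1], coords[, 2], 0), con)
  wl("CELLS ", m, " ", 4L * m)
  writeLines(paste(3L, mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                   mesh$tri[, 3] - 1L), con)
  wl("CELL_TYPES ", m)
  writeLines(rep("5", m), con)
  if (length(point_data)) {
    wl("POINT_DATA ", n)
    for (nm in names(point_data)) {
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(format(point_data[[nm]], digits = 12), con)
    }
  }
  if (length(cell_data)) {
    wl("CELL_DATA ", m)
    for (nm in names(cell_data)) {
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(format(cell_data[[nm]], digits = 12), con)
    }
  }
  invisible(path)
}
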