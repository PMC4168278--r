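# Minimal VTK XML unstructured-grid (.vtu) export, ASCII appended-free
# format: nodes, tets, optional per-node and per-cell scalar arrays.
# Written in-package because no installed R package provides VTU output.

#' Export a mesh (with fields) to VTK XML unstructured-grid format
#'
#' Writes an ASCII `.vtu` file readable by ParaView/VTK with the tetrahedra
#' as cells and any supplied nodal (`point_data`) or per-element
#' (`cell_data`) scalar arrays.
#'
#' @param path output file path.
#' @param mesh a `labeled_tet_mesh`.
#' @param point_data named list of numeric vectors (one value per node).
#' @param cell_data named list of numeric vectors (one value per element).
#' @return invisibly, `path`.
#' @export
write_vtu <- function(path, mesh, point_data = list(), cell_data = list()) {
  np <- nrow(mesh$nodes); nc <- nrow(mesh$tets)
  for (nm in names(point_data)) stopifnot(length(point_data[[nm]]) == np)
  for (nm in names(cell_data)) stopifnot(length(cell_data[[nm]]) == nc)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  arr <- function(name, x, ncomp = 1) {
    w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              name, ncomp))
    writeLines(paste(format(x, digits = 12, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
    w("        </DataArray>")
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w("  <UnstructuredGrid>")
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', np, nc))
  w("      <Points>")
  arr("Points", as.vector(t(mesh$nodes)), ncomp = 3)
  w("      </Points>")
  w("      <Cells>")
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(paste(as.vector(t(mesh$tets)) - 1L, collapse = " "), con)
  w("        </DataArray>")
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(nc) * 4L, collapse = " "), con)
  w("        </DataArray>")
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(10L, nc), collapse = " "), con)
  w("        </DataArray>")
  w("      </Cells>")
  if (length(point_data)) {
    w("      <PointData>")
    for (nm in names(point_data)) arr(nm, point_data[[nm]])
    w("      </PointData>")
  }
  if (length(cell_data)) {
    w("      <CellData>")
    for (nm in names(cell_data)) arr(nm, cell_data[[nm]])
    w("      </CellData>")
  }
  w("    </Piece>")
  w("  </UnstructuredGrid>")
  w("</VTKFile>")
  invisible(path)
}
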