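# Legacy-VTK (ASCII) export of the generated meshes, with region labels and
# fiber vectors as cell data; readable by ParaView and meshio.

#' Write a mesh to a legacy VTK (ASCII) file
#'
#' Tetrahedral meshes (`bv_mesh`) carry cell data `region_id`, `depth` and
#' the fiber vector field; membrane meshes (`vessel_mesh`) carry
#' `region_id` and the local frame vectors.
#'
#' @param mesh A `bv_mesh` or `vessel_mesh`.
#' @param path Output file path (`.vtk`).
#' @param u Optional displacement to add to the coordinates.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, u = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  x <- mesh$nodes
  if (!is.null(u)) x <- x + .as_disp_matrix(u)[seq_len(nrow(x)), , drop = FALSE]
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("vacoupler mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", nrow(x))
  writeLines(apply(x, 1, function(r) paste(format(r, digits = 10),
                                           collapse = " ")), con)
  is_tet <- inherits(mesh, "bv_mesh")
  cells <- if (is_tet) mesh$tets else mesh$tris
  k <- ncol(cells)
  w("CELLS %d %d", nrow(cells), nrow(cells) * (k + 1))
  writeLines(apply(cells - 1L, 1, function(r)
    paste(c(k, r), collapse = " ")), con)
  w("CELL_TYPES %d", nrow(cells))
  writeLines(rep(if (is_tet) "10" else "5", nrow(cells)), con)
  w("CELL_DATA %d", nrow(cells))
  region_id <- as.integer(factor(mesh$region))
  w("SCALARS region_id int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(region_id), con)
  if (is_tet) {
    w("SCALARS depth double 1")
    w("LOOKUP_TABLE default")
    writeLines(format(mesh$depth, digits = 6), con)
    if (!is.null(mesh$fibers)) {
      w("VECTORS fiber double")
      writeLines(apply(mesh$fibers$f, 1, function(r)
        paste(format(r, digits = 6), collapse = " ")), con)
    }
  } else {
    w("VECTORS longitudinal double")
    writeLines(apply(mesh$frames$e_l, 1, function(r)
      paste(format(r, digits = 6), collapse = " ")), con)
  }
  invisible(path)
}

#' Write waveforms of a simulation record as CSV
#'
#' Columns: `time_ms`, then the named variables in internal units (ml, Pa,
#' ml/ms, mm).
#'
#' @param record A `simulation_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveforms_csv <- function(record, path) {
  utils::write.csv(tibble::as_tibble(record), path, row.names = FALSE)
  invisible(path)
}
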