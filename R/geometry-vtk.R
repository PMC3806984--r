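#' Export / import an ear mesh as legacy ASCII VTK
#'
#' Writes the mesh as a legacy ASCII VTK unstructured grid (triangles as
#' cell type 5, tetrahedra as type 10) with two cell-data arrays:
#' `region_id` (integer) and `thickness_mm` (shell thickness; 0 for
#' solids). The region-id-to-label table and the coordinate convention
#' are appended as `#`-prefixed trailer lines after the VTK payload,
#' which VTK readers ignore but [read_mesh_vtk()] uses to restore the
#' labels. Connectivity round-trips bit-identically.
#'
#' @param mesh An `ear_mesh`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    abort(paste0("cannot open path for writing: ", path))
  })
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  regions <- sort(unique(c(mesh$shell$region, mesh$solid$region)))
  rid <- function(r) match(r, regions)

  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("otomech middle-ear mesh; mm; annulus in z=0 plane, umbo apex at -z")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w(sprintf("POINTS %d double", n))
  writeLines(apply(mesh$nodes, 1, function(p)
    paste(sprintf("%.17g", p), collapse = " ")), con)

  ns <- nrow(mesh$shell); nt <- nrow(mesh$solid)
  w(sprintf("CELLS %d %d", ns + nt, 4 * ns + 5 * nt))
  writeLines(sprintf("3 %d %d %d", mesh$shell$n1 - 1L, mesh$shell$n2 - 1L,
                     mesh$shell$n3 - 1L), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$solid$n1 - 1L, mesh$solid$n2 - 1L,
                     mesh$solid$n3 - 1L, mesh$solid$n4 - 1L), con)
  w(sprintf("CELL_TYPES %d", ns + nt))
  writeLines(c(rep("5", ns), rep("10", nt)), con)

  w(sprintf("CELL_DATA %d", ns + nt))
  w("SCALARS region_id int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(c(rid(mesh$shell$region), rid(mesh$solid$region))),
             con)
  w("SCALARS thickness_mm double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.17g", c(mesh$shell$thickness_mm, rep(0, nt))), con)

  for (i in seq_along(regions)) w(sprintf("# otomech-region %d %s", i,
                                          regions[i]))
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @return `read_mesh_vtk()`: a list with `nodes`, `shell`, `solid`
#'   tables (region labels and shell thickness restored). Tags and
#'   connectors are not part of the VTK payload.
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  stopifnot(grepl("^# vtk DataFile", lines[1]))
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(lines[ip + seq_len(n)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))

  ic <- grep("^CELLS", lines)[1]
  ncell <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- lapply(lines[ic + seq_len(ncell)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  it <- grep("^CELL_TYPES", lines)[1]
  types <- as.integer(lines[it + seq_len(ncell)])

  ir <- grep("^SCALARS region_id", lines)[1]
  rids <- as.integer(lines[ir + 1L + seq_len(ncell)])
  ith <- grep("^SCALARS thickness_mm", lines)[1]
  thick <- as.numeric(lines[ith + 1L + seq_len(ncell)])

  reg_lines <- grep("^# otomech-region ", lines, value = TRUE)
  reg_map <- vapply(strsplit(reg_lines, " "), function(x)
    paste(x[4:length(x)], collapse = " "), character(1))

  tri <- which(types == 5L); tet <- which(types == 10L)
  shell <- tibble(
    n1 = vapply(cells[tri], function(x) x[2] + 1L, integer(1)),
    n2 = vapply(cells[tri], function(x) x[3] + 1L, integer(1)),
    n3 = vapply(cells[tri], function(x) x[4] + 1L, integer(1)),
    region = reg_map[rids[tri]],
    thickness_mm = thick[tri]
  )
  solid <- tibble(
    n1 = vapply(cells[tet], function(x) x[2] + 1L, integer(1)),
    n2 = vapply(cells[tet], function(x) x[3] + 1L, integer(1)),
    n3 = vapply(cells[tet], function(x) x[4] + 1L, integer(1)),
    n4 = vapply(cells[tet], function(x) x[5] + 1L, integer(1)),
    region = reg_map[rids[tet]]
  )
  list(nodes = pts, shell = shell, solid = solid)
}
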