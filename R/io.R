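# Mesh and field interchange: Gmsh MSH 2.2 (ASCII) with named physical
# groups, and ASCII XML VTU (+ PVD time series index) for visualization.

label_ids <- c(moving_wall = 1L, rigid_wall = 2L, outlet = 3L)

#' Write a labeled mesh in Gmsh MSH 2.2 ASCII format
#'
#' Boundary triangles carry physical groups `moving_wall` / `rigid_wall` /
#' `outlet`; tetrahedra carry the `fluid` group.
#'
#' @param mesh a `csf_mesh`.
#' @param file output path (conventionally `.msh`).
#' @return `file`, invisibly.
#' @export
write_mesh_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", "4",
               "2 1 \"moving_wall\"", "2 2 \"rigid_wall\"",
               "2 3 \"outlet\"", "3 4 \"fluid\"",
               "$EndPhysicalNames"), con)
  n <- nrow(mesh$nodes)
  writeLines(c("$Nodes", as.character(n)), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(n),
                     mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]), con)
  writeLines("$EndNodes", con)
  nt <- nrow(mesh$tris)
  ne <- nrow(mesh$tets)
  writeLines(c("$Elements", as.character(nt + ne)), con)
  lid <- label_ids[mesh$labels]
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(nt), lid, lid,
                     mesh$tris[, 1L], mesh$tris[, 2L], mesh$tris[, 3L]), con)
  writeLines(sprintf("%d 4 2 4 4 %d %d %d %d", nt + seq_len(ne),
                     mesh$tets[, 1L], mesh$tets[, 2L], mesh$tets[, 3L],
                     mesh$tets[, 4L]), con)
  writeLines("$EndElements", con)
  invisible(file)
}

#' Read a labeled mesh from Gmsh MSH 2.2 ASCII
#'
#' Reads meshes written by [write_mesh_msh()] (or any MSH 2.2 file with
#' triangle physical tags 1-3 and first-order tetrahedra).
#'
#' @param file path to the `.msh` file.
#' @return a `csf_mesh` (geometry metadata fields such as the aqueduct
#'   extent are absent unless re-attached by the caller).
#' @export
read_mesh_msh <- function(file) {
  lines <- readLines(file)
  sect <- function(tag) {
    i0 <- which(lines == paste0("$", tag)) + 1L
    i1 <- which(lines == paste0("$End", tag)) - 1L
    if (!length(i0) || !length(i1)) stop(sprintf("missing $%s section", tag))
    lines[i0:i1]
  }
  nl <- sect("Nodes")
  nn <- as.integer(nl[1L])
  nd <- matrix(scan(text = nl[1L + seq_len(nn)], quiet = TRUE),
               ncol = 4L, byrow = TRUE)
  nodes <- nd[order(nd[, 1L]), 2:4, drop = FALSE]
  el <- sect("Elements")
  nel <- as.integer(el[1L])
  tris <- matrix(0L, 0L, 3L); labs <- integer(0)
  tets <- matrix(0L, 0L, 4L)
  for (ln in el[1L + seq_len(nel)]) {
    v <- as.integer(strsplit(trimws(ln), "\\s+")[[1L]])
    etype <- v[2L]; ntags <- v[3L]
    conn <- v[-(seq_len(3L + ntags))]
    if (etype == 2L) {
      tris <- rbind(tris, conn)
      labs <- c(labs, if (ntags >= 1L) v[4L] else 2L)
    } else if (etype == 4L) {
      tets <- rbind(tets, conn)
    }
  }
  labels <- names(label_ids)[match(labs, label_ids)]
  labels[is.na(labels)] <- "rigid_wall"
  structure(list(nodes = nodes, tets = tets, tris = tris, labels = labels,
                 base_size = NA_real_, d = NA_real_, aqueduct_z = NULL,
                 length = max(nodes[, 3L]) - min(nodes[, 3L]), kind = "imported",
                 cache = new.env(parent = emptyenv())),
            class = "csf_mesh")
}

#' Write a mesh (with optional nodal data) as ASCII XML VTU
#'
#' @param mesh a `csf_mesh`.
#' @param file output path (`.vtu`).
#' @param point_data named list of nodal scalars (length n) or vectors
#'   (n x 3 matrices).
#' @return `file`, invisibly.
#' @export
write_vtu <- function(mesh, file, point_data = list()) {
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$tets)
  num <- function(x) paste(formatC(as.vector(x), format = "g", digits = 9),
                           collapse = " ")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    "<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" byte_order=\"LittleEndian\">",
    "  <UnstructuredGrid>",
    sprintf("    <Piece NumberOfPoints=\"%d\" NumberOfCells=\"%d\">", n, ne),
    "      <Points>",
    "        <DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">",
    num(t(mesh$nodes)),
    "        </DataArray>", "      </Points>"), con)
  if (length(point_data)) {
    writeLines("      <PointData>", con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      writeLines(sprintf("        <DataArray type=\"Float64\" Name=\"%s\" NumberOfComponents=\"%d\" format=\"ascii\">",
                         nm, nc), con)
      writeLines(num(if (is.matrix(v)) t(v) else v), con)
      writeLines("        </DataArray>", con)
    }
    writeLines("      </PointData>", con)
  }
  writeLines(c(
    "      <Cells>",
    "        <DataArray type=\"Int32\" Name=\"connectivity\" format=\"ascii\">",
    paste(as.vector(t(mesh$tets)) - 1L, collapse = " "),
    "        </DataArray>",
    "        <DataArray type=\"Int32\" Name=\"offsets\" format=\"ascii\">",
    paste(seq_len(ne) * 4L, collapse = " "),
    "        </DataArray>",
    "        <DataArray type=\"UInt8\" Name=\"types\" format=\"ascii\">",
    paste(rep(10L, ne), collapse = " "),
    "        </DataArray>", "      </Cells>",
    "    </Piece>", "  </UnstructuredGrid>", "</VTKFile>"), con)
  invisible(file)
}

#' Export a phase-resolved velocity field as a VTU series with PVD index
#'
#' One `.vtu` per stored phase (velocity and, when stored, pressure as nodal
#' data) plus a `.pvd` time index.
#'
#' @param field a `velocity_field`.
#' @param dir output directory.
#' @param basename file name stem.
#' @return the `.pvd` path, invisibly.
#' @export
write_field_series <- function(field, dir, basename = "field") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  P <- dim(field$u)[3L]
  files <- character(P)
  for (p in seq_len(P)) {
    pd <- list(velocity = field$u[, , p])
    if (!is.null(field$p)) pd$pressure <- field$p[, p]
    files[p] <- sprintf("%s_%03d.vtu", basename, p)
    write_vtu(field$mesh, file.path(dir, files[p]), pd)
  }
  pvd <- file.path(dir, paste0(basename, ".pvd"))
  con <- file(pvd, "w")
  writeLines(c("<?xml version=\"1.0\"?>",
               "<VTKFile type=\"Collection\" version=\"0.1\">",
               "  <Collection>",
               sprintf("    <DataSet timestep=\"%.6g\" file=\"%s\"/>",
                       field$times, files),
               "  </Collection>", "</VTKFile>"), con)
  close(con)
  invisible(pvd)
}
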