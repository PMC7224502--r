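# Tetrahedral mesh I/O: GMSH file format version 2.2 (ASCII) and VTU
# (ASCII XML UnstructuredGrid). GMSH physical volume tags carry cell
# labels; physical surface tags carry patch ids (with names in
# $PhysicalNames). VTU carries cells, labels and optional cell fields but
# no patches.

#' Read / write tetrahedral meshes
#'
#' GMSH v2.2 round-trips preserve points, cells, cell labels and patch
#' names; VTU preserves points, cells, labels and any numeric cell fields
#' passed via `fields`. Reading a GMSH file of a newer format version
#' raises an explicit unsupported-version error.
#'
#' @param mesh a [tet_mesh()].
#' @param path file path.
#' @param format `"gmsh2"` or `"vtu"`; default inferred from the extension
#'   (`.msh` / `.vtu`).
#' @param fields optional named list of per-cell numeric vectors (or 3-column
#'   matrices) written as VTU cell data.
#' @return `read_mesh()` returns a [tet_mesh()]; `write_mesh()` returns
#'   `path` invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, fields = list()) {
  format <- infer_mesh_format(path, format)
  switch(format,
         gmsh2 = write_gmsh2(mesh, path),
         vtu = write_vtu(mesh, path, fields))
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = NULL) {
  format <- infer_mesh_format(path, format)
  switch(format, gmsh2 = read_gmsh2(path), vtu = read_vtu(path))
}

infer_mesh_format <- function(path, format) {
  if (!is.null(format)) {
    if (!format %in% c("gmsh2", "vtu")) stop("unknown mesh format: ", format)
    return(format)
  }
  if (grepl("\\.msh$", path)) "gmsh2"
  else if (grepl("\\.vtu$", path)) "vtu"
  else stop("cannot infer mesh format from extension: ", path)
}

write_gmsh2 <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  pn <- names(mesh$patches)
  writeLines("$PhysicalNames", con)
  vols <- sort(unique(mesh$cell_labels))
  writeLines(as.character(length(pn) + length(vols)), con)
  if (length(pn))
    writeLines(sprintf("2 %d \"%s\"", seq_along(pn), pn), con)
  writeLines(sprintf("3 %d \"volume_%d\"", vols, vols), con)
  writeLines("$EndPhysicalNames", con)
  writeLines("$Nodes", con)
  writeLines(as.character(nrow(mesh$points)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$points)),
                     mesh$points[, 1], mesh$points[, 2], mesh$points[, 3]), con)
  writeLines("$EndNodes", con)
  nf <- if (length(pn)) sum(vapply(mesh$patches, function(p) nrow(p$faces), 1L)) else 0L
  writeLines("$Elements", con)
  writeLines(as.character(nf + nrow(mesh$cells)), con)
  eid <- 1L
  for (k in seq_along(mesh$patches)) {
    f <- mesh$patches[[k]]$faces
    if (nrow(f)) {
      writeLines(sprintf("%d 2 2 %d %d %d %d %d",
                         seq.int(eid, length.out = nrow(f)), k, k,
                         f[, 1], f[, 2], f[, 3]), con)
      eid <- eid + nrow(f)
    }
  }
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d",
                     seq.int(eid, length.out = nrow(mesh$cells)),
                     mesh$cell_labels, mesh$cell_labels,
                     mesh$cells[, 1], mesh$cells[, 2], mesh$cells[, 3],
                     mesh$cells[, 4]), con)
  writeLines("$EndElements", con)
}

read_gmsh2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1))
      stop(sprintf("parse error: section $%s missing (near line %s)", name,
                   ifelse(is.na(i0), "?", i0)))
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- scan(text = sect("MeshFormat")[1], quiet = TRUE)
  if (fmt[1] >= 3)
    stop(sprintf("unsupported GMSH format version %s (only 2.x is supported)", fmt[1]))
  nodes <- sect("Nodes")
  nn <- as.integer(nodes[1])
  nd <- matrix(scan(text = paste(nodes[-1], collapse = "\n"), quiet = TRUE),
               ncol = 4L, byrow = TRUE)
  pts <- nd[order(nd[, 1]), 2:4, drop = FALSE]
  phys_names <- character(0)
  if (any(lines == "$PhysicalNames")) {
    ph <- sect("PhysicalNames")[-1]
    m <- regmatches(ph, regexec('^(\\d+) (\\d+) "(.*)"$', ph))
    for (g in m) if (length(g) == 4 && g[2] == "2")
      phys_names[as.integer(g[3])] <- g[4]
  }
  el <- sect("Elements")[-1]
  first <- matrix(scan(text = paste(vapply(strsplit(el, " "),
                                           function(x) paste(x[1:3], collapse = " "), ""),
                                    collapse = "\n"), quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
  types <- first[, 2]
  tet_lines <- el[types == 4]
  tri_lines <- el[types == 2]
  if (!length(tet_lines)) stop("parse error: no tetrahedral elements found")
  td <- matrix(scan(text = paste(tet_lines, collapse = "\n"), quiet = TRUE),
               ncol = 9L, byrow = TRUE)   # id type ntags t1 t2 v1..v4
  cells <- td[, 6:9, drop = FALSE]
  labels <- as.integer(td[, 4])
  patches <- list()
  if (length(tri_lines)) {
    fd <- matrix(scan(text = paste(tri_lines, collapse = "\n"), quiet = TRUE),
                 ncol = 8L, byrow = TRUE)
    mesh0 <- tet_mesh(pts, cells, labels)
    faces <- mesh_faces(mesh0)
    key_all <- face_keys(sorted_triples(faces$verts), nrow(pts))
    for (tag in sort(unique(fd[, 4]))) {
      f <- fd[fd[, 4] == tag, 6:8, drop = FALSE]
      storage.mode(f) <- "integer"
      nm <- if (!is.na(phys_names[tag])) phys_names[tag] else paste0("patch_", tag)
      idx <- match(face_keys(sorted_triples(f), nrow(pts)), key_all)
      type <- if (all(faces$internal[idx], na.rm = TRUE)) "interface" else "boundary"
      patches[[nm]] <- list(faces = f, type = type)
    }
  }
  tet_mesh(pts, cells, labels, patches)
}

write_vtu <- function(mesh, path, fields = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$points); m <- nrow(mesh$cells)
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(sprintf("%.17g %.17g %.17g", mesh$points[, 1], mesh$points[, 2],
                     mesh$points[, 3]), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(sprintf("%d %d %d %d", mesh$cells[, 1] - 1L, mesh$cells[, 2] - 1L,
                     mesh$cells[, 3] - 1L, mesh$cells[, 4] - 1L), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(m) * 4L), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", m), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <CellData>')
  w('        <DataArray type="Int32" Name="label" format="ascii">')
  writeLines(as.character(mesh$cell_labels), con)
  w('        </DataArray>')
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (is.matrix(v)) {
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, ncol(v))
      writeLines(apply(v, 1L, paste, collapse = " "), con)
    } else {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(sprintf("%.17g", v), con)
    }
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
}

read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  get_arr <- function(xpath) {
    node <- xml2::xml_find_first(piece, xpath)
    if (inherits(node, "xml_missing")) stop("parse error: missing ", xpath)
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pts <- matrix(get_arr(".//Points/DataArray"), ncol = 3L, byrow = TRUE)
  conn <- get_arr(".//Cells/DataArray[@Name='connectivity']")
  types <- get_arr(".//Cells/DataArray[@Name='types']")
  if (any(types != 10)) stop("parse error: VTU contains non-tetrahedral cells")
  cells <- matrix(conn + 1L, ncol = 4L, byrow = TRUE)
  labnode <- xml2::xml_find_first(piece, ".//CellData/DataArray[@Name='label']")
  labels <- if (!inherits(labnode, "xml_missing"))
    as.integer(scan(text = xml2::xml_text(labnode), quiet = TRUE))
  else rep(1L, nrow(cells))
  tet_mesh(pts, cells, labels)
}
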