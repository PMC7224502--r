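# Image-based meshing: each retained voxel is split into 6 tetrahedra
# around the voxel's main diagonal. A uniform diagonal direction makes all
# shared faces conform automatically.

# corner coding within a voxel, binary (x, y, z) offsets
.cube_corners <- rbind(
  c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L),
  c(0L, 0L, 1L), c(1L, 0L, 1L), c(0L, 1L, 1L), c(1L, 1L, 1L))

# 6-tet decomposition around the main diagonal corner1 -> corner8
.cube_tets <- rbind(
  c(1L, 2L, 4L, 8L), c(1L, 4L, 3L, 8L), c(1L, 3L, 7L, 8L),
  c(1L, 7L, 5L, 8L), c(1L, 5L, 6L, 8L), c(1L, 6L, 2L, 8L))

#' Tetrahedralize a labeled image
#'
#' Converts every retained voxel (label not in `exclude_labels`) into six
#' tetrahedra; cell labels inherit voxel labels and the exterior surface of
#' the retained region becomes the boundary patch `"boundary"`.
#'
#' Voxel corners are placed half a voxel from the voxel centers, so the
#' mesh of voxel (i, j, k) spans `origin + (index -/+ 0.5) * spacing`.
#'
#' @param image a [labeled_image()].
#' @param exclude_labels labels to drop (default background 0).
#' @return A [tet_mesh()].
#' @export
tetrahedralize_labeled_image <- function(image, exclude_labels = 0L) {
  dims <- dim(image$labels)
  keep <- which(!(image$labels %in% exclude_labels))
  if (!length(keep)) stop("no voxels retained after exclusion")
  ijk <- arrayInd(keep, dims) - 1L                      # 0-based voxel index
  nxc <- dims[1] + 1L; nyc <- dims[2] + 1L
  cid <- function(i, j, k) i + nxc * (j + nyc * k) + 1  # corner grid id
  nvox <- nrow(ijk)
  corner_ids <- matrix(0, nvox, 8L)
  for (c8 in 1:8)
    corner_ids[, c8] <- cid(ijk[, 1] + .cube_corners[c8, 1],
                            ijk[, 2] + .cube_corners[c8, 2],
                            ijk[, 3] + .cube_corners[c8, 3])
  cells <- matrix(0, 6L * nvox, 4L)
  for (t6 in 1:6) {
    rows <- seq.int(t6, by = 6L, length.out = nvox)
    cells[rows, ] <- corner_ids[, .cube_tets[t6, ], drop = FALSE]
  }
  labels <- rep(as.integer(image$labels[keep]), each = 6L)
  used <- sort(unique(as.vector(cells)))
  remap <- rep(NA_integer_, nxc * nyc * (dims[3] + 1L))
  remap[used] <- seq_along(used)
  cells <- matrix(remap[cells], ncol = 4L)
  u0 <- used - 1
  ci <- u0 %% nxc; cj <- (u0 %/% nxc) %% nyc; ck <- u0 %/% (nxc * nyc)
  pts <- cbind(image$origin[1] + (ci - 0.5) * image$spacing[1],
               image$origin[2] + (cj - 0.5) * image$spacing[2],
               image$origin[3] + (ck - 0.5) * image$spacing[3])
  mesh <- tet_mesh(pts, cells, labels)
  recompute_patches(mesh)
}

#' Recompute patches from cell labels
#'
#' Rebuilds the patch structure of a mesh: all exterior faces form the
#' boundary patch `"boundary"` and, for every pair of compartment labels in
#' contact, the internal faces separating them form an interface patch
#' `"interface_<a>_<b>"` (a < b).
#'
#' @param mesh a [tet_mesh()].
#' @param faces optional precomputed [mesh_faces()] structure.
#' @return The mesh with replaced `patches`.
#' @export
recompute_patches <- function(mesh, faces = NULL) {
  if (is.null(faces)) faces <- mesh_faces(mesh)
  patches <- list(boundary = list(faces = faces$verts[!faces$internal, ,
                                                      drop = FALSE],
                                  type = "boundary"))
  int <- which(faces$internal)
  la <- mesh$cell_labels[faces$owner[int]]
  lb <- mesh$cell_labels[faces$neighbour[int]]
  diff_ <- la != lb
  if (any(diff_)) {
    lo <- pmin(la, lb)[diff_]; hi <- pmax(la, lb)[diff_]
    iface <- int[diff_]
    for (key in unique(paste(lo, hi, sep = "_"))) {
      sel <- iface[paste(lo, hi, sep = "_") == key]
      patches[[paste0("interface_", key)]] <-
        list(faces = faces$verts[sel, , drop = FALSE], type = "interface")
    }
  }
  mesh$patches <- patches
  mesh
}

#' Name a boundary patch by a geometric predicate
#'
#' Selects exterior faces whose centroids satisfy `predicate` and collects
#' them into a new boundary patch, leaving other patches untouched (faces
#' are removed from the `"boundary"` patch if present there).
#'
#' @param mesh a [tet_mesh()].
#' @param name new patch name.
#' @param predicate function taking a k x 3 matrix of face centroids and
#'   returning a logical vector.
#' @return The mesh with the added patch.
#' @export
define_patch <- function(mesh, name, predicate) {
  faces <- mesh_faces(mesh)
  bidx <- which(!faces$internal)
  sel <- predicate(faces$centroid[bidx, , drop = FALSE])
  if (!any(sel)) stop("predicate selects no boundary faces")
  fv <- faces$verts[bidx[sel], , drop = FALSE]
  if (!is.null(mesh$patches$boundary)) {
    npts <- nrow(mesh$points)
    kb <- face_keys(sorted_triples(mesh$patches$boundary$faces), npts)
    ks <- face_keys(sorted_triples(fv), npts)
    mesh$patches$boundary$faces <-
      mesh$patches$boundary$faces[!(kb %in% ks), , drop = FALSE]
  }
  mesh$patches[[name]] <- list(faces = fv, type = "boundary")
  mesh
}
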