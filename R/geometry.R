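# Vectorized geometric primitives shared by the meshing, classification and
# solver code. All coordinates are in mm unless stated otherwise.

# row-wise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(m) sqrt(rowSums(m * m))

# signed volumes of tetrahedra (mm^3)
tet_signed_volumes <- function(points, cells) {
  a <- points[cells[, 1], , drop = FALSE]
  b <- points[cells[, 2], , drop = FALSE] - a
  c_ <- points[cells[, 3], , drop = FALSE] - a
  d <- points[cells[, 4], , drop = FALSE] - a
  rowSums(b * cross3(c_, d)) / 6
}

#' Cell centroids and volumes
#'
#' @param mesh a [tet_mesh()].
#' @return `cell_centroids()`: m x 3 matrix of centroids (mm);
#'   `cell_volumes()`: numeric vector of (positive) cell volumes in mm^3.
#' @export
cell_centroids <- function(mesh) {
  (mesh$points[mesh$cells[, 1], , drop = FALSE] +
   mesh$points[mesh$cells[, 2], , drop = FALSE] +
   mesh$points[mesh$cells[, 3], , drop = FALSE] +
   mesh$points[mesh$cells[, 4], , drop = FALSE]) / 4
}

#' @rdname cell_centroids
#' @export
cell_volumes <- function(mesh) {
  abs(tet_signed_volumes(mesh$points, mesh$cells))
}

# Canonical (sorted) face key columns for matching faces between structures.
sorted_triples <- function(f) {
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  cbind(lo, mid, hi)
}

# Single numeric key per face; safe for meshes with < 2^17 points (keys stay
# below 2^53). Errors out otherwise rather than silently colliding.
face_keys <- function(st, npts) {
  if (npts >= 131072) stop("face keying limited to meshes with < 131072 points")
  (as.numeric(st[, 1]) * npts + st[, 2]) * npts + st[, 3]
}

#' Face connectivity of a tetrahedral mesh
#'
#' Enumerates every distinct triangular face once, with its owner cell (and
#' neighbour cell for internal faces), outward-of-owner orientation, area
#' vector and centroid. The owner of an internal face is the lower-numbered
#' cell; boundary faces keep their single cell as owner.
#'
#' @param mesh a [tet_mesh()].
#' @return A list with `verts` (F x 3 vertex triples, oriented outward from
#'   the owner), `owner`, `neighbour` (`NA` for boundary faces), `area_vec`
#'   (F x 3, mm^2, pointing owner -> neighbour / outward), `centroid`
#'   (F x 3, mm), and `internal` (logical).
#' @export
mesh_faces <- function(mesh) {
  cells <- mesh$cells
  m <- nrow(cells)
  # outward-oriented faces of a positively oriented tet (opposite v1..v4)
  f <- rbind(cells[, c(2, 3, 4), drop = FALSE],
             cells[, c(1, 4, 3), drop = FALSE],
             cells[, c(1, 2, 4), drop = FALSE],
             cells[, c(1, 3, 2), drop = FALSE])
  own <- rep.int(seq_len(m), 4L)
  st <- sorted_triples(f)
  key <- face_keys(st, nrow(mesh$points))
  o <- order(key, own)
  key_o <- key[o]
  dup <- c(FALSE, key_o[-1] == key_o[-length(key_o)])
  first <- o[!dup]
  second_idx <- which(dup)
  if (any(c(FALSE, dup[-length(dup)]) & dup))
    stop("non-conforming mesh: a face is shared by more than 2 cells")
  # map each duplicate (second occurrence) to its first occurrence
  first_pos <- cumsum(!dup)
  verts <- f[first, , drop = FALSE]
  owner <- own[first]
  neighbour <- rep(NA_integer_, length(first))
  neighbour[first_pos[second_idx]] <- own[o[second_idx]]
  # ensure owner < neighbour with orientation following the owner
  internal <- !is.na(neighbour)
  flip <- internal & neighbour < owner
  if (any(flip)) {
    tmp <- owner[flip]; owner[flip] <- neighbour[flip]; neighbour[flip] <- tmp
    verts[flip, ] <- verts[flip, c(1, 3, 2), drop = FALSE]
  }
  p1 <- mesh$points[verts[, 1], , drop = FALSE]
  p2 <- mesh$points[verts[, 2], , drop = FALSE]
  p3 <- mesh$points[verts[, 3], , drop = FALSE]
  list(verts = verts, owner = owner, neighbour = neighbour,
       area_vec = 0.5 * cross3(p2 - p1, p3 - p1),
       centroid = (p1 + p2 + p3) / 3,
       internal = internal)
}

# indices (into the face structure) of the faces listed in a patch
match_patch_faces <- function(faces, patch_faces, npts) {
  key_all <- face_keys(sorted_triples(faces$verts), npts)
  key_p <- face_keys(sorted_triples(as.matrix(patch_faces)), npts)
  idx <- match(key_p, key_all)
  if (anyNA(idx)) stop("patch face not present in mesh")
  idx
}

#' Surface checks and measures
#'
#' `is_watertight()` reports whether every edge of a triangulated surface is
#' shared by exactly two triangles (with opposite orientation), i.e. the
#' surface is closed and edge-manifold. `surface_area()` sums triangle
#' areas; `enclosed_volume()` integrates the divergence theorem over a
#' closed, outward-oriented surface.
#'
#' @param surface a [tri_surface()].
#' @return logical / numeric scalar (`mm^2`, `mm^3`).
#' @export
is_watertight <- function(surface) {
  tr <- surface$triangles
  if (nrow(tr) == 0) return(FALSE)
  e <- rbind(tr[, 1:2, drop = FALSE], tr[, 2:3, drop = FALSE],
             tr[, c(3, 1), drop = FALSE])
  key_dir <- e[, 1] * (nrow(surface$vertices) + 1) + e[, 2]
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- lo * (nrow(surface$vertices) + 1) + hi
  tab <- table(key)
  if (any(tab != 2L)) return(FALSE)
  # opposite orientation: each directed edge must appear exactly once
  !any(duplicated(key_dir))
}

#' @rdname is_watertight
#' @export
surface_area <- function(surface) {
  p1 <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  p2 <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  p3 <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  sum(0.5 * rownorm(cross3(p2 - p1, p3 - p1)))
}

#' @rdname is_watertight
#' @export
enclosed_volume <- function(surface) {
  p1 <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  p2 <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  p3 <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  abs(sum(rowSums(p1 * cross3(p2, p3))) / 6)
}

# boundary edges (directed, in triangle orientation) of an open surface
boundary_edges <- function(surface) {
  tr <- surface$triangles
  e <- rbind(tr[, 1:2, drop = FALSE], tr[, 2:3, drop = FALSE],
             tr[, c(3, 1), drop = FALSE])
  n1 <- nrow(surface$vertices) + 1
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- lo * n1 + hi
  cnt <- table(key)
  single <- names(cnt)[cnt == 1L]
  e[key %in% as.numeric(single), , drop = FALSE]
}

# merge duplicate vertices (within tol) and drop degenerate triangles
clean_surface <- function(surface, tol = 1e-9, min_edge = 0) {
  v <- surface$vertices; tr <- surface$triangles
  if (min_edge > 0) {
    # collapse edges shorter than min_edge by snapping to the lower index
    repeat {
      p1 <- v[tr[, 1], , drop = FALSE]; p2 <- v[tr[, 2], , drop = FALSE]
      p3 <- v[tr[, 3], , drop = FALSE]
      el <- cbind(rownorm(p2 - p1), rownorm(p3 - p2), rownorm(p1 - p3))
      short <- which(el < min_edge, arr.ind = TRUE)
      if (nrow(short) == 0) break
      i <- short[1, 1]; side <- short[1, 2]
      pair <- tr[i, c(side, side %% 3L + 1L)]
      keep <- min(pair); drop_ <- max(pair)
      v[keep, ] <- (v[keep, ] + v[drop_, ]) / 2
      tr[tr == drop_] <- keep
      tr <- tr[tr[, 1] != tr[, 2] & tr[, 2] != tr[, 3] & tr[, 1] != tr[, 3], ,
               drop = FALSE]
    }
  }
  key <- paste(round(v[, 1] / max(tol, 1e-300)),
               round(v[, 2] / max(tol, 1e-300)),
               round(v[, 3] / max(tol, 1e-300)))
  uid <- match(key, key)
  tr <- matrix(uid[tr], ncol = 3L)
  tr <- tr[tr[, 1] != tr[, 2] & tr[, 2] != tr[, 3] & tr[, 1] != tr[, 3], ,
           drop = FALSE]
  used <- sort(unique(as.vector(tr)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  s <- tri_surface(v[used, , drop = FALSE], matrix(remap[tr], ncol = 3L),
                   surface$name)
  # drop zero-area triangles
  p1 <- s$vertices[s$triangles[, 1], , drop = FALSE]
  p2 <- s$vertices[s$triangles[, 2], , drop = FALSE]
  p3 <- s$vertices[s$triangles[, 3], , drop = FALSE]
  area <- 0.5 * rownorm(cross3(p2 - p1, p3 - p1))
  s$triangles <- s$triangles[area > 1e-14, , drop = FALSE]
  s
}

#' Boundary surface of a tetrahedral mesh
#'
#' Extracts the exterior faces (those belonging to exactly one cell) as a
#' closed, outward-oriented triangulated surface.
#'
#' @param mesh a [tet_mesh()].
#' @param faces optional precomputed [mesh_faces()] structure.
#' @return A [tri_surface()].
#' @export
boundary_surface <- function(mesh, faces = NULL) {
  if (is.null(faces)) faces <- mesh_faces(mesh)
  bf <- faces$verts[!faces$internal, , drop = FALSE]
  used <- sort(unique(as.vector(bf)))
  remap <- integer(nrow(mesh$points)); remap[used] <- seq_along(used)
  tri_surface(mesh$points[used, , drop = FALSE],
              matrix(remap[bf], ncol = 3L), "boundary")
}

# nearest point on a triangulated surface to each query point (brute force,
# vectorized over triangles for each point)
project_to_surface <- function(surface, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  v1 <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  v2 <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  v3 <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  out <- matrix(0, nrow(pts), 3L)
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ]
    cp <- closest_point_on_triangles(p, v1, v2, v3)
    d2 <- rowSums((cp - rep(p, each = nrow(cp)))^2)
    out[q, ] <- cp[which.min(d2), ]
  }
  out
}

# closest point on each triangle to a single point p (Ericson's algorithm,
# vectorized over triangles)
closest_point_on_triangles <- function(p, a, b, c_) {
  n <- nrow(a)
  pm <- matrix(p, n, 3L, byrow = TRUE)
  ab <- b - a; ac <- c_ - a; ap <- pm - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- pm - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp_ <- pm - c_
  d5 <- rowSums(ab * cp_); d6 <- rowSums(ac * cp_)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  res <- matrix(NA_real_, n, 3L)
  set_ <- function(mask, val) {
    if (any(mask)) res[mask & is.na(res[, 1]), ] <<- val[mask & is.na(res[, 1]), , drop = FALSE]
  }
  set_(d1 <= 0 & d2 <= 0, a)
  set_(d3 >= 0 & d4 <= d3, b)
  set_(d6 >= 0 & d5 <= d6, c_)
  v_ab <- d1 / pmax(d1 - d3, 1e-300)
  set_(vc <= 0 & d1 >= 0 & d3 <= 0, a + v_ab * ab)
  w_ac <- d2 / pmax(d2 - d6, 1e-300)
  set_(vb <= 0 & d2 >= 0 & d6 <= 0, a + w_ac * ac)
  w_bc <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), 1e-300)
  set_(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + w_bc * (c_ - b))
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  inner <- is.na(res[, 1])
  res[inner, ] <- a[inner, , drop = FALSE] + v[inner] * ab[inner, , drop = FALSE] +
    w[inner] * ac[inner, , drop = FALSE]
  res
}
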