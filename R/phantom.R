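# Synthetic phantom generators: layered-sphere label images, body-fitted
# layered-sphere tetrahedral meshes (icosphere extrusion), and a fully
# face-orthogonal slab mesh used as the solver's reference fixture.

#' Icosphere surface
#'
#' Subdivides an icosahedron `n` times, projecting new vertices onto the
#' sphere. All vertices lie exactly at the requested radius.
#'
#' @param subdivisions number of 4-way subdivision passes (>= 0).
#' @param radius sphere radius, mm.
#' @param center sphere center, mm.
#' @return A watertight [tri_surface()] with `20 * 4^subdivisions` triangles.
#' @export
icosphere <- function(subdivisions = 3L, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / rownorm(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
    key <- lo * (nrow(v) + 1) + hi
    uk <- unique(key)
    mid_id <- nrow(v) + match(key, uk)
    pairs <- cbind(lo, hi)[!duplicated(key), , drop = FALSE]
    mid <- (v[pairs[, 1], , drop = FALSE] + v[pairs[, 2], , drop = FALSE]) / 2
    mid <- mid / rownorm(mid)
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  tri_surface(sweep(v * radius, 2, center, "+"), f,
              sprintf("icosphere_%d", subdivisions))
}

#' Voxelized layered-sphere phantom
#'
#' Generates a label image of concentric spheres: each voxel is labeled with
#' the index of the innermost layer whose radius covers the voxel-center
#' distance from the sphere center (0 outside the outermost radius).
#'
#' @param model a [layered_sphere_model()].
#' @param spacing voxel size, mm (scalar or length 3).
#' @param margin empty margin around the outer sphere, voxels.
#' @return A [labeled_image()].
#' @export
generate_layered_sphere_image <- function(model, spacing = 1, margin = 2L) {
  if (!inherits(model, "layered_sphere_model")) stop("invalid-model: not a layered_sphere_model")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  R <- model$radii[1]
  dims <- as.integer(ceiling(2 * R / spacing)) + 2L * margin + 1L
  origin <- model$center - (dims - 1) / 2 * spacing
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1] - model$center[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2] - model$center[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3] - model$center[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  lab <- array(0L, dims)
  for (r in model$radii) lab <- lab + (d2 <= r * r)
  labeled_image(lab, spacing, origin)
}

# prism -> 3 tets with conforming diagonals (min-vertex rule).
# prisms: n x 6 matrix, columns = outer triangle (a,b,c) then inner (a',b',c').
# Returns (3n) x 4 matrix of tets.
split_prisms <- function(prisms) {
  a <- prisms[, 1]; b <- prisms[, 2]; c_ <- prisms[, 3]
  # diagonal flags intrinsic to each quad face (outer copy of the smaller
  # surface vertex connects to the inner copy of the larger)
  d1 <- a < b    # quad over edge (a,b): TRUE -> diag 1-5, FALSE -> 2-4
  d2 <- b < c_   # quad over edge (b,c): TRUE -> diag 2-6, FALSE -> 3-5
  d3 <- c_ < a   # quad over edge (c,a): TRUE -> diag 3-4, FALSE -> 1-6
  cfg <- 4L * d1 + 2L * d2 + d3          # 0..7; 0 and 7 cannot occur
  # decomposition table: rows = cfg 1..6, entries = prism-local indices
  tab <- list(
    `1` = rbind(c(3, 4, 5, 6), c(1, 2, 3, 4), c(2, 3, 4, 5)),  # FFT
    `2` = rbind(c(2, 4, 5, 6), c(1, 2, 3, 6), c(1, 2, 6, 4)),  # FTF
    `3` = rbind(c(1, 2, 3, 4), c(2, 3, 4, 6), c(2, 4, 5, 6)),  # FTT
    `4` = rbind(c(1, 4, 5, 6), c(1, 2, 3, 5), c(1, 3, 5, 6)),  # TFF
    `5` = rbind(c(1, 2, 3, 5), c(1, 3, 4, 5), c(3, 4, 5, 6)),  # TFT
    `6` = rbind(c(1, 4, 5, 6), c(1, 2, 6, 5), c(1, 2, 3, 6)))  # TTF
  out <- matrix(0L, 3L * nrow(prisms), 4L)
  for (k in 1:6) {
    sel <- which(cfg == k)
    if (!length(sel)) next
    t3 <- tab[[as.character(k)]]
    for (j in 1:3) {
      rows <- (sel - 1L) * 3L + j
      out[rows, ] <- prisms[sel, t3[j, ], drop = FALSE]
    }
  }
  out
}

#' Body-fitted layered-sphere tetrahedral mesh
#'
#' Builds a conforming tetrahedral mesh of a layered sphere by radial
#' extrusion of an icosphere: concentric icosphere shells are placed at
#' every model radius (so layer interfaces are resolved exactly) and at
#' intermediate radii, radial prisms between consecutive shells are split
#' into three tetrahedra each with conforming diagonals, and the innermost
#' shell is capped with apex tetrahedra meeting at the center.
#'
#' @param model a [layered_sphere_model()].
#' @param subdivisions icosphere subdivision level (>= 2).
#' @param radial_layers integer vector, number of radial cell layers per
#'   model layer (outer -> inner; the innermost count spans radius -> 0 and
#'   includes the apex layer). Default resolves each layer to roughly the
#'   icosphere edge length.
#' @return A [tet_mesh()] with cell labels 1 (outermost) .. L (innermost)
#'   and one boundary patch `"outer"`.
#' @export
generate_layered_sphere_mesh <- function(model, subdivisions = 3L,
                                         radial_layers = NULL) {
  if (subdivisions < 2L) stop("subdivisions must be >= 2")
  L <- length(model$radii)
  bounds <- c(model$radii, 0)
  thick <- -diff(bounds)
  if (any(thick <= 0)) stop("degenerate radial layering: zero-thickness shell")
  if (is.null(radial_layers)) {
    edge <- 1.0515 * model$radii[1] / 2^subdivisions
    radial_layers <- pmax(1L, as.integer(round(thick / edge)))
  }
  radial_layers <- as.integer(rep(radial_layers, length.out = L))
  if (any(radial_layers < 1L)) stop("radial_layers must be >= 1")
  # radii of all shell copies, outer -> inner (excluding 0)
  radii_all <- numeric(0)
  for (i in seq_len(L)) {
    r_seq <- seq(bounds[i], bounds[i + 1], length.out = radial_layers[i] + 1L)
    radii_all <- c(radii_all, r_seq[-length(r_seq)])
  }
  r_last <- bounds[L] / radial_layers[L]            # innermost shell radius
  radii_all <- c(radii_all[radii_all > r_last * (1 + 1e-9)], r_last)
  ico <- icosphere(subdivisions, radius = 1)
  nv <- nrow(ico$vertices); nshell <- length(radii_all)
  pts <- matrix(0, nv * nshell + 1L, 3L)
  for (k in seq_len(nshell))
    pts[(k - 1L) * nv + seq_len(nv), ] <- ico$vertices * radii_all[k]
  center_id <- nv * nshell + 1L
  pts <- sweep(pts, 2, model$center, "+")
  pts[center_id, ] <- model$center
  tris <- ico$triangles
  cells_list <- vector("list", nshell)
  labels_list <- vector("list", nshell)
  for (k in seq_len(nshell - 1L)) {
    off_o <- (k - 1L) * nv; off_i <- k * nv
    prisms <- cbind(tris + off_o, tris + off_i)
    cells_list[[k]] <- split_prisms(prisms)
    lab <- sum(model$radii >= radii_all[k] - 1e-9)
    labels_list[[k]] <- rep(lab, nrow(cells_list[[k]]))
  }
  off_i <- (nshell - 1L) * nv
  cells_list[[nshell]] <- cbind(tris + off_i, center_id)
  labels_list[[nshell]] <- rep(L, nrow(tris))
  cells <- do.call(rbind, cells_list)
  labels <- unlist(labels_list)
  patches <- list(outer = list(faces = tris, type = "boundary"))
  tet_mesh(pts, cells, labels, patches)
}

#' Fully orthogonal slab mesh
#'
#' Meshes an axis-aligned box of voxels with 12 tetrahedra per voxel (one
#' pyramid per voxel face, apex at the voxel center, each face split along
#' the diagonal through its even-parity corners). Every internal face of
#' this decomposition separates two mirror-image cells, so the line joining
#' adjacent cell centroids is parallel to the face normal: the mesh has
#' zero non-orthogonality, making it the reference fixture for solver
#' exactness tests and for layered-slab solutions with closed forms.
#'
#' @param dims number of voxels per axis, length 3.
#' @param spacing voxel edge length, mm (scalar or length 3; orthogonality
#'   of the diagonal-split faces requires cubic voxels, enforced).
#' @param labels optional integer array `dims` of compartment labels per
#'   voxel (default all 1).
#' @param origin mm position of the first voxel corner.
#' @return A [tet_mesh()] with boundary patches `xmin`, `xmax`, `ymin`,
#'   `ymax`, `zmin`, `zmax`.
#' @export
generate_slab_mesh <- function(dims, spacing = 1, labels = NULL,
                               origin = c(0, 0, 0)) {
  dims <- as.integer(rep(dims, length.out = 3L))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (max(spacing) - min(spacing) > 1e-12 * max(spacing))
    stop("orthogonal slab mesh requires cubic voxels")
  if (is.null(labels)) labels <- array(1L, dims)
  if (!all(dim(labels) == dims)) stop("labels must have dim = dims")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # corner grid ids
  cid <- function(i, j, k) i + (nx + 1L) * (j + (ny + 1L) * k) + 1L
  ncorner <- (nx + 1L) * (ny + 1L) * (nz + 1L)
  corner_idx <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  pts_c <- cbind(origin[1] + corner_idx$i * spacing[1],
                 origin[2] + corner_idx$j * spacing[2],
                 origin[3] + corner_idx$k * spacing[3])
  vox <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  nvox <- nrow(vox)
  center_id0 <- ncorner
  pts_ctr <- cbind(origin[1] + (vox$i + 0.5) * spacing[1],
                   origin[2] + (vox$j + 0.5) * spacing[2],
                   origin[3] + (vox$k + 0.5) * spacing[3])
  pts <- rbind(pts_c, pts_ctr)
  vi <- vox$i; vj <- vox$j; vk <- vox$k
  ctr <- center_id0 + seq_len(nvox)
  # the six faces of each voxel; each face given as its 4 corners in cyclic
  # order starting from (lowest i,j,k) so parity splitting is intrinsic
  face_corners <- function(axis, side) {
    # returns 4 corner-id vectors c00,c10,c11,c01 and their parities
    if (axis == 1L) { o <- side; q <- list(c(vi + o, vj, vk), c(vi + o, vj + 1L, vk),
                                           c(vi + o, vj + 1L, vk + 1L), c(vi + o, vj, vk + 1L)) }
    if (axis == 2L) { o <- side; q <- list(c(vi, vj + o, vk), c(vi + 1L, vj + o, vk),
                                           c(vi + 1L, vj + o, vk + 1L), c(vi, vj + o, vk + 1L)) }
    if (axis == 3L) { o <- side; q <- list(c(vi, vj, vk + o), c(vi + 1L, vj, vk + o),
                                           c(vi + 1L, vj + 1L, vk + o), c(vi, vj + 1L, vk + o)) }
    ids <- lapply(q, function(u) {
      m <- matrix(u, ncol = 3L)
      cid(m[, 1], m[, 2], m[, 3])
    })
    par <- {
      m <- matrix(q[[1]], ncol = 3L)
      (m[, 1] + m[, 2] + m[, 3]) %% 2L
    }
    list(ids = ids, parity00 = par)
  }
  cells <- vector("list", 6L)
  fidx <- 1L
  for (axis in 1:3) for (side in 0:1) {
    fc <- face_corners(axis, side)
    c00 <- fc$ids[[1]]; c10 <- fc$ids[[2]]; c11 <- fc$ids[[3]]; c01 <- fc$ids[[4]]
    even00 <- fc$parity00 == 0L
    # diagonal through even-parity corners: c00-c11 if parity(c00) even,
    # else c10-c01
    triA <- cbind(c00, c10, ifelse(even00, c11, c01))
    triB <- cbind(ifelse(even00, c00, c10), c11, c01)
    cells[[fidx]] <- rbind(cbind(triA, ctr), cbind(triB, ctr))
    fidx <- fidx + 1L
  }
  cells <- do.call(rbind, cells)
  labels_cells <- rep(as.integer(labels[cbind(vi + 1L, vj + 1L, vk + 1L)]), 12L)
  # boundary patches: the two triangles of every exterior voxel face
  patch <- list()
  add_patch <- function(axis, side, name, sel) {
    fc <- face_corners(axis, side)
    c00 <- fc$ids[[1]][sel]; c10 <- fc$ids[[2]][sel]
    c11 <- fc$ids[[3]][sel]; c01 <- fc$ids[[4]][sel]
    even00 <- (fc$parity00 == 0L)[sel]
    triA <- cbind(c00, c10, ifelse(even00, c11, c01))
    triB <- cbind(ifelse(even00, c00, c10), c11, c01)
    patch[[name]] <<- list(faces = rbind(triA, triB), type = "boundary")
  }
  add_patch(1L, 0L, "xmin", vi == 0L);      add_patch(1L, 1L, "xmax", vi == nx - 1L)
  add_patch(2L, 0L, "ymin", vj == 0L);      add_patch(2L, 1L, "ymax", vj == ny - 1L)
  add_patch(3L, 0L, "zmin", vk == 0L);      add_patch(3L, 1L, "zmax", vk == nz - 1L)
  tet_mesh(pts, cells, labels_cells, patch)
}
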