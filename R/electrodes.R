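# Electrode positioning and modeling: 10-20 coordinates from four scalp
# fiducials (iterated Cz fixed point, arc-length fractions along
# plane-surface intersection curves), footprint clipping against a swept
# prism, stepwise extrusion, and electrode tagging on volume meshes.

# --- plane-surface intersection arcs -----------------------------------

# intersect a triangulated surface with the plane through p0 with normal nrm;
# returns closed polylines (list of point matrices, cyclic order)
plane_section <- function(surface, p0, nrm) {
  v <- surface$vertices
  sd <- as.vector(sweep(v, 2, p0) %*% nrm)
  sd[sd == 0] <- 1e-12                       # nudge exact-vertex hits
  tr <- surface$triangles
  s1 <- sd[tr[, 1]]; s2 <- sd[tr[, 2]]; s3 <- sd[tr[, 3]]
  crossed <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  idx <- which(crossed)
  if (!length(idx)) stop("plane does not intersect the surface")
  seg_pt <- list(); seg_edge <- list()
  n1 <- nrow(v) + 1
  for (q in idx) {
    tv <- tr[q, ]; s <- sd[tv]
    pts <- NULL; eks <- NULL
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- tv[e[1]]; b <- tv[e[2]]
      if (s[e[1]] * s[e[2]] < 0) {
        t_ <- s[e[1]] / (s[e[1]] - s[e[2]])
        pts <- rbind(pts, v[a, ] + t_ * (v[b, ] - v[a, ]))
        eks <- c(eks, min(a, b) * n1 + max(a, b))
      }
    }
    if (!is.null(pts) && nrow(pts) == 2) {
      seg_pt[[length(seg_pt) + 1L]] <- pts
      seg_edge[[length(seg_edge) + 1L]] <- eks
    }
  }
  ns <- length(seg_pt)
  edges <- do.call(rbind, seg_edge)          # ns x 2 edge keys
  # walk segments into loops via shared edge keys
  used <- rep(FALSE, ns)
  loops <- list()
  ekey <- as.vector(t(edges))
  lookup <- split(rep(seq_len(ns), each = 2L), ekey)
  while (any(!used)) {
    start <- which(!used)[1]
    used[start] <- TRUE
    loop_pts <- list(seg_pt[[start]][1, ], seg_pt[[start]][2, ])
    cur_edge <- edges[start, 2]
    repeat {
      nxt <- setdiff(lookup[[as.character(cur_edge)]], which(used))
      if (!length(nxt)) break
      nxt <- nxt[1]
      used[nxt] <- TRUE
      if (edges[nxt, 1] == cur_edge) {
        loop_pts[[length(loop_pts) + 1L]] <- seg_pt[[nxt]][2, ]
        cur_edge <- edges[nxt, 2]
      } else {
        loop_pts[[length(loop_pts) + 1L]] <- seg_pt[[nxt]][1, ]
        cur_edge <- edges[nxt, 1]
      }
    }
    loops[[length(loops) + 1L]] <- do.call(rbind, loop_pts)
  }
  loops
}

# cumulative arc length of an open polyline
polyline_lengths <- function(p) {
  c(0, cumsum(rownorm(p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])))
}

# point at arc-length fraction f of an open polyline
polyline_at <- function(p, f) {
  cl <- polyline_lengths(p)
  target <- f * cl[length(cl)]
  i <- findInterval(target, cl, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(p) - 1L)
  t_ <- (target - cl[i]) / max(cl[i + 1] - cl[i], 1e-300)
  p[i, ] + t_ * (p[i + 1, ] - p[i, ])
}

# index of loop point closest to x
closest_on_loop <- function(loop, x) {
  which.min(rowSums(sweep(loop, 2, x)^2))
}

# open path along the loop from A to B, choosing (of the two directions)
# the one passing closest to `via`
loop_path <- function(loop, a, b, via) {
  ia <- closest_on_loop(loop, a); ib <- closest_on_loop(loop, b)
  n <- nrow(loop)
  if (ia == ib) stop("arc endpoints coincide on the section loop")
  idx1 <- if (ia <= ib) ia:ib else c(ia:n, 1:ib)
  idx2 <- if (ib <= ia) ib:ia else c(ib:n, 1:ia)
  p1 <- loop[idx1, , drop = FALSE]
  p2 <- loop[rev(idx2), , drop = FALSE]      # both run a -> b
  d1 <- min(rowSums(sweep(p1, 2, via)^2))
  d2 <- min(rowSums(sweep(p2, 2, via)^2))
  p <- if (d1 <= d2) p1 else p2
  # pin the exact endpoints
  p[1, ] <- a; p[nrow(p), ] <- b
  p
}

# surface arc from a to b in the plane (a, b, third), passing near `via`
surface_arc <- function(surface, a, b, third, via = third) {
  nrm <- cross3(matrix(b - a, 1), matrix(third - a, 1))[1, ]
  nl <- sqrt(sum(nrm^2))
  if (nl < 1e-12) stop("degenerate arc plane")
  loops <- plane_section(surface, a, nrm / nl)
  # choose the loop closest to both endpoints
  sc <- vapply(loops, function(lp)
    min(rowSums(sweep(lp, 2, a)^2)) + min(rowSums(sweep(lp, 2, b)^2)), 0)
  loop_path(loops[[which.min(sc)]], a, b, via)
}

# --- 10-20 positioning --------------------------------------------------

#' 10-20 electrode positions on a scalp surface
#'
#' Computes the standard 10-20 coordinate grid from the four fiducials:
#' Cz is found as the fixed point of alternately bisecting the
#' nasion-inion and tragus-tragus surface arcs (converged when successive
#' estimates move < 0.1 mm), the midline and central positions lie at the
#' standard 10/20% arc-length fractions of the sagittal and coronal arcs,
#' and the remaining standard positions lie on the 10% circumferential
#' ring through Fpz/Oz at 10% steps (F3/F4 and P3/P4 at the midpoints of
#' the Fz-F7/F8 and Pz-T5/T6 arcs).
#'
#' @param scalp a closed [tri_surface()].
#' @param fid a [fiducial_set()]; points are projected onto the scalp.
#' @param max_iter maximum Cz fixed-point iterations (default 100).
#' @return Named matrix (rows = positions, mm) including Cz, Fpz, Fz, Pz,
#'   Oz, C3, C4, T3, T4, Fp1, Fp2, F7, F8, T5, T6, O1, O2, F3, F4, P3, P4.
#' @export
locate_1020 <- function(scalp, fid, max_iter = 100L) {
  if (!is_watertight(scalp))
    stop("scalp surface must be closed (watertight) for 10-20 positioning")
  fp <- project_to_surface(scalp, rbind(fid$nasion, fid$inion,
                                        fid$tragus_left, fid$tragus_right))
  nas <- fp[1, ]; ini <- fp[2, ]; tl <- fp[3, ]; tr_ <- fp[4, ]
  up <- cross3(matrix(ini - nas, 1), matrix(tr_ - tl, 1))[1, ]
  up <- up / sqrt(sum(up^2))
  ctr <- colMeans(scalp$vertices)
  # initial Cz: surface point farthest along `up`
  cz <- scalp$vertices[which.max(as.vector(sweep(scalp$vertices, 2, ctr) %*% up)), ]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sag <- surface_arc(scalp, nas, ini, cz, via = cz)
    cz1 <- polyline_at(sag, 0.5)
    cor <- surface_arc(scalp, tl, tr_, cz1, via = cz1)
    cz2 <- polyline_at(cor, 0.5)
    if (sqrt(sum((cz2 - cz)^2)) < 0.1) { cz <- cz2; converged <- TRUE; break }
    cz <- cz2
  }
  if (!converged) stop("Cz fixed-point iteration did not converge")
  sag <- surface_arc(scalp, nas, ini, cz, via = cz)
  cor <- surface_arc(scalp, tl, tr_, cz, via = cz)
  pos <- list(
    Cz = cz,
    Fpz = polyline_at(sag, 0.1), Fz = polyline_at(sag, 0.3),
    Pz = polyline_at(sag, 0.7), Oz = polyline_at(sag, 0.9),
    T3 = polyline_at(cor, 0.1), C3 = polyline_at(cor, 0.3),
    C4 = polyline_at(cor, 0.7), T4 = polyline_at(cor, 0.9))
  # circumferential 10% ring through Fpz, T3, Oz (and T4)
  nrm <- cross3(matrix(pos$Oz - pos$Fpz, 1), matrix(pos$T3 - pos$Fpz, 1))[1, ]
  loops <- plane_section(scalp, pos$Fpz, nrm / sqrt(sum(nrm^2)))
  sc <- vapply(loops, function(lp) min(rowSums(sweep(lp, 2, pos$Fpz)^2)), 0)
  ring <- loops[[which.min(sc)]]
  i0 <- closest_on_loop(ring, pos$Fpz)
  ring <- ring[c(i0:nrow(ring), seq_len(i0 - 1L)), , drop = FALSE]
  # pin the start of the parametrization to the exact Fpz position
  ring[1, ] <- pos$Fpz
  ring <- rbind(ring, pos$Fpz)               # closed, starting at Fpz
  # orient the ring so that T3 (left) sits at fraction ~0.25
  if (sum((polyline_at(ring, 0.25) - pos$T3)^2) >
      sum((polyline_at(ring, 0.75) - pos$T3)^2))
    ring <- ring[nrow(ring):1, , drop = FALSE]
  rng <- function(f) polyline_at(ring, f)
  pos <- c(pos, list(
    Fp1 = rng(0.05), F7 = rng(0.15), T5 = rng(0.35), O1 = rng(0.45),
    O2 = rng(0.55), T6 = rng(0.65), F8 = rng(0.85), Fp2 = rng(0.95)))
  mid <- function(a, b) polyline_at(surface_arc(scalp, a, b, ctr,
                                                via = (a + b) / 2), 0.5)
  pos <- c(pos, list(
    F3 = mid(pos$F7, pos$Fz), F4 = mid(pos$F8, pos$Fz),
    P3 = mid(pos$T5, pos$Pz), P4 = mid(pos$T6, pos$Pz)))
  out <- do.call(rbind, pos)
  rownames(out) <- names(pos)
  out
}

# --- footprint clipping -------------------------------------------------

# orthonormal tangent basis for a unit normal
tangent_basis <- function(nrm) {
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- cross3(matrix(nrm, 1), matrix(ref, 1))[1, ]
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- cross3(matrix(nrm, 1), matrix(t1, 1))[1, ]
  list(t1 = t1, t2 = t2)
}

# outward surface normal near a point: area-weighted average over the
# triangles whose centroid lies within `radius` of the point
surface_normal_at <- function(surface, p, radius = Inf) {
  v1 <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  v2 <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  v3 <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  cen <- (v1 + v2 + v3) / 3
  d2 <- rowSums(sweep(cen, 2, p)^2)
  fn <- cross3(v2 - v1, v3 - v1)
  ref <- fn[which.min(d2), ]                # nearest triangle sets the side
  sel <- if (is.finite(radius)) which(d2 <= radius^2) else seq_len(nrow(cen))
  if (!length(sel)) sel <- which.min(d2)
  sel <- sel[as.vector(fn[sel, , drop = FALSE] %*% ref) > 0]
  if (!length(sel)) sel <- which.min(d2)
  nrm <- colSums(fn[sel, , drop = FALSE])
  nrm / sqrt(sum(nrm^2))
}

# Sutherland-Hodgman clip of a 3-D polygon against the half space
# (x - q) . m <= 0
clip_halfspace <- function(poly, q, m) {
  if (is.null(poly) || nrow(poly) == 0) return(poly)
  d <- as.vector(sweep(poly, 2, q) %*% m)
  n <- nrow(poly)
  out <- NULL
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    if (d[i] <= 0) out <- rbind(out, poly[i, ])
    if (d[i] * d[j] < 0) {
      t_ <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t_ * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Clip an electrode footprint patch from the scalp
#'
#' Intersects the scalp triangles with the prism obtained by sweeping the
#' electrode footprint along the outward surface normal at `center` (exact
#' convex polygon clipping at the prism walls), then merges duplicate
#' vertices and collapses edges shorter than 1e-3 mm.
#'
#' @param scalp a [tri_surface()].
#' @param spec an [electrode_spec()] (footprints must be convex).
#' @param center footprint center on the scalp, mm.
#' @return An open [tri_surface()] patch.
#' @export
clip_patch <- function(scalp, spec, center) {
  center <- as.numeric(center)
  fp2 <- footprint_polygon(spec$shape, spec$size)
  half_diag <- max(rownorm(fp2)) * 1.5 + 1
  nrm <- surface_normal_at(scalp, center, radius = half_diag)
  tb <- tangent_basis(nrm)
  fp3 <- t(center + outer(tb$t1, fp2[, 1]) + outer(tb$t2, fp2[, 2]))
  k <- nrow(fp3)
  planes <- vector("list", k)
  for (i in seq_len(k)) {
    j <- i %% k + 1L
    m <- cross3(matrix(fp3[j, ] - fp3[i, ], 1), matrix(nrm, 1))[1, ]
    m <- m / sqrt(sum(m^2))
    if (sum((center - fp3[i, ]) * m) > 0) m <- -m   # outward
    planes[[i]] <- list(q = fp3[i, ], m = m)
  }
  # candidate triangles by bounding-sphere test
  v1 <- scalp$vertices[scalp$triangles[, 1], , drop = FALSE]
  v2 <- scalp$vertices[scalp$triangles[, 2], , drop = FALSE]
  v3 <- scalp$vertices[scalp$triangles[, 3], , drop = FALSE]
  cen <- (v1 + v2 + v3) / 3
  rad <- pmax(rownorm(v1 - cen), rownorm(v2 - cen), rownorm(v3 - cen))
  cand <- which(rownorm(sweep(cen, 2, center)) <= rad + half_diag)
  tris <- NULL
  for (q in cand) {
    poly <- rbind(v1[q, ], v2[q, ], v3[q, ])
    for (pl in planes) {
      poly <- clip_halfspace(poly, pl$q, pl$m)
      if (is.null(poly) || nrow(poly) < 3) { poly <- NULL; break }
    }
    if (!is.null(poly))
      for (i in 2:(nrow(poly) - 1L))
        tris <- rbind(tris, poly[c(1L, i, i + 1L), ])
  }
  if (is.null(tris)) stop("empty patch: footprint misses the surface")
  soup <- soup_to_surface(tris, paste0(spec$name, "_patch"))
  clean_surface(soup, tol = 1e-9, min_edge = 1e-3)
}

# --- extrusion ----------------------------------------------------------

#' Extrude an electrode patch to a closed solid
#'
#' Offsets the patch along per-vertex normals in 1 mm steps (the last step
#' sized so the total equals `thickness`), builds quad side walls along the
#' patch boundary, and closes the solid with the original patch as bottom.
#' The final offset copy is tagged as the outer (equipotential) face set in
#' attribute `outer_faces`.
#'
#' @param patch an open, manifold [tri_surface()] (from [clip_patch()]).
#' @param thickness extrusion thickness, mm.
#' @return A watertight [tri_surface()]; attributes `outer_faces` (row
#'   indices of the outer face triangles) and `n_layers`.
#' @export
extrude_electrode <- function(patch, thickness) {
  if (thickness <= 0) stop("thickness must be > 0")
  nl <- ceiling(thickness - 1e-9)
  steps <- c(rep(1, nl - 1), thickness - (nl - 1))
  v <- patch$vertices; tr <- patch$triangles
  nv <- nrow(v)
  # area-weighted vertex normals
  p1 <- v[tr[, 1], , drop = FALSE]; p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  fn <- cross3(p2 - p1, p3 - p1)
  vn <- matrix(0, nv, 3L)
  for (cidx in 1:3) {
    acc <- rowsum(fn, tr[, cidx])
    vn[as.integer(rownames(acc)), ] <- vn[as.integer(rownames(acc)), ] + acc
  }
  vn <- vn / pmax(rownorm(vn), 1e-300)
  offs <- cumsum(steps)
  layers <- lapply(offs, function(o) v + o * vn)
  # self-intersection guard: offset triangles must not flip
  for (k in seq_along(layers)) {
    lp1 <- layers[[k]][tr[, 1], , drop = FALSE]
    lp2 <- layers[[k]][tr[, 2], , drop = FALSE]
    lp3 <- layers[[k]][tr[, 3], , drop = FALSE]
    if (any(rowSums(cross3(lp2 - lp1, lp3 - lp1) * fn) <= 0))
      stop("self-intersecting offset at extrusion layer ", k)
  }
  allv <- do.call(rbind, c(list(v), layers))
  tris <- tr[, c(1, 3, 2), drop = FALSE]            # bottom, flipped
  be <- boundary_edges(patch)
  for (k in 0:(nl - 1L)) {
    o1 <- k * nv; o2 <- (k + 1L) * nv
    a1 <- be[, 1] + o1; b1 <- be[, 2] + o1
    a2 <- be[, 1] + o2; b2 <- be[, 2] + o2
    tris <- rbind(tris, cbind(a1, b1, b2), cbind(a1, b2, a2))
  }
  top <- tr + nl * nv
  top_rows <- nrow(tris) + seq_len(nrow(top))
  tris <- rbind(tris, top)
  out <- tri_surface(allv, tris, paste0(patch$name, "_solid"))
  if (!is_watertight(out))
    stop("extrusion produced a non-watertight solid (degenerate boundary?)")
  attr(out, "outer_faces") <- top_rows
  attr(out, "n_layers") <- nl
  out
}

# --- electrode tagging on a volume mesh --------------------------------

# 2-D convex-polygon containment for points in tangent coordinates
in_footprint <- function(fp2, uv) {
  k <- nrow(fp2)
  inside <- rep(TRUE, nrow(uv))
  for (i in seq_len(k)) {
    j <- i %% k + 1L
    ex <- fp2[j, 1] - fp2[i, 1]; ey <- fp2[j, 2] - fp2[i, 2]
    cr <- ex * (uv[, 2] - fp2[i, 2]) - ey * (uv[, 1] - fp2[i, 1])
    inside <- inside & cr >= 0
  }
  inside
}

#' Tag an electrode compartment on a volume mesh
#'
#' Relabels the cells under the footprint (swept along the outward normal
#' at `center`, to depth `spec$thickness` measured inward) as an electrode
#' compartment, and creates the boundary patch `"<name>_outer"` (exterior
#' faces of the electrode) and the interface patch `"<name>_contact"`
#' (electrode-tissue faces). Patches of previously tagged electrodes are
#' preserved.
#'
#' @param mesh a [tet_mesh()].
#' @param spec an [electrode_spec()].
#' @param center electrode center on the mesh boundary, mm.
#' @param electrode_label compartment label for the electrode (default:
#'   one above the current maximum).
#' @return The modified [tet_mesh()]; electrode labels are recorded in
#'   attribute `electrode_labels`.
#' @export
tag_electrode_on_mesh <- function(mesh, spec, center,
                                  electrode_label = NULL) {
  center <- as.numeric(center)
  prev <- attr(mesh, "electrode_labels")
  if (is.null(electrode_label)) electrode_label <- max(mesh$cell_labels) + 1L
  fp2 <- footprint_polygon(spec$shape, spec$size)
  if (polygon_area2(fp2) < 0) fp2 <- fp2[nrow(fp2):1, , drop = FALSE]
  half_diag <- max(rownorm(fp2)) * 1.5 + 1
  bs <- boundary_surface(mesh)
  nrm <- surface_normal_at(bs, center, radius = half_diag)
  tb <- tangent_basis(nrm)
  # make the 2-D footprint CCW so in_footprint() works
  ce <- cell_centroids(mesh)
  rel <- sweep(ce, 2, center)
  uv <- cbind(as.vector(rel %*% tb$t1), as.vector(rel %*% tb$t2))
  if (!mean(in_footprint(fp2, matrix(0, 1, 2))) )
    fp2 <- fp2[nrow(fp2):1, , drop = FALSE]
  # boundary faces under the footprint define the local surface; depth is
  # measured inward from the nearest covering boundary face along the
  # normal, so the tagged slab follows a curved scalp
  faces <- mesh_faces(mesh)
  bidx <- which(!faces$internal)
  brel <- sweep(faces$centroid[bidx, , drop = FALSE], 2, center)
  buv <- cbind(as.vector(brel %*% tb$t1), as.vector(brel %*% tb$t2))
  # only faces facing the electrode count (the swept footprint would also
  # hit the far side of a closed scalp)
  facing <- as.vector(faces$area_vec[bidx, , drop = FALSE] %*% nrm) > 0
  bsel <- in_footprint(fp2, buv) & facing
  if (!any(bsel)) stop("footprint covers no boundary faces")
  cand <- which(in_footprint(fp2, uv))
  if (!length(cand)) stop("footprint selects no cells")
  bu <- buv[bsel, , drop = FALSE]
  bheight <- as.vector(brel[bsel, , drop = FALSE] %*% nrm)
  depth <- vapply(cand, function(q) {
    lat2 <- (bu[, 1] - uv[q, 1])^2 + (bu[, 2] - uv[q, 2])^2
    bheight[which.min(lat2)] - sum(rel[q, ] * nrm)
  }, 0)
  sel <- cand[depth >= 0 & depth <= spec$thickness]
  if (!length(sel)) stop("footprint selects no cells")
  mesh$cell_labels[sel] <- as.integer(electrode_label)
  labels_rec <- c(prev, stats::setNames(as.integer(electrode_label), spec$name))
  mesh <- recompute_patches(mesh)
  mesh <- add_electrode_patches(mesh, labels_rec)
  attr(mesh, "electrode_labels") <- labels_rec
  mesh
}

# (re)create <name>_outer / <name>_contact patches for all recorded electrodes
add_electrode_patches <- function(mesh, labels_rec) {
  faces <- mesh_faces(mesh)
  for (nm in names(labels_rec)) {
    lab <- labels_rec[[nm]]
    bsel <- !faces$internal & mesh$cell_labels[faces$owner] == lab
    csel <- faces$internal &
      xor(mesh$cell_labels[faces$owner] == lab,
          mesh$cell_labels[pmax(faces$neighbour, 1L)] == lab)
    mesh$patches[[paste0(nm, "_outer")]] <-
      list(faces = faces$verts[bsel, , drop = FALSE], type = "boundary")
    mesh$patches[[paste0(nm, "_contact")]] <-
      list(faces = faces$verts[csel, , drop = FALSE], type = "interface")
  }
  mesh
}

#' Boundary spec for a tagged electrode pair
#'
#' Convenience constructor: +/- 5 V Dirichlet on the electrode outer
#' patches and the anode/cathode contact patches recorded for current
#' integration and scaling.
#'
#' @param mesh a mesh with electrodes tagged by [tag_electrode_on_mesh()].
#' @param anode,cathode electrode names as given in their specs.
#' @param potentials Dirichlet potentials, V (default +5/-5).
#' @param target_current target stimulation current, A.
#' @return A [boundary_spec()].
#' @export
electrode_boundary_spec <- function(mesh, anode, cathode,
                                    potentials = c(5, -5),
                                    target_current = 1e-3) {
  labs <- attr(mesh, "electrode_labels")
  if (is.null(labs) || !all(c(anode, cathode) %in% names(labs)))
    stop("electrodes not tagged on this mesh")
  dir <- stats::setNames(potentials,
                         c(paste0(anode, "_outer"), paste0(cathode, "_outer")))
  contact <- c(paste0(anode, "_contact"), paste0(cathode, "_contact"))
  attr(contact, "electrode_labels") <- unname(labs[c(anode, cathode)])
  boundary_spec(dirichlet = dir, target_current = target_current,
                contact_patches = contact)
}
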