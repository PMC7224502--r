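# Isosurface extraction from a label image by marching tetrahedra: the
# 0/1 indicator of the target label, sampled at voxel centers, is
# interpolated piecewise-linearly on a 6-tet decomposition of the dual
# grid and contoured at iso-level 0.5.

# per-case triangle table; tet vertices 1..4, edges indexed
# 1:(1,2) 2:(1,3) 3:(1,4) 4:(2,3) 5:(2,4) 6:(3,4)
.mt_edges <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L),
                   c(3L, 4L))
.mt_cases <- list(
  `1`  = rbind(c(1L, 2L, 3L)),                       # v1 in
  `2`  = rbind(c(1L, 4L, 5L)),                       # v2 in
  `4`  = rbind(c(2L, 4L, 6L)),                       # v3 in
  `8`  = rbind(c(3L, 5L, 6L)),                       # v4 in
  `14` = rbind(c(1L, 2L, 3L)),                       # v1 out
  `13` = rbind(c(1L, 4L, 5L)),                       # v2 out
  `11` = rbind(c(2L, 4L, 6L)),                       # v3 out
  `7`  = rbind(c(3L, 5L, 6L)),                       # v4 out
  `3`  = rbind(c(2L, 3L, 5L), c(2L, 5L, 4L)),        # v1,v2 in
  `5`  = rbind(c(1L, 3L, 6L), c(1L, 6L, 4L)),        # v1,v3 in
  `9`  = rbind(c(1L, 2L, 6L), c(1L, 6L, 5L)),        # v1,v4 in
  `6`  = rbind(c(1L, 2L, 6L), c(1L, 6L, 5L)),        # v2,v3 in
  `10` = rbind(c(1L, 3L, 6L), c(1L, 6L, 4L)),        # v2,v4 in
  `12` = rbind(c(2L, 3L, 5L), c(2L, 5L, 4L)))        # v3,v4 in

#' Extract the isosurface of a label
#'
#' Returns the closed triangulated boundary of the region `labels == label`
#' at iso-level 0.5 (vertices sit midway between inside and outside voxel
#' centers). The image is padded with background so the surface always
#' closes, and triangles are oriented outward.
#'
#' @param image a [labeled_image()].
#' @param label the target label (must be present).
#' @return A watertight [tri_surface()].
#' @export
extract_isosurface <- function(image, label) {
  dims <- dim(image$labels)
  if (!any(image$labels == label)) stop(sprintf("label %s absent from image", label))
  ind <- array(0L, dims + 2L)
  ind[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <-
    (image$labels == label) * 1L
  pd <- dims + 2L
  vid <- function(i, j, k) i + pd[1] * ((j - 1L) + pd[2] * (k - 1L))
  # dual cubes between adjacent padded voxel centers
  cube <- expand.grid(i = 1:(pd[1] - 1L), j = 1:(pd[2] - 1L),
                      k = 1:(pd[3] - 1L))
  corner <- matrix(0, nrow(cube), 8L)
  for (c8 in 1:8)
    corner[, c8] <- vid(cube$i + .cube_corners[c8, 1],
                        cube$j + .cube_corners[c8, 2],
                        cube$k + .cube_corners[c8, 3])
  inside <- matrix(ind[corner] == 1L, nrow(cube), 8L)
  # drop cubes fully inside/outside before splitting into tets
  act <- which(rowSums(inside) %in% 1:7)
  if (!length(act)) stop("label produces no isosurface")
  corner <- corner[act, , drop = FALSE]
  inside <- inside[act, , drop = FALSE]
  lo_list <- list(); hi_list <- list()
  for (t6 in 1:6) {
    tv <- corner[, .cube_tets[t6, ], drop = FALSE]
    tin <- inside[, .cube_tets[t6, ], drop = FALSE]
    case <- tin[, 1] + 2L * tin[, 2] + 4L * tin[, 3] + 8L * tin[, 4]
    for (cs in names(.mt_cases)) {
      sel <- which(case == as.integer(cs))
      if (!length(sel)) next
      tris <- .mt_cases[[cs]]
      for (r in seq_len(nrow(tris))) {
        lo3 <- hi3 <- matrix(0, length(sel), 3L)
        for (col in 1:3) {
          eidx <- tris[r, col]
          a <- tv[sel, .mt_edges[eidx, 1]]
          b <- tv[sel, .mt_edges[eidx, 2]]
          lo3[, col] <- pmin(a, b); hi3[, col] <- pmax(a, b)
        }
        lo_list[[length(lo_list) + 1L]] <- lo3
        hi_list[[length(hi_list) + 1L]] <- hi3
      }
    }
  }
  lo <- t(do.call(rbind, lo_list))        # 3 x nt (edge per triangle corner)
  hi <- t(do.call(rbind, hi_list))
  key <- as.vector(lo) * (prod(pd) + 1) + as.vector(hi)
  uk <- unique(key)
  vmap <- match(key, uk)
  tri <- matrix(vmap, nrow = 3L)
  pair <- cbind(as.vector(lo), as.vector(hi))[!duplicated(key), , drop = FALSE]
  coord_of <- function(id) {
    id0 <- id - 1
    i <- id0 %% pd[1] + 1L
    j <- (id0 %/% pd[1]) %% pd[2] + 1L
    k <- id0 %/% (pd[1] * pd[2]) + 1L
    # padded voxel (1,1,1) is centered one spacing below the first voxel
    cbind(image$origin[1] + (i - 2L) * image$spacing[1],
          image$origin[2] + (j - 2L) * image$spacing[2],
          image$origin[3] + (k - 2L) * image$spacing[3])
  }
  verts <- (coord_of(pair[, 1]) + coord_of(pair[, 2])) / 2
  tris <- t(tri)
  # orient each triangle outward: normal must point from the inside voxel
  # centers toward the outside ones along the cut edges
  insum <- coord_of(ifelse(ind[pair[, 1]] == 1L, pair[, 1], pair[, 2]))
  outsum <- coord_of(ifelse(ind[pair[, 1]] == 1L, pair[, 2], pair[, 1]))
  outdir_v <- outsum - insum
  p1 <- verts[tris[, 1], , drop = FALSE]
  p2 <- verts[tris[, 2], , drop = FALSE]
  p3 <- verts[tris[, 3], , drop = FALSE]
  nrm <- cross3(p2 - p1, p3 - p1)
  od <- (outdir_v[tris[, 1], , drop = FALSE] + outdir_v[tris[, 2], , drop = FALSE] +
         outdir_v[tris[, 3], , drop = FALSE]) / 3
  flip <- rowSums(nrm * od) < 0
  tris[flip, ] <- tris[flip, c(1, 3, 2), drop = FALSE]
  clean_surface(tri_surface(verts, tris, sprintf("iso_label_%s", label)))
}
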