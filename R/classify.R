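# Hybrid domain point classification: ordered closed surfaces, then the
# labeled image; the last positive responder wins.

#' Point-in-surface test by ray casting
#'
#' Casts rays from each query point and counts triangle crossings; an odd
#' count means inside. Three jittered ray directions are used with a
#' majority vote, which makes the test robust to rays grazing edges or
#' lying in a triangle's plane.
#'
#' @param surface a closed [tri_surface()].
#' @param pts n x 3 matrix of query points (mm).
#' @param n_rays number of jittered ray directions (odd; default 3).
#' @param seed integer seed for the (deterministic) ray jitter.
#' @return Logical vector: point strictly inside.
#' @export
points_in_surface <- function(surface, pts, n_rays = 3L, seed = 7L) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  set.seed(seed)
  base <- c(0.57735027, 0.52573111, 0.62347329)      # irrational-ish direction
  votes <- matrix(0L, nrow(pts), n_rays)
  for (k in seq_len(n_rays)) {
    dir <- base + stats::rnorm(3, sd = 0.05 * k)
    dir <- dir / sqrt(sum(dir^2))
    votes[, k] <- ray_crossings(surface, pts, dir) %% 2L
  }
  rowSums(votes) > n_rays / 2
}

# number of ray-triangle crossings per point for one shared ray direction
# (Moeller-Trumbore, vectorized over triangles, chunked over points)
ray_crossings <- function(surface, pts, dir) {
  v1 <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  v2 <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  v3 <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  dm <- matrix(dir, nrow(v1), 3L, byrow = TRUE)
  pvec <- cross3(dm, e2)
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > 1e-12
  inv_det <- ifelse(ok, 1 / det, 0)
  nt <- nrow(v1)
  out <- integer(nrow(pts))
  chunk <- max(1L, floor(4e6 / nt))
  for (s in seq(1L, nrow(pts), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(pts))
    cnt <- integer(length(idx))
    for (q in seq_along(idx)) {
      p <- pts[idx[q], ]
      tvec <- cbind(p[1] - v1[, 1], p[2] - v1[, 2], p[3] - v1[, 3])
      u <- rowSums(tvec * pvec) * inv_det
      qvec <- cross3(tvec, e1)
      v <- (qvec[, 1] * dir[1] + qvec[, 2] * dir[2] + qvec[, 3] * dir[3]) * inv_det
      t_ <- rowSums(e2 * qvec) * inv_det
      cnt[q] <- sum(ok & u >= 0 & v >= 0 & (u + v) <= 1 & t_ > 1e-12)
    }
    out[idx] <- cnt
  }
  out
}

#' Classify points against a hybrid domain
#'
#' Each query point is tested against every closed surface of the domain in
#' entry order, then against the labeled image (non-zero voxel label =
#' positive response). The label of the last positively responding domain
#' is returned; 0 if none respond. The image is queried last, so a non-zero
#' image label overrides any surface.
#'
#' @param domain a [hybrid_domain()].
#' @param pts n x 3 matrix of points (mm).
#' @return Integer label per point.
#' @export
classify_point_hybrid <- function(domain, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  if (length(domain$surfaces) == 0 && is.null(domain$image))
    stop("hybrid domain has no surfaces and no image")
  for (s in domain$surfaces)
    if (!is_watertight(s$surface))
      stop(sprintf("surface '%s' is not watertight", s$surface$name))
  lab <- integer(nrow(pts))
  for (s in domain$surfaces) {
    inside <- points_in_surface(s$surface, pts)
    lab[inside] <- as.integer(s$label)
  }
  img <- domain$image
  if (!is.null(img)) {
    dims <- dim(img$labels)
    idx <- sweep(sweep(pts, 2, img$origin), 2, img$spacing, "/")
    idx <- round(idx) + 1                 # voxel-center convention, 1-based
    ingrid <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
              idx[, 2] >= 1 & idx[, 2] <= dims[2] &
              idx[, 3] >= 1 & idx[, 3] <= dims[3]
    if (any(ingrid)) {
      ii <- idx[ingrid, , drop = FALSE]
      vox <- img$labels[cbind(ii[, 1], ii[, 2], ii[, 3])]
      pos <- vox > 0L
      lab[ingrid][pos] <- vox[pos]
    }
  }
  lab
}

#' Relabel mesh cells by hybrid-domain classification
#'
#' Sets each cell's compartment label to the hybrid-domain classification
#' of its centroid and recomputes the patch structure from the new label
#' interfaces.
#'
#' @param mesh a [tet_mesh()].
#' @param domain a [hybrid_domain()].
#' @return The relabeled [tet_mesh()].
#' @export
relabel_cells <- function(mesh, domain) {
  mesh$cell_labels <- classify_point_hybrid(domain, cell_centroids(mesh))
  recompute_patches(mesh)
}
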