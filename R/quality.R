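#' Mesh quality report
#'
#' Computes, per internal face, the non-orthogonality (angle in degrees
#' between the face area vector and the owner-to-neighbour centroid vector)
#' and the skewness (offset between the face centroid and the point where
#' the centroid line crosses the face plane, normalized by the centroid
#' distance). Faces with non-orthogonality above 70 degrees degrade the
#' two-point flux approximation and are counted separately.
#'
#' @param mesh a [tet_mesh()].
#' @param threshold non-orthogonality reporting threshold in degrees
#'   (default 70).
#' @return An object of class `quality_report`: list with `n_cells`,
#'   `n_nonorthogonal_faces`, `max_nonorthogonality` (degrees),
#'   `max_skewness`, plus the per-face vectors `nonorthogonality` and
#'   `skewness`.
#' @export
mesh_quality <- function(mesh, threshold = 70) {
  faces <- mesh_faces(mesh)
  int <- which(faces$internal)
  if (!length(int)) stop("mesh has no internal faces")
  ce <- cell_centroids(mesh)
  d <- ce[faces$neighbour[int], , drop = FALSE] - ce[faces$owner[int], , drop = FALSE]
  A <- faces$area_vec[int, , drop = FALSE]
  dn <- rownorm(d); An <- rownorm(A)
  cosang <- rowSums(d * A) / (dn * An)
  nonorth <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  # intersection of the centroid line with the face plane
  nhat <- A / An
  co <- ce[faces$owner[int], , drop = FALSE]
  num <- rowSums((faces$centroid[int, , drop = FALSE] - co) * nhat)
  den <- rowSums(d * nhat)
  t_ <- num / den
  xint <- co + d * t_
  skew <- rownorm(faces$centroid[int, , drop = FALSE] - xint) / dn
  structure(list(n_cells = nrow(mesh$cells),
                 n_nonorthogonal_faces = sum(nonorth > threshold),
                 max_nonorthogonality = max(nonorth),
                 max_skewness = max(skew),
                 threshold = threshold,
                 nonorthogonality = nonorth,
                 skewness = skew),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(paste0("<quality_report> %d cells\n",
                     "  faces with non-orthogonality > %g deg: %d\n",
                     "  max non-orthogonality: %.2f deg\n",
                     "  max skewness: %.4f\n"),
              x$n_cells, x$threshold, x$n_nonorthogonal_faces,
              x$max_nonorthogonality, x$max_skewness))
  invisible(x)
}
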