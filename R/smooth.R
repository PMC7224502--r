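#' Taubin surface smoothing
#'
#' Alternates Laplacian smoothing steps with positive factor `lambda` and
#' negative factor `mu` (|mu| slightly larger), which smooths without the
#' volume shrinkage of plain Laplacian smoothing. Uses uniform (umbrella)
#' vertex weights; connectivity is unchanged and isolated vertices are left
#' fixed.
#'
#' @param surface a [tri_surface()].
#' @param lambda positive smoothing factor (default 0.5).
#' @param mu negative un-shrinking factor (default -0.53).
#' @param steps number of lambda/mu step pairs (default 50).
#' @return The smoothed [tri_surface()].
#' @export
taubin_smooth <- function(surface, lambda = 0.5, mu = -0.53, steps = 50L) {
  if (steps == 0L) return(surface)
  tr <- surface$triangles
  n <- nrow(surface$vertices)
  e <- rbind(tr[, 1:2, drop = FALSE], tr[, 2:3, drop = FALSE],
             tr[, c(3, 1), drop = FALSE])
  e <- rbind(e, e[, 2:1, drop = FALSE])
  e <- unique(e)
  adj <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(adj)
  fixed <- deg == 0
  invdeg <- ifelse(fixed, 0, 1 / pmax(deg, 1))
  v <- surface$vertices
  for (s in seq_len(steps)) {
    for (f in c(lambda, mu)) {
      lap <- as.matrix(adj %*% v) * invdeg - v
      lap[fixed, ] <- 0
      v <- v + f * lap
    }
  }
  tri_surface(v, tr, surface$name)
}
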