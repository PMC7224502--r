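# Post-processing statistics for field comparison: magnitude percentiles
# per compartment, hotspot masks, relative and angular difference maps,
# and line sampling of cell-centered fields.

field_magnitude <- function(E) {
  if (is.matrix(E)) rownorm(E) else as.numeric(E)
}

#' Field-magnitude statistics per compartment
#'
#' Mean, standard deviation and the 90th/95th/99th percentiles of |E|
#' restricted to one mesh compartment. Percentiles use linear interpolation
#' between closest ranks (R quantile type 7); statistics are unweighted
#' per-cell by default, with optional cell-volume weighting.
#'
#' @param E n x 3 field matrix (or precomputed magnitudes).
#' @param mesh a [tet_mesh()].
#' @param compartment compartment label to restrict to.
#' @param volume_weighted weight cells by volume (default `FALSE`).
#' @return List with `mean`, `sd`, `p90`, `p95`, `p99`, `n`.
#' @export
magnitude_stats <- function(E, mesh, compartment, volume_weighted = FALSE) {
  sel <- which(mesh$cell_labels == compartment)
  if (!length(sel)) stop("empty compartment: ", compartment)
  mag <- field_magnitude(E)[sel]
  ok <- is.finite(mag)
  mag <- mag[ok]
  if (volume_weighted) {
    w <- cell_volumes(mesh)[sel][ok]
    w <- w / sum(w)
    mu <- sum(w * mag)
    sd_ <- sqrt(sum(w * (mag - mu)^2))
    o <- order(mag)
    cw <- cumsum(w[o])
    pct <- function(p) mag[o][which.max(cw >= p)]
    list(mean = mu, sd = sd_, p90 = pct(.90), p95 = pct(.95),
         p99 = pct(.99), n = length(mag))
  } else {
    q <- stats::quantile(mag, c(.90, .95, .99), names = FALSE, type = 7)
    list(mean = mean(mag), sd = stats::sd(mag), p90 = q[1], p95 = q[2],
         p99 = q[3], n = length(mag))
  }
}

#' Hotspot mask
#'
#' Flags the cells whose field magnitude lies strictly above the given
#' percentile of the supplied cells (conventionally the 90th percentile of
#' a compartment defines its stimulation hotspots). Scale-invariant.
#'
#' @param E field matrix or magnitude vector (already restricted to the
#'   compartment of interest).
#' @param percentile percentile threshold (default 90).
#' @return Logical mask (with a warning and all-`FALSE` for a constant
#'   field).
#' @export
hotspot_mask <- function(E, percentile = 90) {
  mag <- field_magnitude(E)
  if (max(mag, na.rm = TRUE) - min(mag, na.rm = TRUE) <= 0) {
    warning("constant field: hotspot mask is empty")
    return(rep(FALSE, length(mag)))
  }
  thr <- stats::quantile(mag, percentile / 100, names = FALSE, type = 7,
                         na.rm = TRUE)
  !is.na(mag) & mag > thr
}

#' Relative difference of field magnitudes
#'
#' `100 * | |E_ref| - |E_test| | / |E_ref|` per cell, in percent: the
#' absolute value of the relative difference, normalized by the reference
#' field (hence not symmetric in its arguments). Cells with `|E_ref| = 0`
#' are flagged undefined (`NA`).
#'
#' @param E_ref,E_test field matrices or magnitude vectors, matched cells.
#' @return Percent difference per cell (`NA` where undefined).
#' @export
relative_difference_map <- function(E_ref, E_test) {
  a <- field_magnitude(E_ref); b <- field_magnitude(E_test)
  if (length(a) != length(b)) stop("fields must have matched cells")
  out <- 100 * abs(a - b) / a
  out[!is.finite(out)] <- NA_real_
  out
}

#' Angular difference of field directions
#'
#' `acos(<E_a, E_b> / (|E_a| |E_b|))` in degrees per cell, with the inner
#' product clamped to [-1, 1] so antiparallel fields return exactly 180
#' without NaN. Zero-vector cells are flagged undefined (`NA`). Symmetric
#' in its arguments.
#'
#' @param E_a,E_b n x 3 field matrices, matched cells.
#' @return Angle in degrees per cell, in [0, 180] (`NA` where undefined).
#' @export
angle_difference_map <- function(E_a, E_b) {
  if (!is.matrix(E_a) || !is.matrix(E_b)) stop("vector fields required")
  na <- rownorm(E_a); nb <- rownorm(E_b)
  cosang <- rowSums(E_a * E_b) / (na * nb)
  out <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  out[!is.finite(cosang)] <- NA_real_
  out
}

# containing-cell lookup for query points: candidate cells by centroid
# proximity, then an exact barycentric containment test
locate_cells <- function(mesh, pts, n_candidates = 64L) {
  ce <- cell_centroids(mesh)
  m <- nrow(mesh$cells)
  n_candidates <- min(n_candidates, m)
  out <- rep(NA_integer_, nrow(pts))
  a <- mesh$points[mesh$cells[, 1], , drop = FALSE]
  b <- mesh$points[mesh$cells[, 2], , drop = FALSE]
  c_ <- mesh$points[mesh$cells[, 3], , drop = FALSE]
  d <- mesh$points[mesh$cells[, 4], , drop = FALSE]
  vol <- tet_signed_volumes(mesh$points, mesh$cells)
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ]
    d2 <- (ce[, 1] - p[1])^2 + (ce[, 2] - p[2])^2 + (ce[, 3] - p[3])^2
    cand <- order(d2)[seq_len(n_candidates)]
    pm <- matrix(p, length(cand), 3L, byrow = TRUE)
    sv <- function(p1, p2, p3, p4)
      rowSums((p2 - p1) * cross3(p3 - p1, p4 - p1)) / 6
    tol <- -1e-9 * vol[cand]
    inside <- sv(pm, b[cand, , drop = FALSE], c_[cand, , drop = FALSE],
                 d[cand, , drop = FALSE]) >= tol &
              sv(a[cand, , drop = FALSE], pm, c_[cand, , drop = FALSE],
                 d[cand, , drop = FALSE]) >= tol &
              sv(a[cand, , drop = FALSE], b[cand, , drop = FALSE], pm,
                 d[cand, , drop = FALSE]) >= tol &
              sv(a[cand, , drop = FALSE], b[cand, , drop = FALSE],
                 c_[cand, , drop = FALSE], pm) >= tol
    hit <- which(inside)
    if (length(hit)) out[q] <- cand[hit[1]]
  }
  out
}

sample_line_values <- function(mesh, field, pts) {
  cells <- locate_cells(mesh, pts)
  vals <- ifelse(is.na(cells), NA_real_, field[cells])
  labels <- ifelse(is.na(cells), NA_integer_, mesh$cell_labels[cells])
  list(values = vals, labels = labels, cells = cells)
}

#' Sample a cell field along a line
#'
#' Places `n_samples` equidistant points on the segment `p0 -> p1` and
#' reports the (piecewise-constant) value of the containing cell at each,
#' together with the compartment label. Points outside the mesh are flagged
#' (`inside = FALSE`, value `NA`) but kept, so the returned sample count
#' always equals `n_samples`.
#'
#' @param mesh a [tet_mesh()].
#' @param field per-cell values (vector) or n x 3 matrix (sampled as
#'   magnitude).
#' @param p0,p1 segment end points, mm.
#' @param n_samples number of samples.
#' @return data.frame with `s` (arc length, mm), `x`, `y`, `z`, `value`,
#'   `label`, `inside`.
#' @export
sample_line <- function(mesh, field, p0, p1, n_samples = 100L) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  tt <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]),
               p0[2] + tt * (p1[2] - p0[2]),
               p0[3] + tt * (p1[3] - p0[3]))
  cells <- locate_cells(mesh, pts)
  if (all(is.na(cells))) stop("segment lies entirely outside the mesh")
  mag <- field_magnitude(field)
  data.frame(s = tt * sqrt(sum((p1 - p0)^2)),
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             value = ifelse(is.na(cells), NA_real_, mag[cells]),
             label = ifelse(is.na(cells), NA_integer_,
                            mesh$cell_labels[cells]),
             inside = !is.na(cells))
}
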