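# Per-cell conductivity tensors: uniform isotropic values per compartment,
# and anisotropic white-matter tensors mapped from diffusion tensors by the
# volume-constraint method (shared eigenvectors, fixed 1:10 anisotropy
# ratio, geometric mean pinned to the tissue's scalar conductivity).

#' Per-cell conductivity tensor field
#'
#' Stores one symmetric positive-definite 3x3 tensor (S/m) per cell in
#' compact symmetric form (columns xx, yy, zz, xy, xz, yz) plus a
#' provenance flag per cell.
#'
#' @param tensors m x 6 matrix (xx, yy, zz, xy, xz, yz).
#' @param provenance character vector, `"isotropic"` or `"anisotropic"`.
#' @return An object of class `conductivity_field`.
#' @export
conductivity_field <- function(tensors, provenance = NULL) {
  tensors <- as.matrix(tensors)
  if (ncol(tensors) != 6L) stop("tensors must be m x 6 (xx, yy, zz, xy, xz, yz)")
  if (is.null(provenance)) provenance <- rep("isotropic", nrow(tensors))
  structure(list(tensors = tensors, provenance = provenance),
            class = "conductivity_field")
}

# expand compact row to full 3x3
sym6_to_mat <- function(row) {
  matrix(c(row[1], row[4], row[5],
           row[4], row[2], row[6],
           row[5], row[6], row[3]), 3L, 3L)
}

mat_to_sym6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

#' Uniform isotropic conductivity per compartment
#'
#' Assigns `sigma * I` to every cell of each compartment, with sigma looked
#' up in the tissue table by the compartment's label name.
#'
#' @param mesh a [tet_mesh()].
#' @param table a [tissue_table()] keyed either by the character form of the
#'   numeric cell labels or via `label_names`.
#' @param label_names optional named character vector mapping numeric cell
#'   labels to tissue table keys, e.g. `c("1" = "skin", "2" = "skull")`.
#' @return A [conductivity_field()].
#' @export
isotropic_field <- function(mesh, table, label_names = NULL) {
  labs <- mesh$cell_labels
  key <- as.character(labs)
  if (!is.null(label_names)) key <- unname(label_names[key])
  missing_ <- setdiff(unique(key), names(table))
  if (length(missing_) || anyNA(key))
    stop("labels missing from tissue table: ",
         paste(unique(c(missing_, as.character(labs)[is.na(key)])), collapse = ", "))
  sig <- unlist(table)[key]
  tensors <- cbind(sig, sig, sig, 0, 0, 0)
  colnames(tensors) <- NULL
  conductivity_field(tensors, rep("isotropic", length(sig)))
}

#' Volume-constraint conductivity tensor
#'
#' Maps a diffusion tensor to a white-matter conductivity tensor: the
#' eigenvectors are retained while the eigenvalues are replaced by
#' `(sigma_main, sigma_aux, sigma_aux)` (principal direction = largest
#' diffusion eigenvalue), where the two constraints
#' `sigma_wm^2 = sigma_main * sigma_aux` and
#' `sigma_main = ratio * sigma_aux` give
#' `sigma_main = sigma_wm * sqrt(ratio)` and
#' `sigma_aux = sigma_wm / sqrt(ratio)`. The geometric mean of the extreme
#' eigenvalues therefore always equals `sigma_wm` (the volume constraint).
#'
#' @param D symmetric 3x3 diffusion tensor (any diffusivity units; only the
#'   eigenvectors are used).
#' @param sigma_wm scalar white-matter conductivity, S/m.
#' @param ratio anisotropy ratio between principal and auxiliary
#'   conductivity (default 10).
#' @return Symmetric positive-definite 3x3 conductivity tensor, S/m.
#' @export
volume_constraint_tensor <- function(D, sigma_wm, ratio = 10) {
  if (sigma_wm <= 0) stop("sigma_wm must be > 0")
  if (ratio <= 1) stop("ratio must be > 1")
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-9 * max(1, max(abs(D))))
    stop("diffusion tensor is not symmetric")
  D <- (D + t(D)) / 2
  if (anyNA(D)) D <- diag(3)               # NaN-cleaned fallback: isotropic
  eg <- ordered_eigen(D)
  s_main <- sigma_wm * sqrt(ratio)
  s_aux <- sigma_wm / sqrt(ratio)
  eg$vectors %*% diag(c(s_main, s_aux, s_aux)) %*% t(eg$vectors)
}

# eigendecomposition with descending eigenvalues and a deterministic sign /
# tie-break: each eigenvector is flipped so its lexicographically largest
# component is positive
ordered_eigen <- function(D) {
  eg <- eigen(D, symmetric = TRUE)        # eigen() returns descending order
  v <- eg$vectors
  for (k in 1:3) {
    col <- v[, k]
    j <- which.max(abs(col))
    if (col[j] < 0) v[, k] <- -col
  }
  list(values = eg$values, vectors = v)
}

#' Repair a (possibly broken) symmetric tensor
#'
#' Total function used to sanitize diffusion tensors before use: tensors
#' containing NaN are replaced by an isotropic fallback, and eigenvalues
#' below `eps` are clamped to `eps` so the result is always symmetric
#' positive definite.
#'
#' @param D 3x3 matrix.
#' @param fallback isotropic fallback value used for NaN tensors.
#' @param eps eigenvalue clamp (default 1e-12).
#' @return Symmetric positive-definite 3x3 matrix.
#' @export
spd_repair <- function(D, fallback = 1, eps = 1e-12) {
  D <- as.matrix(D)
  if (anyNA(D)) return(diag(rep(fallback, 3)))
  D <- (D + t(D)) / 2
  eg <- eigen(D, symmetric = TRUE)
  if (min(eg$values) >= eps) return(D)
  vals <- pmax(eg$values, eps)
  eg$vectors %*% diag(vals) %*% t(eg$vectors)
}

#' Synthetic diffusion tensor volume
#'
#' A voxel grid of symmetric 3x3 tensors in lower-triangular component
#' order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), grid geometry as in
#' [labeled_image()]. `uniform_tensor_field()` repeats one tensor
#' everywhere; `swirl_tensor_field()` orients the principal axis along the
#' local azimuthal direction around the z axis (eigenvalues 3, 1, 1), a
#' field with a known analytic principal direction for testing.
#'
#' @param dims grid size, length 3.
#' @param D 3x3 symmetric tensor to repeat.
#' @param spacing,origin grid geometry, mm.
#' @return An object of class `diffusion_tensor_field` (list with `data`,
#'   an array `c(dims, 6)`, plus `spacing` and `origin`).
#' @export
uniform_tensor_field <- function(dims, D, spacing = 1, origin = c(0, 0, 0)) {
  dims <- as.integer(rep(dims, length.out = 3L))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  D <- as.matrix(D)
  comp <- c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
  data <- array(rep(comp, each = prod(dims)), c(dims, 6L))
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "diffusion_tensor_field")
}

#' @rdname uniform_tensor_field
#' @export
swirl_tensor_field <- function(dims, spacing = 1, origin = NULL) {
  dims <- as.integer(rep(dims, length.out = 3L))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing  # centered on axis
  g <- expand.grid(i = 0:(dims[1] - 1L), j = 0:(dims[2] - 1L),
                   k = 0:(dims[3] - 1L))
  x <- origin[1] + g$i * spacing[1]
  y <- origin[2] + g$j * spacing[2]
  r <- pmax(sqrt(x^2 + y^2), 1e-9)
  ex <- -y / r; ey <- x / r                 # azimuthal unit vector
  # D = I + 2 e e^T  (eigenvalues 3 along e, 1 elsewhere)
  data <- array(0, c(dims, 6L))
  data[, , , 1] <- array(1 + 2 * ex * ex, dims)        # Dxx
  data[, , , 2] <- array(2 * ex * ey, dims)            # Dxy
  data[, , , 3] <- array(1 + 2 * ey * ey, dims)        # Dyy
  data[, , , 4] <- 0                                   # Dxz
  data[, , , 5] <- 0                                   # Dyz
  data[, , , 6] <- 1                                   # Dzz
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "diffusion_tensor_field")
}

#' Read / write diffusion tensor volumes (NIfTI)
#'
#' Tensor volumes are stored as 4-D NIfTI with 6 components per voxel in
#' lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
#'
#' @param field a `diffusion_tensor_field`.
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `read_tensor_field()` returns a `diffusion_tensor_field`.
#' @export
write_tensor_field <- function(field, path) {
  im <- RNifti::asNifti(field$data, reference = list(
    pixdim = c(1, field$spacing, 1, 1, 1, 1),
    qform_code = 1L, quatern_b = 0, quatern_c = 0, quatern_d = 0,
    qoffset_x = field$origin[1], qoffset_y = field$origin[2],
    qoffset_z = field$origin[3]), internal = FALSE)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_tensor_field
#' @export
read_tensor_field <- function(path) {
  im <- RNifti::readNifti(path)
  dat <- as.array(im)
  if (length(dim(dat)) != 4L || dim(dat)[4] != 6L)
    stop("tensor volume must have 6 components per voxel")
  x <- RNifti::xform(im)
  structure(list(data = array(as.numeric(dat), dim(dat)),
                 spacing = abs(diag(x[1:3, 1:3])),
                 origin = unname(x[1:3, 4])),
            class = "diffusion_tensor_field")
}

#' Transfer diffusion tensors onto white-matter cells
#'
#' For every cell of the white-matter compartment, samples the diffusion
#' tensor of the voxel containing the cell centroid (nearest-voxel, no
#' interpolation), maps it through [volume_constraint_tensor()] and
#' overwrites the cell's conductivity tensor; all other cells are
#' untouched. Centroids outside the tensor grid (and NaN tensors) fall back
#' to the isotropic `sigma_wm`, with the count reported as an attribute.
#'
#' @param field a `diffusion_tensor_field`.
#' @param mesh a [tet_mesh()].
#' @param conductivity a [conductivity_field()] to update.
#' @param wm_label numeric cell label of the white-matter compartment.
#' @param sigma_wm white-matter scalar conductivity, S/m (default 0.126).
#' @param ratio anisotropy ratio (default 10).
#' @return The updated [conductivity_field()]; attribute `n_fallback`
#'   counts out-of-grid or NaN cells.
#' @export
tensors_to_cells <- function(field, mesh, conductivity, wm_label,
                             sigma_wm = 0.126, ratio = 10) {
  wm <- which(mesh$cell_labels == wm_label)
  if (!length(wm)) stop("no cells with wm_label ", wm_label)
  ce <- cell_centroids(mesh)[wm, , drop = FALSE]
  dims <- dim(field$data)[1:3]
  idx <- round(sweep(sweep(ce, 2, field$origin), 2, field$spacing, "/")) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
        idx[, 2] >= 1 & idx[, 2] <= dims[2] &
        idx[, 3] >= 1 & idx[, 3] <= dims[3]
  n_fallback <- 0L
  for (q in seq_along(wm)) {
    if (ok[q]) {
      comp <- field$data[idx[q, 1], idx[q, 2], idx[q, 3], ]
      D <- matrix(c(comp[1], comp[2], comp[4],
                    comp[2], comp[3], comp[5],
                    comp[4], comp[5], comp[6]), 3L, 3L)
      if (anyNA(D)) { n_fallback <- n_fallback + 1L; D <- diag(3) }
      D <- spd_repair(D, fallback = 1)
      sig <- volume_constraint_tensor(D, sigma_wm, ratio)
    } else {
      n_fallback <- n_fallback + 1L
      sig <- diag(rep(sigma_wm, 3))
    }
    conductivity$tensors[wm[q], ] <- mat_to_sym6(sig)
    conductivity$provenance[wm[q]] <- "anisotropic"
  }
  if (n_fallback > 0)
    message(n_fallback, " white-matter cells fell back to isotropic conductivity")
  attr(conductivity, "n_fallback") <- n_fallback
  conductivity
}
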