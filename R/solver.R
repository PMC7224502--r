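# Cell-centered finite-volume discretization of div(sigma grad phi) = 0.
#
# Internal faces carry an implicit two-point ("orthogonal") flux
# coefficient sigma_fn |A|^2 / (A . d); the non-orthogonal remainder of the
# face flux is evaluated explicitly from least-squares cell gradients
# (over-relaxed decomposition) and iterated in an outer correction loop.
# Dirichlet boundary faces contribute a half-cell flux; all other boundary
# faces are zero-gradient Neumann. Geometry is converted from mm to metres
# here, so phi is in V, E in V/m, J in A/m^2 and currents in A.

MM <- 1e-3  # mm -> m

# quadratic form n' T n for compact symmetric tensors (k x 6) and unit rows n
sym6_quad <- function(T6, n) {
  T6[, 1] * n[, 1]^2 + T6[, 2] * n[, 2]^2 + T6[, 3] * n[, 3]^2 +
    2 * (T6[, 4] * n[, 1] * n[, 2] + T6[, 5] * n[, 1] * n[, 3] +
         T6[, 6] * n[, 2] * n[, 3])
}

# rowwise T v for compact symmetric tensors
sym6_mv <- function(T6, v) {
  cbind(T6[, 1] * v[, 1] + T6[, 4] * v[, 2] + T6[, 5] * v[, 3],
        T6[, 4] * v[, 1] + T6[, 2] * v[, 2] + T6[, 6] * v[, 3],
        T6[, 5] * v[, 1] + T6[, 6] * v[, 2] + T6[, 3] * v[, 3])
}

# rowwise inverse of compact symmetric 3x3 matrices; returns list(inv6, det)
sym6_inv <- function(S) {
  a <- S[, 1]; b <- S[, 2]; c_ <- S[, 3]; d <- S[, 4]; e <- S[, 5]; f <- S[, 6]
  A11 <- b * c_ - f * f
  A12 <- e * f - d * c_
  A13 <- d * f - b * e
  A22 <- a * c_ - e * e
  A23 <- d * e - a * f
  A33 <- a * b - d * d
  det <- a * A11 + d * A12 + e * A13
  list(inv6 = cbind(A11, A22, A33, A12, A13, A23) / det, det = det)
}

#' Assemble the finite-volume system
#'
#' Builds the sparse linear system and all face data needed by
#' [solve_potential()]: implicit orthogonal flux coefficients per internal
#' face, Dirichlet half-cell flux terms, the least-squares gradient
#' structure, and the non-orthogonal correction geometry. Cells whose
#' conductivity tensor is at the insulator sentinel are excluded from the
#' system when `cfg$exclude_insulator` is set.
#'
#' @param mesh a [tet_mesh()].
#' @param conductivity a [conductivity_field()] with one tensor per cell.
#' @param bc a [boundary_spec()].
#' @param cfg a [solver_config()].
#' @return An object of class `fvm_system`.
#' @export
fvm_assemble <- function(mesh, conductivity, bc, cfg = solver_config()) {
  m <- nrow(mesh$cells)
  T6 <- conductivity$tensors
  if (nrow(T6) != m) stop("conductivity must provide one tensor per cell")
  tr_scale <- T6[, 1] + T6[, 2] + T6[, 3]
  if (any(!is.finite(tr_scale)) || any(tr_scale <= 0))
    stop("singular conductivity tensor at cell ",
         which(!is.finite(tr_scale) | tr_scale <= 0)[1])
  active <- if (cfg$exclude_insulator) tr_scale > 3e-12 else rep(TRUE, m)
  row_of <- rep(NA_integer_, m)
  row_of[active] <- seq_len(sum(active))
  n <- sum(active)
  if (n == 0) stop("no active cells")

  faces <- mesh_faces(mesh)
  ce <- cell_centroids(mesh) * MM
  fc <- faces$centroid * MM
  Av <- faces$area_vec * MM^2
  npts <- nrow(mesh$points)
  key_all <- face_keys(sorted_triples(faces$verts), npts)

  # resolve Dirichlet faces: named patches first, explicit faces second
  dir_idx <- integer(0); dir_val <- numeric(0)
  for (nm in names(bc$dirichlet)) {
    p <- mesh$patches[[nm]]
    if (is.null(p)) stop("Dirichlet patch not found on mesh: ", nm)
    idx <- match(face_keys(sorted_triples(p$faces), npts), key_all)
    dir_idx <- c(dir_idx, idx)
    dir_val <- c(dir_val, rep(unname(bc$dirichlet[nm]), length(idx)))
  }
  if (!is.null(bc$dirichlet_faces)) {
    idx <- match(face_keys(sorted_triples(as.matrix(bc$dirichlet_faces$faces)),
                           npts), key_all)
    dir_idx <- c(dir_idx, idx)
    dir_val <- c(dir_val, bc$dirichlet_faces$values)
  }
  if (!length(dir_idx)) stop("no Dirichlet faces: problem is ill-posed")
  if (any(faces$internal[dir_idx]))
    stop("Dirichlet faces must lie on the boundary")
  if (any(!active[faces$owner[dir_idx]]))
    stop("Dirichlet faces attached to insulator cells")

  # internal faces between two active cells
  int_idx <- which(faces$internal & active[faces$owner] &
                   active[pmax(faces$neighbour, 1L)])
  if (!length(int_idx)) stop("mesh has no internal faces between active cells")
  iO <- faces$owner[int_idx]; iN <- faces$neighbour[int_idx]
  A <- Av[int_idx, , drop = FALSE]
  Alen <- rownorm(A)
  nhat <- A / Alen
  d <- ce[iN, , drop = FALSE] - ce[iO, , drop = FALSE]
  Ad <- rowSums(A * d)
  if (any(Ad <= 0)) stop("face orientation error: A . d <= 0")
  coef_geo <- Alen^2 / Ad
  dOn <- rowSums((fc[int_idx, , drop = FALSE] - ce[iO, , drop = FALSE]) * nhat)
  dNn <- rowSums((ce[iN, , drop = FALSE] - fc[int_idx, , drop = FALSE]) * nhat)
  dOn <- pmax(dOn, 1e-30); dNn <- pmax(dNn, 1e-30)
  wO <- dNn / (dOn + dNn)
  TO <- T6[iO, , drop = FALSE]; TN <- T6[iN, , drop = FALSE]
  Ta <- TO * wO + TN * (1 - wO)             # arithmetic face tensor
  sOn <- sym6_quad(TO, nhat); sNn <- sym6_quad(TN, nhat)
  sfn <- if (cfg$face_interp == "harmonic")
    (dOn + dNn) / (dOn / sOn + dNn / sNn)
  else sym6_quad(Ta, nhat)
  a_f <- sfn * coef_geo

  # Dirichlet half-cell terms
  bO <- faces$owner[dir_idx]
  Ab <- Av[dir_idx, , drop = FALSE]
  Ablen <- rownorm(Ab)
  nb <- Ab / Ablen
  db <- fc[dir_idx, , drop = FALSE] - ce[bO, , drop = FALSE]
  Abd <- rowSums(Ab * db)
  if (any(Abd <= 0)) stop("Dirichlet face orientation error")
  coef_b <- Ablen^2 / Abd
  Tb <- T6[bO, , drop = FALSE]
  sbn <- sym6_quad(Tb, nb)
  a_b <- sbn * coef_b

  rO <- row_of[iO]; rN <- row_of[iN]; rB <- row_of[bO]
  M <- Matrix::sparseMatrix(
    i = c(rO, rN, rO, rN, rB),
    j = c(rN, rO, rO, rN, rB),
    x = c(-a_f, -a_f, a_f, a_f, a_b),
    dims = c(n, n))
  M <- methods::as(M, "CsparseMatrix")
  b_base <- rowsum_vec(rB, a_b * dir_val, n)

  # least-squares gradient structure: directed internal pairs + Dirichlet
  # pseudo-neighbours at face centroids, weights 1/distance
  g_cell <- c(rO, rN, rB)
  g_dx <- rbind(d, -d, db)
  g_other <- c(rN, rO, rep(NA_integer_, length(rB)))   # NA = Dirichlet
  g_dirval <- c(rep(NA_real_, 2 * length(rO)), dir_val)
  w2 <- 1 / rowSums(g_dx * g_dx)                        # (1/dist)^2 in LSQ
  Sw <- cbind(g_dx[, 1]^2, g_dx[, 2]^2, g_dx[, 3]^2,
              g_dx[, 1] * g_dx[, 2], g_dx[, 1] * g_dx[, 3],
              g_dx[, 2] * g_dx[, 3]) * w2
  S6 <- rowsum_mat(g_cell, Sw, n)
  si <- sym6_inv(S6)
  scale6 <- (S6[, 1] + S6[, 2] + S6[, 3])^3
  deficient <- which(!is.finite(si$det) | si$det < 1e-10 * scale6)
  if (length(deficient)) {
    # augment rank-deficient cells with second-ring neighbours
    adj <- cbind(c(rO, rN), c(rN, rO))
    adj_split <- split(adj[, 2], adj[, 1])
    extra_cell <- integer(0); extra_other <- integer(0)
    for (cc in deficient) {
      n1 <- adj_split[[as.character(cc)]]
      n2 <- unique(unlist(adj_split[as.character(n1)]))
      n2 <- setdiff(n2, c(cc, n1))
      extra_cell <- c(extra_cell, rep(cc, length(n2)))
      extra_other <- c(extra_other, n2)
    }
    if (length(extra_cell)) {
      act_idx <- which(active)
      dx2 <- ce[act_idx[extra_other], , drop = FALSE] -
        ce[act_idx[extra_cell], , drop = FALSE]
      g_cell <- c(g_cell, extra_cell)
      g_dx <- rbind(g_dx, dx2)
      g_other <- c(g_other, extra_other)
      g_dirval <- c(g_dirval, rep(NA_real_, length(extra_cell)))
      w2x <- 1 / rowSums(dx2 * dx2)
      Swx <- cbind(dx2[, 1]^2, dx2[, 2]^2, dx2[, 3]^2,
                   dx2[, 1] * dx2[, 2], dx2[, 1] * dx2[, 3],
                   dx2[, 2] * dx2[, 3]) * w2x
      S6 <- S6 + rowsum_mat(extra_cell, Swx, n)
      si <- sym6_inv(S6)
    }
    if (any(!is.finite(si$det[deficient])) ||
        any(si$det[deficient] < 1e-12 * scale6[deficient]))
      stop("gradient rank deficiency at cell(s) ",
           paste(utils::head(which(active)[deficient], 5), collapse = ", "))
  }
  w2 <- 1 / rowSums(g_dx * g_dx)

  structure(list(
    mesh = mesh, cfg = cfg, bc = bc, n = n, active = active, row_of = row_of,
    M = M, b_base = b_base, tensors = T6,
    int = list(idx = int_idx, rO = rO, rN = rN, A = A, Alen = Alen,
               nhat = nhat, d = d, coef_geo = coef_geo, wO = wO,
               Ta = Ta, sfn = sfn, a_f = a_f),
    dir = list(idx = dir_idx, rB = rB, A = Ab, Alen = Ablen, nhat = nb,
               d = db, coef_geo = coef_b, Tb = Tb, sbn = sbn, a_b = a_b,
               val = dir_val),
    grad = list(cell = g_cell, dx = g_dx, other = g_other,
                dirval = g_dirval, w2 = w2, Sinv = si$inv6)),
    class = "fvm_system")
}

# rowsum into a dense vector / matrix of given length (absent rows = 0)
rowsum_vec <- function(idx, x, n) {
  out <- numeric(n)
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

rowsum_mat <- function(idx, x, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# least-squares cell gradients for the active-cell vector phi (V), given the
# precomputed structure; returns n x 3 gradients in V/m
lsq_gradients <- function(sys, phi, dirichlet_scale = 1) {
  g <- sys$grad
  other_val <- ifelse(is.na(g$other), g$dirval * dirichlet_scale,
                      phi[pmax(g$other, 1L)])
  dphi <- other_val - phi[g$cell]
  rhs <- rowsum_mat(g$cell, g$dx * (g$w2 * dphi), sys$n)
  sym6_mv(g$Sinv, rhs)
}

# explicit non-orthogonal correction fluxes (internal + Dirichlet), given
# cell gradients; returns list(r_int, r_dir)
correction_fluxes <- function(sys, grad) {
  it <- sys$int; dr <- sys$dir
  gf <- grad[it$rO, , drop = FALSE] * it$wO +
    grad[it$rN, , drop = FALSE] * (1 - it$wO)
  Tg <- sym6_mv(it$Ta, gf)
  r_int <- rowSums(Tg * it$A) - rowSums(Tg * it$nhat) * it$Alen +
    it$sfn * (rowSums(gf * it$nhat) * it$Alen -
              rowSums(gf * it$d) * it$coef_geo)
  gb <- grad[dr$rB, , drop = FALSE]
  Tgb <- sym6_mv(dr$Tb, gb)
  r_dir <- rowSums(Tgb * dr$A) - rowSums(Tgb * dr$nhat) * dr$Alen +
    dr$sbn * (rowSums(gb * dr$nhat) * dr$Alen -
              rowSums(gb * dr$d) * dr$coef_geo)
  list(r_int = r_int, r_dir = r_dir)
}

rhs_with_correction <- function(sys, phi, alpha) {
  if (alpha == 0) return(list(b = sys$b_base, grad = NULL))
  grad <- lsq_gradients(sys, phi)
  r <- correction_fluxes(sys, grad)
  b <- sys$b_base +
    rowsum_vec(sys$int$rO, alpha * r$r_int, sys$n) -
    rowsum_vec(sys$int$rN, alpha * r$r_int, sys$n) +
    rowsum_vec(sys$dir$rB, alpha * r$r_dir, sys$n)
  list(b = b, grad = grad)
}

#' Solve for the electric potential
#'
#' Runs the outer non-orthogonality correction loop: the explicit
#' correction is recomputed from the current least-squares cell gradients,
#' the linear system is solved to the inner relative residual tolerance
#' with an IC(0)-preconditioned conjugate gradient, and the loop stops when
#' the normalized residual of the fully corrected system falls below the
#' outer tolerance. Deterministic for fixed inputs (zero initial guess).
#'
#' @param sys an `fvm_system` from [fvm_assemble()].
#' @param cfg optional [solver_config()] overriding the one in `sys`.
#' @return List with `phi` (V, per cell of the full mesh; `NA` for excluded
#'   insulator cells), `residuals` (outer residual history), and
#'   `inner_iterations`.
#' @export
solve_potential <- function(sys, cfg = NULL) {
  if (is.null(cfg)) cfg <- sys$cfg
  alpha <- switch(cfg$correction, none = 0, corrected = 1, limited = cfg$alpha)
  phi <- numeric(sys$n)
  hist <- numeric(0)
  inner_its <- integer(0)
  converged <- FALSE
  if (alpha == 0) {
    res <- ic0_pcg_solve(sys$M, sys$b_base, phi, cfg$inner_tol, cfg$max_inner)
    phi <- res$x
    hist <- res$relres
    inner_its <- res$iterations
    converged <- res$converged
  } else {
    # the explicit correction is iterated with under-relaxation of the
    # correction RHS (answer-invariant: the fixed point is unchanged);
    # convergence is judged on the fully corrected residual
    b_corr <- numeric(sys$n)
    for (outer in seq_len(cfg$max_outer)) {
      rc <- rhs_with_correction(sys, phi, alpha)
      b_full <- rc$b
      rvec <- b_full - as.vector(sys$M %*% phi)
      rel <- sqrt(sum(rvec^2)) / max(sqrt(sum(b_full^2)), 1e-300)
      if (outer > 1L) hist <- c(hist, rel)
      if (outer > 1L && rel < cfg$outer_tol) { converged <- TRUE; break }
      b_corr <- b_corr + cfg$relax * ((b_full - sys$b_base) - b_corr)
      res <- ic0_pcg_solve(sys$M, sys$b_base + b_corr, phi, cfg$inner_tol,
                           cfg$max_inner)
      phi <- res$x
      inner_its <- c(inner_its, res$iterations)
    }
  }
  if (!converged)
    stop("outer correction loop did not converge; residual history: ",
         paste(signif(hist, 3), collapse = ", "))
  phi_full <- rep(NA_real_, nrow(sys$mesh$cells))
  phi_full[sys$active] <- phi
  list(phi = phi_full, residuals = hist, inner_iterations = inner_its)
}

ic0_pcg_solve <- function(M, b, x0, tol, maxit) {
  .ic0_pcg(M@p, M@i, M@x, b, x0, tol, as.integer(maxit))
}

#' Least-squares gradient and electric field
#'
#' Computes per-cell gradients of a cell-centered scalar field by a
#' distance-weighted least-squares fit over face neighbours (with Dirichlet
#' boundary faces as pseudo-neighbours at the face centroids), and returns
#' the electric field `E = -grad(phi)` in V/m.
#'
#' @param sys an `fvm_system` from [fvm_assemble()].
#' @param phi potential per cell of the full mesh (V).
#' @return n_cells x 3 matrix, V/m (`NA` rows for excluded cells).
#' @export
gradient_lsq <- function(sys, phi) {
  g <- lsq_gradients(sys, phi[sys$active])
  out <- matrix(NA_real_, nrow(sys$mesh$cells), 3L)
  out[sys$active, ] <- -g
  out
}

#' Current density from field and conductivity
#'
#' `J = sigma E` per cell (full tensor product).
#'
#' @param E n x 3 electric field, V/m.
#' @param conductivity a [conductivity_field()].
#' @return n x 3 current density, A/m^2.
#' @export
current_density <- function(E, conductivity) {
  sym6_mv(conductivity$tensors, E)
}

#' Integrate current through a patch
#'
#' Sums the face-interpolated current density over a patch:
#' `I = sum_f (J_f . n_f) |A_f|`. For interface patches the face value is
#' the distance-weighted average of the two adjacent cells and the normal
#' is oriented away from `from_label` (electrode into scalp); for boundary
#' patches the owner-cell value and the outward normal are used.
#'
#' When the assembled system and the solved potential are supplied
#' (`sys`, `phi`), the integration instead sums the discrete finite-volume
#' face fluxes (implicit two-point part plus non-orthogonal correction),
#' which are conservative by construction -- the recommended way to measure
#' electrode currents across high-contrast contact interfaces.
#'
#' @param mesh a [tet_mesh()].
#' @param J n x 3 current density, A/m^2.
#' @param patch patch name.
#' @param from_label orient interface normals away from this compartment
#'   label (default: keep stored orientation).
#' @param sys optional `fvm_system` for conservative flux integration.
#' @param phi potential per cell (required with `sys`).
#' @param dirichlet_scale factor applied to the Dirichlet boundary values
#'   when the supplied `phi` has been rescaled (use the solution's `s`).
#' @return Current in ampere (signed).
#' @export
integrate_current <- function(mesh, J, patch, from_label = NULL,
                              sys = NULL, phi = NULL, dirichlet_scale = 1) {
  if (!is.null(sys)) {
    if (is.null(phi)) stop("phi is required for flux integration")
    return(integrate_patch_flux(sys, phi, patch, from_label, dirichlet_scale))
  }
  integrate_current_J(mesh, J, patch, from_label)
}

integrate_current_J <- function(mesh, J, patch, from_label = NULL) {
  p <- mesh$patches[[patch]]
  if (is.null(p) || nrow(p$faces) == 0) stop("empty or missing patch: ", patch)
  faces <- mesh_faces(mesh)
  npts <- nrow(mesh$points)
  idx <- match_patch_faces(faces, p$faces, npts)
  A <- faces$area_vec[idx, , drop = FALSE] * MM^2
  # honor the orientation stored in the patch (faces$area_vec is
  # owner-outward; flip where the patch lists the triple reversed)
  sv <- faces$verts[idx, , drop = FALSE]
  pf <- as.matrix(p$faces)
  pos <- (pf[, 1] == sv[, 1]) * 1L + (pf[, 1] == sv[, 2]) * 2L +
    (pf[, 1] == sv[, 3]) * 3L
  nxt <- sv[cbind(seq_along(pos), pos %% 3L + 1L)]
  flip_or <- pf[, 2] != nxt
  A[flip_or, ] <- -A[flip_or, , drop = FALSE]
  own <- faces$owner[idx]; nbr <- faces$neighbour[idx]
  internal <- faces$internal[idx]
  Jf <- J[own, , drop = FALSE]
  if (any(internal)) {
    ii <- which(internal)
    ce <- cell_centroids(mesh)
    fcn <- faces$centroid[idx[ii], , drop = FALSE]
    dO <- rownorm(fcn - ce[own[ii], , drop = FALSE])
    dN <- rownorm(ce[nbr[ii], , drop = FALSE] - fcn)
    w <- dN / (dO + dN)
    JO <- J[own[ii], , drop = FALSE]; JN <- J[nbr[ii], , drop = FALSE]
    JO[is.na(JO)] <- 0; JN[is.na(JN)] <- 0
    Jf[ii, ] <- JO * w + JN * (1 - w)
    if (!is.null(from_label)) {
      flip <- mesh$cell_labels[own[ii]] != from_label
      A[ii[flip], ] <- -A[ii[flip], , drop = FALSE]
    }
  }
  Jf[is.na(Jf)] <- 0
  sum(rowSums(Jf * A))
}

# conservative integration of the discrete FVM face fluxes over a patch
integrate_patch_flux <- function(sys, phi, patch, from_label = NULL,
                                 dirichlet_scale = 1) {
  mesh <- sys$mesh
  p <- mesh$patches[[patch]]
  if (is.null(p) || nrow(p$faces) == 0) stop("empty or missing patch: ", patch)
  npts <- nrow(mesh$points)
  key_p <- face_keys(sorted_triples(p$faces), npts)
  faces <- mesh_faces(mesh)
  key_all <- face_keys(sorted_triples(faces$verts), npts)
  fidx <- match(key_p, key_all)
  if (anyNA(fidx)) stop("patch face not present in mesh")
  phi_a <- phi[sys$active]
  grad <- lsq_gradients(sys, phi_a, dirichlet_scale)
  r <- correction_fluxes(sys, grad)
  alpha <- switch(sys$cfg$correction, none = 0, corrected = 1,
                  limited = sys$cfg$alpha)
  total <- 0
  it <- sys$int
  pos <- match(fidx, it$idx)
  ii <- which(!is.na(pos))
  if (length(ii)) {
    k <- pos[ii]
    # (sigma grad phi) . A oriented owner -> neighbour; current J = -sigma grad phi
    flux <- -(it$a_f[k] * (phi_a[it$rN[k]] - phi_a[it$rO[k]]) +
              alpha * r$r_int[k])
    if (!is.null(from_label)) {
      flip <- mesh$cell_labels[faces$owner[it$idx[k]]] != from_label
      flux[flip] <- -flux[flip]
    }
    total <- total + sum(flux)
  }
  dr <- sys$dir
  posd <- match(fidx, dr$idx)
  jj <- which(!is.na(posd))
  if (length(jj)) {
    k <- posd[jj]
    flux <- dr$a_b[k] * (dr$val[k] * dirichlet_scale - phi_a[dr$rB[k]]) +
      alpha * r$r_dir[k]
    total <- total - sum(flux)   # outward through the boundary
  }
  if (length(ii) + length(jj) == 0)
    stop("patch carries no resolved fluxes (insulator or Neumann faces)")
  total
}

#' Net current balance over the Dirichlet boundary
#'
#' Sums the discrete outward face fluxes over every Dirichlet face of the
#' system: `net` should vanish (discrete conservation) relative to `gross`,
#' the total positive influx (the delivered electrode current).
#'
#' @param sys an `fvm_system`.
#' @param phi solved potential per cell of the full mesh.
#' @param dirichlet_scale factor applied to the Dirichlet values when `phi`
#'   has been rescaled.
#' @return List with `net` and `gross` currents (A) and their ratio
#'   `imbalance`.
#' @export
boundary_current_balance <- function(sys, phi, dirichlet_scale = 1) {
  phi_a <- phi[sys$active]
  grad <- lsq_gradients(sys, phi_a, dirichlet_scale)
  r <- correction_fluxes(sys, grad)
  alpha <- switch(sys$cfg$correction, none = 0, corrected = 1,
                  limited = sys$cfg$alpha)
  dr <- sys$dir
  outflux <- -(dr$a_b * (dr$val * dirichlet_scale - phi_a[dr$rB]) +
               alpha * r$r_dir)
  net <- sum(outflux)
  gross <- sum(abs(outflux)) / 2
  list(net = net, gross = gross, imbalance = abs(net) / gross)
}

#' Scale a solution to the target current
#'
#' Multiplies potential, field and current density by
#' `s = I_target / I_measured` so that the re-integrated contact current
#' equals the requested stimulation current.
#'
#' @param sol a `field_solution` (see [solve_tes()]).
#' @param I_target target current, A (default: the one in the solution's
#'   boundary spec).
#' @return The scaled `field_solution` with `s` recorded.
#' @export
scale_solution <- function(sol, I_target = NULL) {
  if (is.null(I_target)) I_target <- sol$I_target
  if (is.null(sol$I_measured) || !is.finite(sol$I_measured) ||
      sol$I_measured == 0)
    stop("degenerate solution: measured current is zero")
  s <- I_target / sol$I_measured
  sol$phi <- sol$phi * s
  sol$E <- sol$E * s
  sol$J <- sol$J * s
  sol$s <- sol$s * s
  sol$I_measured <- sol$I_measured * s
  sol$I_target <- I_target
  sol
}

#' End-to-end potential/field/current solve
#'
#' Assembles and solves the quasi-static problem, derives `E` and `J`,
#' integrates the delivered current over the anode contact patch and scales
#' the linear solution to the target current.
#'
#' @param mesh a [tet_mesh()].
#' @param conductivity a [conductivity_field()].
#' @param bc a [boundary_spec()]; if `bc$contact_patches` is empty no
#'   current scaling is applied.
#' @param cfg a [solver_config()].
#' @return An object of class `field_solution`: `phi` (V), `E` (V/m), `J`
#'   (A/m^2), `s`, `I_measured` (A), `residuals`.
#' @export
solve_tes <- function(mesh, conductivity, bc, cfg = solver_config()) {
  sys <- fvm_assemble(mesh, conductivity, bc, cfg)
  pot <- solve_potential(sys)
  E <- gradient_lsq(sys, pot$phi)
  J <- current_density(E, conductivity)
  sol <- structure(list(phi = pot$phi, E = E, J = J, s = 1,
                        I_measured = NA_real_,
                        I_target = bc$target_current,
                        residuals = pot$residuals,
                        inner_iterations = pot$inner_iterations,
                        mesh = mesh, bc = bc, sys = sys),
                   class = "field_solution")
  if (length(bc$contact_patches)) {
    anode <- bc$contact_patches[1]
    elec_label <- attr(bc$contact_patches, "electrode_labels")
    from <- if (!is.null(elec_label)) elec_label[1] else NULL
    sol$I_measured <- abs(integrate_current(mesh, J, anode, from_label = from,
                                            sys = sys, phi = pot$phi))
    if (!is.null(bc$target_current)) sol <- scale_solution(sol, bc$target_current)
  }
  sol
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %d cells\n", length(x$phi)))
  cat(sprintf("  phi range [V]: %.4g .. %.4g\n",
              min(x$phi, na.rm = TRUE), max(x$phi, na.rm = TRUE)))
  cat(sprintf("  |E| max [V/m]: %.4g\n",
              max(rownorm(x$E[stats::complete.cases(x$E), , drop = FALSE]))))
  if (is.finite(x$I_measured))
    cat(sprintf("  I_measured: %.4g A, scale s: %.4g\n", x$I_measured, x$s))
  cat(sprintf("  outer residuals: %s\n",
              paste(signif(x$residuals, 3), collapse = " ")))
  invisible(x)
}
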