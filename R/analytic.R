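# Analytic (Legendre-series) solution for point-electrode stimulation of
# concentric spheres, the percentile Dirichlet construction and NRMSD:
# the quantitative verification engine for the finite-volume solver.
#
# In each layer the potential is phi = sum_n [A r^n + B r^-(n+1)] P_n(cos g)
# with phi and sigma dphi/dr continuous at interfaces, B = 0 innermost, and
# the surface condition given by the point source/sink pair. Coefficients
# are propagated inner -> outer per harmonic degree n in radius-scaled form
# to avoid overflow, and the final scale is fixed by the outer boundary
# condition sigma dphi/dr = (2n+1) I / (4 pi R^2) per degree.

#' Analytic point-electrode setup
#'
#' @param model a [layered_sphere_model()] (outermost radius = electrode
#'   sphere radius).
#' @param source,sink electrode positions as `c(colatitude, azimuth)` in
#'   radians on the outer sphere; default antipodal poles.
#' @param current injected current I, ampere.
#' @param N series truncation (>= 50).
#' @return An object of class `analytic_setup`.
#' @export
analytic_setup <- function(model, source = c(0, 0), sink = c(pi, 0),
                           current = 1e-3, N = 300L) {
  if (N < 50L) stop("series truncation N must be >= 50")
  sdir <- colat_az_to_unit(source)
  kdir <- colat_az_to_unit(sink)
  if (sum(abs(sdir - kdir)) < 1e-12) stop("source and sink must differ")
  structure(list(model = model, source = sdir, sink = kdir,
                 current = current, N = as.integer(N)),
            class = "analytic_setup")
}

colat_az_to_unit <- function(ca) {
  c(sin(ca[1]) * cos(ca[2]), sin(ca[1]) * sin(ca[2]), cos(ca[1]))
}

# per-degree layer coefficients: list with, per layer (inner -> outer),
# reference radius t_l (m) and scaled coefficient matrices a[n, l], b[n, l];
# plus the outer-condition scale k[n]
series_coefficients <- function(model, N, current) {
  radii_m <- rev(model$radii) * MM          # ascending, metres
  sig <- rev(model$conductivities)
  L <- length(radii_m)
  R <- radii_m[L]
  n <- seq_len(N)
  if (L == 1) {
    # homogeneous: A_n R^n = (2n+1) I / (4 pi sigma n R)
    a <- matrix(1, N, 1); b <- matrix(0, N, 1)
    vR <- sig[1] * n / R
    k <- ((2 * n + 1) * current / (4 * pi * R^2)) / vR
    return(list(tref = R, a = a, b = b, k = k, L = 1L))
  }
  tref <- c(radii_m[1], radii_m[seq_len(L - 1)])  # reference radius per layer
  a <- matrix(0, N, L); b <- matrix(0, N, L)
  a[, 1] <- 1; b[, 1] <- 0
  av <- rep(1, N); bv <- rep(0, N)
  t_now <- radii_m[1]
  for (j in seq_len(L - 1)) {
    sj <- radii_m[j]                        # interface radius
    u <- av + bv
    v <- sig[j] * (n * av - (n + 1) * bv) / sj
    av <- ((n + 1) * u + sj * v / sig[j + 1]) / (2 * n + 1)
    bv <- (n * u - sj * v / sig[j + 1]) / (2 * n + 1)
    a[, j + 1] <- av; b[, j + 1] <- bv
    t_next <- radii_m[j + 1]
    grow <- (t_next / sj)^n
    av <- av * grow
    bv <- bv / grow * (sj / t_next)         # (sj/t_next)^(n+1)
    t_now <- t_next
  }
  vR <- sig[L] * (n * av - (n + 1) * bv) / R
  if (any(!is.finite(vR)))
    stop("series coefficients overflow at this truncation; reduce N")
  k <- ((2 * n + 1) * current / (4 * pi * R^2)) / vR
  list(tref = tref, a = a, b = b, k = k, L = L)
}

#' Analytic potential of the layered sphere
#'
#' Evaluates the Legendre series at arbitrary interior points, with
#' Kahan-compensated accumulation of the per-degree terms.
#'
#' @param setup an [analytic_setup()].
#' @param pts n x 3 matrix of points (mm) inside the outer sphere.
#' @return Potential in volts per point.
#' @export
analytic_potential <- function(setup, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  model <- setup$model
  pc <- sweep(pts, 2, model$center)
  r_mm <- rownorm(pc)
  if (any(r_mm > model$radii[1] * (1 + 1e-9)))
    stop("points outside the electrode sphere")
  co <- series_coefficients(model, setup$N, setup$current)
  # layer index (inner -> outer): innermost layer 1 holds r <= smallest radius
  radii_asc <- rev(model$radii)
  layer <- findInterval(r_mm, radii_asc * (1 + 1e-12)) + 1L
  layer[layer > co$L] <- co$L
  r_m <- r_mm * MM
  rhat <- pc / pmax(r_mm, 1e-30)
  rhat[r_mm < 1e-30, ] <- 0
  c_src <- pmin(1, pmax(-1, as.vector(rhat %*% setup$source)))
  c_snk <- pmin(1, pmax(-1, as.vector(rhat %*% setup$sink)))
  phi <- numeric(nrow(pts))
  for (l in sort(unique(layer))) {
    sel <- which(layer == l)
    t_l <- if (co$L == 1) co$tref else co$tref[l]
    phi[sel] <- series_sum(r_m[sel] / t_l, c_src[sel], c_snk[sel],
                           co$a[, l], co$b[, l], co$k, setup$N)
  }
  phi
}

# Kahan-compensated accumulation of
# sum_n k_n (a_n x^n + b_n x^-(n+1)) (P_n(cs) - P_n(ck))
series_sum <- function(x, cs, ck, a_n, b_n, k_n, N) {
  m <- length(x)
  has_b <- any(b_n != 0)          # innermost layer: B = 0, and 1/x may overflow
  acc <- numeric(m); comp <- numeric(m)
  pow_a <- x                      # x^n
  inv_x <- if (has_b) 1 / x else numeric(m)
  pow_b <- inv_x * inv_x          # x^-(n+1)
  Ps0 <- rep(1, m); Ps1 <- cs     # P_{n-1}, P_n at cs
  Pk0 <- rep(1, m); Pk1 <- ck
  for (n in seq_len(N)) {
    term <- k_n[n] * (a_n[n] * pow_a + b_n[n] * pow_b) * (Ps1 - Pk1)
    y <- term - comp
    t <- acc + y
    comp <- (t - acc) - y
    acc <- t
    if (n < N) {
      Ps2 <- ((2 * n + 1) * cs * Ps1 - n * Ps0) / (n + 1)
      Pk2 <- ((2 * n + 1) * ck * Pk1 - n * Pk0) / (n + 1)
      Ps0 <- Ps1; Ps1 <- Ps2; Pk0 <- Pk1; Pk1 <- Pk2
      pow_a <- pow_a * x
      pow_b <- pow_b * inv_x
    }
  }
  acc
}

#' Closed-form homogeneous-sphere point-electrode potential
#'
#' Independent closed form for a homogeneous sphere of radius R with a
#' surface point source (+I) and sink (-I):
#' `phi = I/(4 pi sigma R) * [f(t, c_src) - f(t, c_snk)]` with
#' `f(t, c) = 2/S + log(2 / (1 - t c + S))`, `S = sqrt(1 - 2 t c + t^2)`,
#' `t = r/R`. Used as the analytic-limit oracle for the Legendre series.
#'
#' @param radius sphere radius, mm.
#' @param sigma conductivity, S/m.
#' @param pts n x 3 points, mm.
#' @param source,sink electrode positions `c(colatitude, azimuth)`, radians.
#' @param current injected current, A.
#' @param center sphere center, mm.
#' @return Potential in volts per point.
#' @export
homogeneous_sphere_potential <- function(radius, sigma, pts,
                                         source = c(0, 0), sink = c(pi, 0),
                                         current = 1e-3, center = c(0, 0, 0)) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  pc <- sweep(pts, 2, center)
  r <- rownorm(pc)
  t <- r / radius
  rhat <- pc / pmax(r, 1e-30)
  f <- function(cg) {
    S <- sqrt(pmax(1 - 2 * t * cg + t^2, 0))
    2 / S + log(2 / pmax(1 - t * cg + S, 1e-300))
  }
  cs <- pmin(1, pmax(-1, as.vector(rhat %*% colat_az_to_unit(source))))
  ck <- pmin(1, pmax(-1, as.vector(rhat %*% colat_az_to_unit(sink))))
  current / (4 * pi * sigma * radius * MM) * (f(cs) - f(ck))
}

#' Percentile Dirichlet construction
#'
#' Evaluates the analytic potential at every exterior face centroid of the
#' mesh and turns the faces whose |phi| exceeds the given percentile of
#' |phi| into Dirichlet faces carrying their analytic values; all remaining
#' boundary faces stay zero-gradient Neumann.
#'
#' @param setup an [analytic_setup()] (its sphere must enclose the mesh).
#' @param mesh a [tet_mesh()] whose outer boundary lies strictly inside the
#'   electrode sphere.
#' @param percentile percentile of |phi| in `[0, 100)`; 0 makes every
#'   boundary face Dirichlet.
#' @param target_current target current for later scaling (optional).
#' @return A [boundary_spec()] with face-level Dirichlet values.
#' @export
percentile_dirichlet <- function(setup, mesh, percentile = 85,
                                 target_current = NULL) {
  if (percentile >= 100)
    stop("percentile >= 100 selects no Dirichlet faces: ill-posed")
  faces <- mesh_faces(mesh)
  bidx <- which(!faces$internal)
  phi <- analytic_potential(setup, faces$centroid[bidx, , drop = FALSE])
  sel <- if (percentile <= 0) rep(TRUE, length(phi))
  else abs(phi) > stats::quantile(abs(phi), percentile / 100, names = FALSE)
  boundary_spec(dirichlet = NULL,
                dirichlet_faces = list(faces = faces$verts[bidx[sel], ,
                                                           drop = FALSE],
                                       values = phi[sel]),
                target_current = target_current)
}

#' Normalized root-mean-square deviation
#'
#' `100 * sqrt(mean((a - b)^2)) / norm`, in percent, with the reference
#' field `b` supplying the normalizer: its range (default), its mean
#' absolute value, or its maximum absolute value.
#'
#' @param a test field (e.g. finite-volume potential per cell).
#' @param b reference field (e.g. analytic potential per cell).
#' @param normalizer `"range"`, `"mean"` or `"max"`.
#' @return Percent NRMSD (scalar).
#' @export
nrmsd <- function(a, b, normalizer = c("range", "mean", "max")) {
  normalizer <- match.arg(normalizer)
  if (length(a) != length(b)) stop("fields must have the same length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  norm <- switch(normalizer,
                 range = max(b) - min(b),
                 mean = mean(abs(b)),
                 max = max(abs(b)))
  if (norm <= 0) stop("constant reference field: normalizer is zero")
  100 * sqrt(mean((a - b)^2)) / norm
}

#' Layered-sphere verification run
#'
#' End-to-end quantitative verification of the finite-volume solver against
#' the analytic solution: build a body-fitted mesh of the numerical sphere
#' (outer radius = analytic outer radius minus `offset`), impose the
#' analytic potential as Dirichlet data on the boundary faces above the
#' given percentile of |phi| (zero-gradient Neumann elsewhere), solve, and
#' compare against the analytic potential at every cell centroid.
#'
#' @param model analytic [layered_sphere_model()] (default: the 92/85/80 mm
#'   scalp/skull/brain phantom, [three_layer_head_model()]).
#' @param subdivisions,radial_layers mesh resolution, passed to
#'   [generate_layered_sphere_mesh()].
#' @param percentile Dirichlet percentile (default 85).
#' @param N series truncation for the analytic evaluation.
#' @param current injected electrode current, A.
#' @param offset numerical sphere shrink, mm (default 2).
#' @param cfg a [solver_config()].
#' @param n_profile number of samples of the radial (electrode-axis) line
#'   profile.
#' @return List with `nrmsd` (range-normalized, percent), `nrmsd_by`
#'   (all three normalizers), `n_cells`, `phi` (FVM), `phi_analytic`,
#'   `profile` (data frame along the electrode axis), `mesh`, `residuals`.
#' @export
sphere_verification <- function(model = three_layer_head_model(),
                                subdivisions = 3L, radial_layers = NULL,
                                percentile = 85, N = 600L, current = 1e-3,
                                offset = 2, cfg = solver_config(),
                                n_profile = 200L) {
  num_radii <- model$radii
  num_radii[1] <- num_radii[1] - offset
  num_model <- layered_sphere_model(num_radii, model$conductivities,
                                    model$center)
  mesh <- generate_layered_sphere_mesh(num_model, subdivisions, radial_layers)
  setup <- analytic_setup(model, current = current, N = N)
  bc <- percentile_dirichlet(setup, mesh, percentile)
  sig <- stats::setNames(model$conductivities,
                         as.character(seq_along(model$conductivities)))
  cond <- isotropic_field(mesh, tissue_table(sig))
  sys <- fvm_assemble(mesh, cond, bc, cfg)
  pot <- solve_potential(sys)
  ce <- cell_centroids(mesh)
  phi_ref <- analytic_potential(setup, ce)
  by <- c(range = nrmsd(pot$phi, phi_ref, "range"),
          mean = nrmsd(pot$phi, phi_ref, "mean"),
          max = nrmsd(pot$phi, phi_ref, "max"))
  # line profile along the electrode axis (z)
  z <- seq(-num_radii[1] * 0.999, num_radii[1] * 0.999, length.out = n_profile)
  ppts <- cbind(model$center[1], model$center[2], model$center[3] + z)
  prof_num <- sample_line_values(mesh, pot$phi, ppts)
  prof <- data.frame(z = z, phi_fvm = prof_num$values,
                     phi_analytic = analytic_potential(setup, ppts),
                     label = prof_num$labels)
  list(nrmsd = unname(by["range"]), nrmsd_by = by, n_cells = nrow(mesh$cells),
       phi = pot$phi, phi_analytic = phi_ref, profile = prof,
       mesh = mesh, residuals = pot$residuals)
}
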