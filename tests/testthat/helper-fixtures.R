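# Shared fixtures and independent oracles. Oracles here are deliberately
# written without reusing the package's internal geometry helpers, so they
# provide a second, independent route to the same quantities.

# a regular triangulated plane z = 0 on [0, n] x [0, n]
flat_plane <- function(n = 20L, spacing = 1) {
  g <- expand.grid(x = 0:n, y = 0:n)
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  tris <- NULL
  for (j in 0:(n - 1L)) for (i in 0:(n - 1L)) {
    a <- j * (n + 1L) + i + 1L
    tris <- rbind(tris, c(a, a + 1L, a + n + 2L), c(a, a + n + 2L, a + n + 1L))
  }
  tri_surface(v, tris, "plane")
}

# two mirror-image tetrahedra sharing the equilateral face z = 0; the
# shared-face normal is the z axis and both apexes sit above/below the
# face centroid, so non-orthogonality and skewness are exactly zero
mirror_tet_pair <- function(shear = 0) {
  base <- rbind(c(1, 0, 0),
                c(-0.5, sqrt(3) / 2, 0),
                c(-0.5, -sqrt(3) / 2, 0))
  apex_top <- c(0 + shear, 0, 1)
  apex_bot <- c(0, 0, -1)
  pts <- rbind(base, apex_top, apex_bot)
  cells <- rbind(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 5L))
  tet_mesh(pts, cells, c(1L, 1L))
}

# independent point-in-polyhedron oracle: vertical (+z) ray crossing count
# via 2-D barycentric containment in the xy projection -- a different
# algorithm from the package's jittered Moeller-Trumbore majority vote
oracle_inside <- function(surface, pts) {
  v <- surface$vertices
  tr <- surface$triangles
  cnt <- integer(nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]; pz <- pts[, 3]
  for (q in seq_len(nrow(tr))) {
    a <- v[tr[q, 1], ]; b <- v[tr[q, 2], ]; c_ <- v[tr[q, 3], ]
    det <- (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])
    if (abs(det) < 1e-14) next
    u <- ((px - a[1]) * (c_[2] - a[2]) - (py - a[2]) * (c_[1] - a[1])) / det
    w <- ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])) / det
    hit <- u >= 0 & w >= 0 & (u + w) <= 1
    if (!any(hit)) next
    ztri <- a[3] + u[hit] * (b[3] - a[3]) + w[hit] * (c_[3] - a[3])
    idx <- which(hit)[ztri > pz[hit]]
    cnt[idx] <- cnt[idx] + 1L
  }
  cnt %% 2L == 1L
}

# analytic shell volume of layer i of a layered sphere model
shell_volume <- function(model, i) {
  r_out <- model$radii[i]
  r_in <- if (i < length(model$radii)) model$radii[i + 1] else 0
  4 / 3 * pi * (r_out^3 - r_in^3)
}

# series-resistance closed form for a two-layer slab of equal thickness L
# (mm) per layer, potentials vL / vR at the outer walls; returns phi(x)
two_layer_phi <- function(sigma1, sigma2, L, vL, vR) {
  R1 <- L / sigma1; R2 <- L / sigma2
  v_if <- vL + (vR - vL) * R1 / (R1 + R2)
  function(x) ifelse(x <= L,
                     vL + (v_if - vL) * x / L,
                     v_if + (vR - v_if) * (x - L) / L)
}

# small two-electrode sphere phantom used by the solver/current tests
small_electrode_phantom <- function(target_current = 1e-3) {
  mod <- layered_sphere_model(c(30, 25), c(0.465, 0.33))
  mesh <- generate_layered_sphere_mesh(mod, 2L, c(2L, 10L))
  mesh <- tag_electrode_on_mesh(
    mesh, electrode_spec("anode", "circle", 7, thickness = 4, role = "anode"),
    c(0, 0, 30))
  mesh <- tag_electrode_on_mesh(
    mesh, electrode_spec("cathode", "circle", 7, thickness = 4,
                         role = "cathode"), c(0, 0, -30))
  cond <- isotropic_field(mesh, tissue_table(
    c("1" = 0.465, "2" = 0.33, "3" = 29.4, "4" = 29.4)))
  bc <- electrode_boundary_spec(mesh, "anode", "cathode",
                                target_current = target_current)
  list(mesh = mesh, cond = cond, bc = bc)
}
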