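# Finite-volume solver: assembly structure, exactness on closed-form
# problems, gradients, current density, integration and scaling.

slab_bc <- function(vL = 5, vR = -5)
  boundary_spec(dirichlet = c(xmin = vL, xmax = vR), target_current = 1e-3)

tight <- solver_config(inner_tol = 1e-13, outer_tol = 1e-12,
                       max_outer = 300L)

test_that("assembly yields a conservative symmetric system", {
  mesh <- generate_slab_mesh(c(4, 2, 2), 1)
  cond <- isotropic_field(mesh, tissue_table(c("1" = 1)))
  sys <- fvm_assemble(mesh, cond, slab_bc())
  expect_true(Matrix::isSymmetric(sys$M))
  # interior rows (no Dirichlet face) sum to zero: discrete conservation
  rs <- Matrix::rowSums(sys$M)
  has_dir <- sort(unique(sys$dir$rB))
  interior <- setdiff(seq_len(sys$n), has_dir)
  expect_lt(max(abs(rs[interior])), 1e-12 * max(abs(sys$M@x)))
  # doubling sigma doubles the matrix and leaves phi unchanged
  sys2 <- fvm_assemble(mesh, isotropic_field(mesh, tissue_table(c("1" = 2))),
                       slab_bc())
  expect_equal(sys2$M@x, 2 * sys$M@x, tolerance = 1e-14)
  p1 <- solve_potential(sys, tight)$phi
  p2 <- solve_potential(sys2, tight)$phi
  expect_equal(p1, p2, tolerance = 1e-9)
  # orthogonal mesh: explicit correction identically zero
  g <- tesfvm:::lsq_gradients(sys, p1[sys$active])
  r <- tesfvm:::correction_fluxes(sys, g)
  expect_lt(max(abs(r$r_int)), 1e-12 * max(sys$int$a_f * abs(range(p1))))
  expect_error(fvm_assemble(mesh, conductivity_field(matrix(0, nrow(mesh$cells), 6)),
                            slab_bc()), "singular")
})

test_that("linear fields are reproduced to round-off on conforming meshes", {
  # orthogonal slab
  mesh <- generate_slab_mesh(c(8, 2, 2), 1)
  cond <- isotropic_field(mesh, tissue_table(c("1" = 1)))
  sys <- fvm_assemble(mesh, cond, slab_bc(), tight)
  pot <- solve_potential(sys)
  phi_exact <- 5 - 10 * cell_centroids(mesh)[, 1] / 8
  expect_lt(max(abs(pot$phi - phi_exact)), 1e-10)
  # non-orthogonal voxel-split mesh: still exact at the corrected fixed point
  img <- labeled_image(array(1L, c(6, 2, 2)))
  vm <- tetrahedralize_labeled_image(img)
  vm <- define_patch(vm, "xmin", function(fc) fc[, 1] < -0.49)
  vm <- define_patch(vm, "xmax", function(fc) fc[, 1] > 5.49)
  sysv <- fvm_assemble(vm, isotropic_field(vm, tissue_table(c("1" = 1))),
                       slab_bc(), tight)
  potv <- solve_potential(sysv)
  phiv <- 5 - 10 * (cell_centroids(vm)[, 1] + 0.5) / 6
  expect_lt(max(abs(potv$phi - phiv)), 1e-10)
  # E = -grad phi recovered exactly for the linear field (V/m)
  E <- gradient_lsq(sysv, potv$phi)
  expect_lt(max(abs(E[, 1] - (10 / 6) * 1e3)), 1e-6)
  expect_lt(max(abs(E[, 2:3])), 1e-6)
})

test_that("two-layer slab matches the series-resistance closed form", {
  lab <- array(1L, c(8, 2, 2)); lab[5:8, , ] <- 2L
  mesh <- generate_slab_mesh(c(8, 2, 2), 1, labels = lab)
  cond <- isotropic_field(mesh, tissue_table(c("1" = 1, "2" = 0.5)))
  cfg <- solver_config(inner_tol = 1e-13, outer_tol = 1e-12,
                       max_outer = 300L, face_interp = "harmonic")
  sys <- fvm_assemble(mesh, cond, slab_bc(), cfg)
  pot <- solve_potential(sys)
  phi_fun <- two_layer_phi(1, 0.5, 4, 5, -5)
  expect_lt(max(abs(pot$phi - phi_fun(cell_centroids(mesh)[, 1]))), 1e-8)
  # interface potential from the closed form: phi(4) = 5 - 10/3
  expect_equal(phi_fun(4), 5 - 10 / 3, tolerance = 1e-12)
  # |E2| / |E1| = sigma1/sigma2 = 2 away from the interface
  E <- gradient_lsq(sys, pot$phi)
  xs <- cell_centroids(mesh)[, 1]
  e1 <- abs(E[xs < 3, 1]); e2 <- abs(E[xs > 5, 1])
  expect_lt(max(abs(e2 / mean(e1) - 2)), 1e-8)
  # net boundary current imbalance well below 0.1 % of the through current
  bal <- boundary_current_balance(sys, pot$phi)
  expect_lt(bal$imbalance, 1e-3)
})

test_that("least-squares gradient is exact for affine and first-order for x^2", {
  mesh <- generate_slab_mesh(c(6, 2, 2), 1)
  cond <- isotropic_field(mesh, tissue_table(c("1" = 1)))
  sys <- fvm_assemble(mesh, cond, slab_bc())
  ce <- cell_centroids(mesh)
  phi_lin <- 2 * ce[, 1] - 3 * ce[, 2] + 0.5 * ce[, 3] + 1
  # pseudo-neighbour Dirichlet values do not match this field, so restrict
  # to a pure-interior check via the internal-pair structure: use a bc-free
  # system (all-Neumann is singular, so check the fitted gradient directly)
  g <- tesfvm:::lsq_gradients(sys, phi_lin)
  interior <- setdiff(seq_len(sys$n), unique(sys$dir$rB))
  expect_lt(max(abs(sweep(g[interior, ], 2, c(2, -3, 0.5) / 1e-3))), 1e-6)
  expect_equal(max(abs(tesfvm:::lsq_gradients(sys, rep(7, sys$n))[interior, ])),
               0, tolerance = 1e-9)
  # phi = x^2 on refined bars: gradient error shrinks at first order
  err <- vapply(c(8L, 16L, 32L), function(nx) {
    m <- generate_slab_mesh(c(nx, 2, 2), 8 / nx)
    s <- fvm_assemble(m, isotropic_field(m, tissue_table(c("1" = 1))),
                      slab_bc())
    cc <- cell_centroids(m)
    gg <- tesfvm:::lsq_gradients(s, cc[, 1]^2)
    int <- setdiff(seq_len(s$n), unique(s$dir$rB))
    max(abs(gg[int, 1] - 2 * cc[int, 1] / 1e-3)) * 1e-3
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3] / err[1], 0.5)
})

test_that("current density applies the full conductivity tensor", {
  cf <- conductivity_field(rbind(c(2, 2, 2, 0, 0, 0)))
  expect_equal(current_density(matrix(c(1, 0, 0), 1), cf),
               matrix(c(2, 0, 0), 1))
  aniso <- conductivity_field(rbind(c(0.398, 0.0398, 0.0398, 0, 0, 0)))
  expect_equal(current_density(matrix(c(0, 1, 0), 1), aniso),
               matrix(c(0, 0.0398, 0), 1))
  expect_equal(current_density(matrix(0, 1, 3), aniso), matrix(0, 1, 3))
})

test_that("patch current integration is exact for uniform J", {
  mesh <- generate_slab_mesh(c(10, 10, 2), 1)   # zmax patch: 1 cm^2
  J <- matrix(rep(c(0, 0, 1), each = nrow(mesh$cells)), ncol = 3)
  I <- integrate_current(mesh, J, "zmax")
  expect_equal(I, 1e-4, tolerance = 1e-12)      # 1 A/m^2 through 1 cm^2
  # reversing the face orientation flips the sign
  rev_mesh <- mesh
  rev_mesh$patches$zmax$faces <- rev_mesh$patches$zmax$faces[, c(1, 3, 2)]
  expect_equal(integrate_current(rev_mesh, J, "zmax"), -1e-4,
               tolerance = 1e-12)
  expect_error(integrate_current(mesh, J, "nope"), "missing")
})

test_that("solved electrode problems conserve current and scale exactly", {
  ph <- small_electrode_phantom()
  cfg <- solver_config(inner_tol = 1e-10, outer_tol = 1e-7, max_outer = 400L)
  sol <- solve_tes(ph$mesh, ph$cond, ph$bc, cfg)
  # re-integrated anode current equals the 1 mA target within 0.5 %
  Ia <- integrate_current(ph$mesh, sol$J, "anode_contact", from_label = 3L,
                          sys = sol$sys, phi = sol$phi,
                          dirichlet_scale = sol$s)
  expect_lt(abs(abs(Ia) - 1e-3) / 1e-3, 0.005)
  # anode and cathode currents agree within 0.1 %
  Ic <- integrate_current(ph$mesh, sol$J, "cathode_contact", from_label = 4L,
                          sys = sol$sys, phi = sol$phi,
                          dirichlet_scale = sol$s)
  expect_lt(abs(abs(Ia) - abs(Ic)) / abs(Ia), 1e-3)
  # net boundary imbalance < 0.1 % of the electrode current
  bal <- boundary_current_balance(sol$sys, sol$phi, dirichlet_scale = sol$s)
  expect_lt(bal$imbalance, 1e-3)
  # scaling: halving / doubling is exact
  s2 <- scale_solution(sol, 2e-3)
  expect_identical(s2$phi, sol$phi * 2)
  expect_identical(s2$E, sol$E * 2)
  expect_identical(s2$J, sol$J * 2)
  expect_equal(scale_solution(sol, sol$I_measured)$s, sol$s)
  bad <- sol; bad$I_measured <- 0
  expect_error(scale_solution(bad, 1e-3), "degenerate")
})

test_that("scale factor follows s = I_target / I_measured", {
  sol <- structure(list(phi = 1, E = matrix(1, 1, 3), J = matrix(1, 1, 3),
                        s = 1, I_measured = 2e-3, I_target = 2e-3),
                   class = "field_solution")
  out <- scale_solution(sol, 1e-3)
  expect_equal(out$s, 0.5)
  expect_equal(out$phi, 0.5)
})

test_that("maximum principle and Dirichlet linearity hold", {
  lab <- array(1L, c(6, 3, 3)); lab[4:6, , ] <- 2L
  mesh <- generate_slab_mesh(c(6, 3, 3), 1, labels = lab)
  cond <- isotropic_field(mesh, tissue_table(c("1" = 0.465, "2" = 0.01)))
  sys <- fvm_assemble(mesh, cond, slab_bc(3, -2), tight)
  pot <- solve_potential(sys)
  expect_true(all(pot$phi <= 3 + 1e-10) && all(pot$phi >= -2 - 1e-10))
  # scaling all Dirichlet values scales phi linearly
  sys4 <- fvm_assemble(mesh, cond, slab_bc(12, -8), tight)
  expect_equal(solve_potential(sys4)$phi, 4 * pot$phi, tolerance = 1e-8)
})
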