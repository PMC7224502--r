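# Conductivity tensor assignment: isotropic tables and the
# volume-constraint anisotropic mapping.

test_that("isotropic fields assign sigma * I per compartment", {
  mesh <- generate_slab_mesh(c(2, 2, 2), 1,
                             labels = array(rep(1:2, 4), c(2, 2, 2)))
  cf <- isotropic_field(mesh, tissue_table(c("1" = 0.33, "2" = 1)))
  t1 <- cf$tensors[mesh$cell_labels == 1L, , drop = FALSE]
  expect_true(all(t1[, 1:3] == 0.33) && all(t1[, 4:6] == 0))
  expect_true(all(cf$tensors[mesh$cell_labels == 2L, 1:3] == 1))
  # air sentinel stays SPD with min eigenvalue 1e-15
  cfa <- isotropic_field(mesh, tissue_table(c("1" = 1e-15, "2" = 1)))
  eg <- eigen(tesfvm:::sym6_to_mat(cfa$tensors[1, ]))$values
  expect_equal(min(eg), 1e-15)
  expect_true(min(eg) > 0)
  expect_error(isotropic_field(mesh, tissue_table(c("1" = 0.33))),
               "missing")
})

test_that("volume-constraint tensor solves the two constraint equations", {
  sig <- volume_constraint_tensor(diag(c(3, 1, 1)), 0.126, 10)
  expect_equal(diag(sig), c(0.126 * sqrt(10), 0.126 / sqrt(10),
                            0.126 / sqrt(10)), tolerance = 1e-12)
  expect_equal(sig[lower.tri(sig)], c(0, 0, 0))
  expect_equal(0.126 * sqrt(10), 0.39845, tolerance = 1e-4)
  # identity: product of extreme eigenvalues is sigma_wm^2 for any input
  set.seed(5)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3); D <- A + t(A)
    ev <- eigen(volume_constraint_tensor(D, 0.126), symmetric = TRUE)$values
    expect_equal(max(ev) * min(ev), 0.126^2, tolerance = 1e-12)
  }
  # rotation equivariance
  set.seed(6)
  A <- matrix(rnorm(9), 3); D <- A + t(A)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  lhs <- volume_constraint_tensor(R %*% D %*% t(R), 0.126)
  rhs <- R %*% volume_constraint_tensor(D, 0.126) %*% t(R)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  expect_error(volume_constraint_tensor(matrix(rnorm(9), 3), 0.126),
               "symmetric")
})

test_that("random tensors keep SPD, ratio-10 and geometric-mean invariants", {
  set.seed(7)
  for (i in 1:200) {
    A <- matrix(rnorm(9), 3); D <- A + t(A)
    sig <- volume_constraint_tensor(D, 0.126, 10)
    expect_lt(max(abs(sig - t(sig))), 1e-12)
    ev <- eigen(sig, symmetric = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(max(ev) / min(ev), 10, tolerance = 1e-9)
    expect_equal(sqrt(max(ev) * min(ev)), 0.126, tolerance = 1e-12)
  }
  # isotropic input: output eigenvalues exactly {s_main, s_aux, s_aux}
  ev <- eigen(volume_constraint_tensor(diag(3) * 2.5, 0.126),
              symmetric = TRUE)$values
  expect_equal(sort(ev), sort(c(0.126 * sqrt(10), rep(0.126 / sqrt(10), 2))),
               tolerance = 1e-12)
})

test_that("spd_repair is total: NaN fallback and eigenvalue clamping", {
  expect_equal(spd_repair(matrix(NaN, 3, 3), fallback = 0.126),
               diag(rep(0.126, 3)))
  good <- diag(c(2, 1, 0.5))
  expect_equal(spd_repair(good), good)
  bad <- diag(c(1, 0, -0.1))
  ev <- eigen(spd_repair(bad), symmetric = TRUE)$values
  expect_equal(sort(ev), sort(c(1, 1e-12, 1e-12)), tolerance = 1e-15)
})

test_that("tensor transfer overwrites white matter only, with provenance", {
  labels <- array(1L, c(4, 4, 4)); labels[, , 3:4] <- 2L
  mesh <- generate_slab_mesh(c(4, 4, 4), 1, labels = labels)
  cond <- isotropic_field(mesh, tissue_table(c("1" = 0.33, "2" = 0.126)))
  tf <- uniform_tensor_field(c(8, 8, 8), diag(c(3, 1, 1)), spacing = 1,
                             origin = c(-1, -1, -1))
  out <- tensors_to_cells(tf, mesh, cond, wm_label = 2L, sigma_wm = 0.126)
  wm <- mesh$cell_labels == 2L
  expect_true(all(out$provenance[wm] == "anisotropic"))
  expect_true(all(out$provenance[!wm] == "isotropic"))
  expect_equal(sum(out$provenance == "anisotropic"), sum(wm))
  expect_equal(out$tensors[which(wm)[1], 1:3],
               c(0.126 * sqrt(10), 0.126 / sqrt(10), 0.126 / sqrt(10)),
               tolerance = 1e-12)
  expect_true(all(out$tensors[!wm, 1] == 0.33))
})

test_that("swirl field aligns principal conductivity with the azimuth", {
  mesh <- generate_slab_mesh(c(20, 20, 1), 2, origin = c(-20, -20, -1))
  cond <- isotropic_field(mesh, tissue_table(c("1" = 0.126)))
  tf <- swirl_tensor_field(c(160, 160, 10), spacing = 0.25)
  out <- tensors_to_cells(tf, mesh, cond, wm_label = 1L, sigma_wm = 0.126)
  ce <- cell_centroids(mesh)
  r <- sqrt(ce[, 1]^2 + ce[, 2]^2)
  sel <- which(r > 14)                     # away from the axis
  worst <- 0
  for (q in sel[seq(1, length(sel), by = 7)]) {
    sig <- tesfvm:::sym6_to_mat(out$tensors[q, ])
    e1 <- eigen(sig, symmetric = TRUE)$vectors[, 1]
    az <- c(-ce[q, 2], ce[q, 1], 0) / r[q]
    ang <- acos(min(1, abs(sum(e1 * az)))) * 180 / pi
    worst <- max(worst, ang)
  }
  expect_lt(worst, 1)
})
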