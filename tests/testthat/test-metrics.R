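# Comparison statistics: percentiles, hotspots, difference maps, line
# sampling.

test_that("magnitude statistics follow the order-statistics oracle", {
  m <- generate_slab_mesh(c(5, 5, 1), 1)              # 25 voxels x 12 = 300 cells
  mag <- seq_len(nrow(m$cells))
  st <- magnitude_stats(cbind(mag, 0, 0), m, 1L)
  n <- length(mag)
  # R type-7 quantile oracle computed directly
  q7 <- function(p) { h <- (n - 1) * p + 1; lo <- floor(h); mag[lo] + (h - lo) * (mag[min(lo + 1, n)] - mag[lo]) }
  expect_equal(st$p90, q7(0.90))
  expect_equal(st$p95, q7(0.95))
  expect_equal(st$p99, q7(0.99))
  expect_true(st$p90 <= st$p95 && st$p95 <= st$p99)
  expect_equal(st$mean, mean(mag))
  # constant field
  stc <- magnitude_stats(cbind(rep(3, nrow(m$cells)), 0, 0), m, 1L)
  expect_equal(unlist(stc[c("mean", "p90", "p95", "p99")]),
               c(mean = 3, p90 = 3, p95 = 3, p99 = 3))
  expect_equal(stc$sd, 0)
  # homogeneity under scaling
  st2 <- magnitude_stats(cbind(2 * mag, 0, 0), m, 1L)
  expect_equal(st2$p95, 2 * st$p95)
  expect_equal(st2$mean, 2 * st$mean)
  expect_error(magnitude_stats(cbind(mag, 0, 0), m, 99L), "empty")
})

test_that("volume weighting changes statistics on unequal cells", {
  m <- generate_slab_mesh(c(4, 2, 2), 1)
  mag <- runif(nrow(m$cells))
  stw <- magnitude_stats(mag, m, 1L, volume_weighted = TRUE)
  st <- magnitude_stats(mag, m, 1L)
  expect_equal(stw$mean, st$mean, tolerance = 1e-9)  # equal-volume cells here
})

test_that("hotspot mask selects the strict top decile and is scale free", {
  vals <- 1:10
  mask <- hotspot_mask(vals, 90)
  expect_identical(which(mask), 10L)
  set.seed(9)
  v <- runif(5000)
  mk <- hotspot_mask(v, 90)
  expect_lt(abs(mean(mk) - 0.10), 0.01)
  expect_identical(hotspot_mask(2 * v, 90), mk)
  expect_warning(mk0 <- hotspot_mask(rep(1, 5)), "constant")
  expect_false(any(mk0))
})

test_that("difference maps reproduce their caption formulas exactly", {
  # relative magnitude difference, percent, reference-normalized
  expect_equal(relative_difference_map(2, 1), 50)
  expect_equal(relative_difference_map(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(relative_difference_map(1, 0), 100)
  expect_true(is.na(relative_difference_map(0, 1)))
  # not symmetric in its arguments
  expect_false(isTRUE(all.equal(relative_difference_map(2, 1),
                                relative_difference_map(1, 2))))
  # angle difference, degrees, clamped
  ex <- matrix(c(1, 0, 0), 1); ey <- matrix(c(0, 1, 0), 1)
  expect_equal(angle_difference_map(ex, 2 * ex), 0, tolerance = 1e-12)
  expect_equal(angle_difference_map(ex, ey), 90, tolerance = 1e-12)
  expect_equal(angle_difference_map(ex, -ex), 180, tolerance = 1e-12)
  expect_equal(angle_difference_map(ex * (1 + 1e-16), ex), 0,
               tolerance = 1e-12)
  expect_equal(angle_difference_map(ex, ey), angle_difference_map(ey, ex))
  expect_true(is.na(angle_difference_map(ex, matrix(0, 1, 3))))
})

test_that("line sampling is piecewise-constant with flagged outside points", {
  lab <- array(1L, c(8, 2, 2)); lab[5:8, , ] <- 2L
  mesh <- generate_slab_mesh(c(8, 2, 2), 1, labels = lab)
  cond <- isotropic_field(mesh, tissue_table(c("1" = 1, "2" = 0.5)))
  bc <- boundary_spec(dirichlet = c(xmin = 5, xmax = -5),
                      target_current = 1e-3)
  cfg <- solver_config(inner_tol = 1e-13, outer_tol = 1e-11,
                       max_outer = 300L, face_interp = "harmonic")
  sys <- fvm_assemble(mesh, cond, bc, cfg)
  pot <- solve_potential(sys)
  E <- gradient_lsq(sys, pot$phi)
  prof <- sample_line(mesh, E, c(0.5, 1, 1), c(7.5, 1, 1), n_samples = 40L)
  expect_equal(nrow(prof), 40L)
  expect_true(all(prof$inside))
  e1 <- stats::median(prof$value[prof$x < 3])
  e2 <- stats::median(prof$value[prof$x > 5])
  expect_equal(e2 / e1, 2, tolerance = 1e-6)
  expect_equal(sort(unique(prof$label)), c(1L, 2L))
  # constant field: constant profile
  profc <- sample_line(mesh, rep(4, nrow(mesh$cells)), c(0.5, 1, 1),
                       c(7.5, 1, 1), 10L)
  expect_true(all(profc$value == 4))
  # points beyond the mesh are flagged, not dropped
  profo <- sample_line(mesh, rep(1, nrow(mesh$cells)), c(-3, 1, 1),
                       c(9, 1, 1), 25L)
  expect_equal(nrow(profo), 25L)
  expect_true(any(!profo$inside) && any(profo$inside))
  expect_true(all(is.na(profo$value[!profo$inside])))
  expect_error(sample_line(mesh, rep(1, nrow(mesh$cells)), c(50, 50, 50),
                           c(60, 60, 60), 5L), "outside")
})
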