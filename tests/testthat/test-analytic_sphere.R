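# Analytic layered-sphere series, percentile Dirichlet construction,
# NRMSD and the end-to-end verification run.

test_that("series matches the independent homogeneous closed form", {
  set.seed(2)
  model <- layered_sphere_model(c(92, 85, 80), rep(0.4, 3))
  setup <- analytic_setup(model, N = 400L)
  u <- matrix(rnorm(300), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * runif(100, 0, 0.9 * 92)
  a <- analytic_potential(setup, pts)
  h <- homogeneous_sphere_potential(92, 0.4, pts)
  expect_lt(max(abs(a - h) / pmax(abs(h), 1e-12)), 1e-8)
})

test_that("antipodal electrodes give an antisymmetric potential", {
  setup <- analytic_setup(three_layer_head_model(), N = 300L)
  set.seed(4)
  pts <- matrix(rnorm(90), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(30, 0, 85)
  mir <- pts; mir[, 3] <- -mir[, 3]
  expect_lt(max(abs(analytic_potential(setup, mir) +
                    analytic_potential(setup, pts))), 1e-14)
  expect_equal(analytic_potential(setup, matrix(0, 1, 3)), 0)
  expect_error(analytic_setup(three_layer_head_model(), N = 10L), "N")
  expect_error(analytic_setup(three_layer_head_model(),
                              source = c(0, 0), sink = c(0, 0)), "differ")
})

test_that("superposition over sinks and interface continuity hold", {
  model <- three_layer_head_model()
  set.seed(5)
  pts <- matrix(rnorm(60), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(20, 10, 75)
  s1 <- analytic_setup(model, sink = c(pi / 2, 0), N = 300L)
  s2 <- analytic_setup(model, sink = c(pi / 2, pi / 2), N = 300L)
  h1 <- analytic_setup(model, sink = c(pi / 2, 0), N = 300L, current = 5e-4)
  h2 <- analytic_setup(model, sink = c(pi / 2, pi / 2), N = 300L,
                       current = 5e-4)
  expect_lt(max(abs(analytic_potential(h1, pts) + analytic_potential(h2, pts) -
                    0.5 * (analytic_potential(s1, pts) +
                           analytic_potential(s2, pts)))), 1e-12)
  # phi continuous across layer interfaces; sigma dphi/dr jump small
  setup <- analytic_setup(model, N = 600L)
  dirv <- c(0.3, 0.4, 0.866); dirv <- dirv / sqrt(sum(dirv^2))
  sig <- model$conductivities
  for (k in 2:3) {
    ri <- model$radii[k]
    eps <- 1e-7
    expect_lt(abs(analytic_potential(setup, matrix(dirv * (ri - eps), 1)) -
                  analytic_potential(setup, matrix(dirv * (ri + eps), 1))),
              1e-8)
    # flux continuity by one-sided finite differences
    fd <- function(r1, r2) (analytic_potential(setup, matrix(dirv * r2, 1)) -
                            analytic_potential(setup, matrix(dirv * r1, 1))) /
      ((r2 - r1) * 1e-3)
    feps <- 1e-4
    flux_in <- sig[k] * fd(ri - 2 * feps, ri - feps)
    flux_out <- sig[k - 1] * fd(ri + feps, ri + 2 * feps)
    expect_lt(abs(flux_in - flux_out) / abs(flux_in), 1e-4)
  }
})

test_that("series tail is negligible away from the surface", {
  model <- three_layer_head_model()
  set.seed(6)
  u <- matrix(rnorm(150), ncol = 3); u <- u / sqrt(rowSums(u^2))
  pts <- u * runif(50, 5, 0.85 * 92)
  p200 <- analytic_potential(analytic_setup(model, N = 200L), pts)
  p400 <- analytic_potential(analytic_setup(model, N = 400L), pts)
  expect_lt(max(abs(p200 - p400) / pmax(abs(p400), 1e-12)), 1e-8)
})

test_that("percentile Dirichlet selects the electrode caps", {
  mesh <- generate_layered_sphere_mesh(three_layer_head_model(numerical = TRUE),
                                       3L)
  setup <- analytic_setup(three_layer_head_model(), N = 400L)
  bc85 <- percentile_dirichlet(setup, mesh, 85)
  faces <- mesh_faces(mesh)
  nb <- sum(!faces$internal)
  ndir <- nrow(bc85$dirichlet_faces$faces)
  expect_lte(abs(ndir - 0.15 * nb), max(2, 0.01 * nb))
  # selected faces cluster at the two poles: |cos(colatitude)| is large
  key <- tesfvm:::face_keys(tesfvm:::sorted_triples(bc85$dirichlet_faces$faces),
                            nrow(mesh$points))
  kall <- tesfvm:::face_keys(tesfvm:::sorted_triples(faces$verts),
                             nrow(mesh$points))
  fc <- faces$centroid[match(key, kall), , drop = FALSE]
  coslat <- abs(fc[, 3]) / sqrt(rowSums(fc^2))
  # cap covering 15% of the boundary area: cos(theta_cap) = 1 - 0.15
  expect_gt(min(coslat), 1 - 0.15 - 0.02)
  bc0 <- percentile_dirichlet(setup, mesh, 0)
  expect_equal(nrow(bc0$dirichlet_faces$faces), nb)
  expect_error(percentile_dirichlet(setup, mesh, 100), "ill-posed")
})

test_that("nrmsd follows its definition and scale invariance", {
  expect_equal(nrmsd(1:10, 1:10), 0)
  set.seed(8)
  b <- runif(20000)
  expect_equal(nrmsd(b + 0.01, b), 100 * 0.01 / (max(b) - min(b)),
               tolerance = 1e-9)
  expect_lt(abs(nrmsd(b + 0.01, b) - 1), 0.05)
  a <- rnorm(100); b2 <- rnorm(100)
  expect_equal(nrmsd(3 * a, 3 * b2), nrmsd(a, b2), tolerance = 1e-12)
  expect_error(nrmsd(1:3, rep(1, 3)), "constant")
  expect_error(nrmsd(1:3, 1:4), "length")
})

test_that("verification error decreases with boundary information and mesh", {
  # homogeneous sphere with full-boundary Dirichlet: NRMSD shrinks under
  # refinement and is below the partial-boundary (85th percentile) run
  model <- layered_sphere_model(c(92, 85, 80), rep(0.4, 3))
  r2 <- sphere_verification(model, subdivisions = 2L, percentile = 0,
                            N = 300L)
  r3 <- sphere_verification(model, subdivisions = 3L, percentile = 0,
                            N = 300L)
  expect_lt(r3$nrmsd, r2$nrmsd)
  r3p <- sphere_verification(model, subdivisions = 3L, percentile = 85,
                             N = 300L)
  expect_lte(r3$nrmsd, r3p$nrmsd)
  expect_lt(r3$nrmsd, 1)
})
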