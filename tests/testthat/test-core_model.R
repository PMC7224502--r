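# Phantom generation, meshing, hybrid classification, isosurface
# extraction, smoothing and mesh quality.

test_that("layered sphere image labels voxels by innermost covering layer", {
  model <- three_layer_head_model(numerical = TRUE)
  img <- generate_layered_sphere_image(model, spacing = 2)
  d <- dim(img$labels)
  ijk <- arrayInd(seq_along(img$labels), d) - 1L
  w <- sweep(ijk * 2, 2, img$origin, "+")    # spacing 2, origin offset
  w <- cbind(img$origin[1] + ijk[, 1] * 2, img$origin[2] + ijk[, 2] * 2,
             img$origin[3] + ijk[, 3] * 2)
  r <- sqrt(rowSums(w^2))
  expect_true(all(r[img$labels == 3L] <= 80 + 1e-9))
  expect_true(all(r[img$labels == 0L] > 90))
  # center voxel gets the innermost label
  expect_equal(classify_center <- img$labels[which.min(r)], 3L)
  # single layer: labeled volume matches the analytic ball volume
  img1 <- generate_layered_sphere_image(layered_sphere_model(10, 1), 1)
  vol <- sum(img1$labels == 1L) * 1
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  expect_error(layered_sphere_model(c(5, 9), c(1, 1)), "decreasing")
})

test_that("body-fitted sphere mesh is conforming with exact interfaces", {
  model <- layered_sphere_model(c(9, 5), c(1, 0.5))
  mesh <- generate_layered_sphere_mesh(model, 2L)
  faces <- mesh_faces(mesh)               # errors if any face shared by > 2
  expect_true(all(tesfvm:::tet_signed_volumes(mesh$points, mesh$cells) > 0))
  # interface vertices exactly at the model radius
  r <- sqrt(rowSums(mesh$points^2))
  expect_true(any(abs(r - 5) < 1e-9))
  on_if <- abs(r - 5) < 0.5
  expect_true(all(abs(r[on_if] - 5) < 1e-9))
  # per-label volumes approach the analytic shell volumes
  vols <- cell_volumes(mesh)
  for (i in 1:2) {
    v <- sum(vols[mesh$cell_labels == i])
    expect_lt(abs(v - shell_volume(model, i)) / shell_volume(model, i), 0.1)
  }
  # volume converges monotonically from below under subdivision
  verr <- vapply(2:4, function(s) {
    m <- generate_layered_sphere_mesh(layered_sphere_model(10, 1), s)
    abs(sum(cell_volumes(m)) - 4 / 3 * pi * 1000)
  }, 0)
  expect_true(all(diff(verr) < 0))
  expect_error(generate_layered_sphere_mesh(model, 1L), "subdivisions")
})

test_that("labeled-image meshing conforms and preserves volumes", {
  img1 <- labeled_image(array(1L, c(1, 1, 1)), spacing = c(2, 2, 2))
  m1 <- tetrahedralize_labeled_image(img1)
  expect_true(nrow(m1$cells) %in% c(5L, 6L))
  expect_equal(sum(cell_volumes(m1)), 8, tolerance = 1e-12)
  img2 <- labeled_image(array(1L, c(2, 2, 2)))
  m2 <- tetrahedralize_labeled_image(img2)
  expect_true(is_watertight(boundary_surface(m2)))
  # sphere image at 2 mm: per-label volume within 10% of analytic shells
  model <- three_layer_head_model(numerical = TRUE)
  img <- generate_layered_sphere_image(model, spacing = 4)
  m <- tetrahedralize_labeled_image(img)
  vols <- cell_volumes(m)
  for (i in 1:3) {
    v <- sum(vols[m$cell_labels == i])
    expect_lt(abs(v - shell_volume(model, i)) / shell_volume(model, i), 0.1)
  }
  expect_error(tetrahedralize_labeled_image(
    labeled_image(array(0L, c(2, 2, 2)))), "retained")
})

test_that("hybrid classification follows entry order with image override", {
  s1 <- icosphere(3, 10)
  s2 <- icosphere(3, 5)
  dom <- hybrid_domain(list(list(surface = s1, label = 1L),
                            list(surface = s2, label = 2L)))
  # point inside both: innermost (last-entered) surface wins
  expect_equal(classify_point_hybrid(dom, matrix(c(0, 0, 1), 1)), 2L)
  # point inside only the first
  expect_equal(classify_point_hybrid(dom, matrix(c(0, 0, 7), 1)), 1L)
  # outside everything
  expect_equal(classify_point_hybrid(dom, matrix(c(0, 0, 20), 1)), 0L)
  # image is queried last and overrides wherever non-zero
  img <- generate_layered_sphere_image(layered_sphere_model(2.5, 1,
                                                            center = c(7, 0, 0)),
                                       spacing = 1)
  img$labels[img$labels == 1L] <- 9L
  dom2 <- hybrid_domain(dom$surfaces, img)
  expect_equal(classify_point_hybrid(dom2, matrix(c(7, 0, 0), 1)), 9L)
  expect_equal(classify_point_hybrid(dom2, matrix(c(0, 0, 0), 1)), 2L)
  # non-watertight surface is rejected before any query
  broken <- s1; broken$triangles <- broken$triangles[-1, , drop = FALSE]
  expect_error(classify_point_hybrid(
    hybrid_domain(list(list(surface = broken, label = 1L))),
    matrix(0, 1, 3)), "watertight")
})

test_that("classification agrees with an independent ray-casting oracle", {
  set.seed(11)
  s1 <- icosphere(2, 10)
  s2 <- icosphere(2, 6)
  dom <- hybrid_domain(list(list(surface = s1, label = 1L),
                            list(surface = s2, label = 2L)))
  pts <- matrix(runif(3 * 400, -12, 12), ncol = 3)
  lab <- classify_point_hybrid(dom, pts)
  in1 <- oracle_inside(s1, pts)
  in2 <- oracle_inside(s2, pts)
  ref <- ifelse(in2, 2L, ifelse(in1, 1L, 0L))
  expect_gte(mean(lab == ref), 0.999)
})

test_that("relabel_cells applies the hybrid oracle at centroids", {
  img <- labeled_image(array(1L, c(6, 6, 6)), spacing = c(4, 4, 4),
                       origin = c(-10, -10, -10))
  mesh <- tetrahedralize_labeled_image(img)
  s <- icosphere(3, 8, center = c(2, 2, 2))
  dom <- hybrid_domain(list(list(surface = s, label = 5L)))
  out <- relabel_cells(mesh, dom)
  ce <- cell_centroids(out)
  r <- sqrt(rowSums(sweep(ce, 2, c(2, 2, 2))^2))
  interior <- r < 7.5
  expect_true(all(out$cell_labels[interior] == 5L))
  expect_true(all(out$cell_labels[r > 8.5] == 0L))
  # empty domain: all labels zero
  far <- hybrid_domain(list(list(surface = icosphere(2, 1,
                                                     center = c(99, 0, 0)),
                                 label = 3L)))
  expect_true(all(relabel_cells(mesh, far)$cell_labels == 0L))
})

test_that("isosurface extraction is watertight with correct volume", {
  img <- generate_layered_sphere_image(layered_sphere_model(20, 1), 1)
  iso <- extract_isosurface(img, 1L)
  expect_true(is_watertight(iso))
  v <- enclosed_volume(iso)
  expect_lt(abs(v - 4 / 3 * pi * 8000) / (4 / 3 * pi * 8000), 0.05)
  # single voxel: closed surface; volume equals the Monte-Carlo volume of
  # the piecewise-linear interpolant region (independent oracle)
  lab <- array(0L, c(3, 3, 3)); lab[2, 2, 2] <- 1L
  iso1 <- extract_isosurface(labeled_image(lab), 1L)
  expect_true(is_watertight(iso1))
  set.seed(3)
  samp <- matrix(runif(3 * 20000, 0.5, 1.5), ncol = 3)  # around voxel (2,2,2)@(1,1,1)
  # PL interpolant of the indicator on the dual grid equals > 0.5 exactly
  # when the point is nearer the inside center than any separating cut
  inside <- oracle_inside(iso1, samp)
  mc_vol <- mean(inside) * 1
  expect_lt(abs(enclosed_volume(iso1) - mc_vol), 0.05)
  expect_error(extract_isosurface(img, 7L), "absent")
})

test_that("Taubin smoothing preserves volume where Laplacian shrinks", {
  ico <- icosphere(3, 10)
  expect_identical(taubin_smooth(ico, steps = 0L), ico)
  v0 <- enclosed_volume(ico)
  vt <- enclosed_volume(taubin_smooth(ico))
  vl <- enclosed_volume(taubin_smooth(ico, lambda = 0.5, mu = 0, steps = 50L))
  expect_lt(abs(vt - v0) / v0, 0.05)
  expect_gt(abs(vl - v0) / v0, 0.20)
  # interior vertices of a plane stay coplanar
  pl <- flat_plane(8)
  sm <- taubin_smooth(pl, steps = 10L)
  expect_lt(max(abs(sm$vertices[, 3])), 1e-12)
  expect_identical(sm$triangles, pl$triangles)
})

test_that("mesh quality metrics match closed-form geometry", {
  q0 <- mesh_quality(mirror_tet_pair())
  expect_lt(q0$max_nonorthogonality, 1e-6)
  expect_equal(q0$n_nonorthogonal_faces, 0L)
  expect_lt(q0$max_skewness, 1e-12)
  # shear one apex parallel to the shared face: closed-form angle between
  # the recomputed centroid line and the face normal (z axis)
  sh <- 0.8
  qs <- mesh_quality(mirror_tet_pair(shear = sh))
  d <- c(sh / 4, 0, 1 / 4) - c(0, 0, -1 / 4)   # centroid offset
  ang <- acos(sum(d * c(0, 0, 1)) / sqrt(sum(d^2))) * 180 / pi
  expect_equal(qs$max_nonorthogonality, ang, tolerance = 1e-9)
  # orthogonal slab: no non-orthogonal faces at all
  q <- mesh_quality(generate_slab_mesh(c(6, 3, 3), 1))
  expect_equal(q$n_nonorthogonal_faces, 0L)
  expect_lt(q$max_nonorthogonality, 1e-4)
  # invariance under rigid rotation
  sl <- generate_slab_mesh(c(3, 2, 2), 1)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  slr <- tet_mesh(sl$points %*% t(Rz), sl$cells, sl$cell_labels)
  expect_equal(mesh_quality(slr)$max_nonorthogonality,
               mesh_quality(tet_mesh(sl$points, sl$cells,
                                     sl$cell_labels))$max_nonorthogonality,
               tolerance = 1e-7)
  expect_error(mesh_quality(tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(0, 1, 0), c(0, 0, 1)),
                                     matrix(1:4, 1))), "internal")
})

test_that("delaunay-quality convex meshes keep non-orthogonality under 90", {
  m <- generate_layered_sphere_mesh(layered_sphere_model(10, 1), 3L)
  q <- mesh_quality(m)
  expect_lt(q$max_nonorthogonality, 90)
})
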