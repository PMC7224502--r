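# 10-20 positioning, footprint clipping, extrusion and mesh tagging.

test_that("10-20 positions match great-circle closed forms on the sphere", {
  scalp <- icosphere(5L, 1)
  fid <- fiducial_set(c(0, 1, 0), c(0, -1, 0), c(-1, 0, 0), c(1, 0, 0))
  pos <- locate_1020(scalp, fid)
  expect_lt(sqrt(sum((pos["Cz", ] - c(0, 0, 1))^2)), 1e-3)
  # C3: spherical angle 20% of pi from Cz toward the left tragus
  c3 <- c(-sin(0.2 * pi), 0, cos(0.2 * pi))
  c4 <- c(sin(0.2 * pi), 0, cos(0.2 * pi))
  oz <- c(0, -cos(0.1 * pi), sin(0.1 * pi))   # 10% of inion->nasion arc
  expect_lt(sqrt(sum((pos["C3", ] - c3)^2)), 1e-3)
  expect_lt(sqrt(sum((pos["C4", ] - c4)^2)), 1e-3)
  expect_lt(sqrt(sum((pos["Oz", ] - oz)^2)), 1e-3)
  # left/right mirror symmetry
  expect_lt(sqrt(sum((pos["C3", ] - pos["C4", ] * c(-1, 1, 1))^2)), 1e-3)
  expect_lt(sqrt(sum((pos["T5", ] - pos["T6", ] * c(-1, 1, 1))^2)), 2e-3)
  # every returned position lies on the scalp surface
  proj <- tesfvm:::project_to_surface(scalp, pos)
  expect_lt(max(sqrt(rowSums((proj - pos)^2))), 1e-6)
})

test_that("footprint clipping has exact area on flat surfaces", {
  pl <- flat_plane(20L)
  rect <- electrode_spec("a", "rect", c(10, 10), thickness = 2)
  patch <- clip_patch(pl, rect, c(10.3, 9.7, 0))
  expect_equal(surface_area(patch), 100, tolerance = 1e-6)
  circ <- electrode_spec("b", "circle", 4, thickness = 2)
  pc <- clip_patch(pl, circ, c(10.2, 10.4, 0))
  expect_lt(abs(surface_area(pc) - pi * 16) / (pi * 16), 0.005)
  # on a curved scalp the patch area exceeds the flat footprint area
  sph <- icosphere(4L, 20)
  ps <- clip_patch(sph, electrode_spec("c", "circle", 5, thickness = 2),
                   c(0, 0, 20))
  expect_gte(surface_area(ps), pi * 25 * (1 - 1e-6))
  expect_error(clip_patch(pl, rect, c(500, 500, 0)), "misses|no boundary")
})

test_that("extrusion follows the 1 mm step rule and closes the solid", {
  pl <- flat_plane(20L)
  patch <- clip_patch(pl, electrode_spec("a", "rect", c(10, 10), thickness = 2),
                      c(10, 10, 0))
  nb0 <- nrow(unique(boundary_edges(patch)))
  ex2 <- extrude_electrode(patch, 2)
  expect_identical(attr(ex2, "n_layers"), 2)
  expect_true(is_watertight(ex2))
  ex3 <- extrude_electrode(patch, 3)
  expect_equal(enclosed_volume(ex3), 300, tolerance = 1e-6)
  ex25 <- extrude_electrode(patch, 2.5)
  expect_identical(attr(ex25, "n_layers"), 3)
  expect_equal(enclosed_volume(ex25), 250, tolerance = 1e-6)
  # outer face set is the final offset copy of the patch
  outer <- attr(ex3, "outer_faces")
  expect_equal(length(outer), nrow(patch$triangles))
  expect_true(all(abs(ex3$vertices[ex3$triangles[outer, ], 3] - 3) < 1e-12))
})

test_that("electrode tagging creates outer and contact patches", {
  mod <- layered_sphere_model(c(30, 25), c(0.465, 0.33))
  mesh <- generate_layered_sphere_mesh(mod, 2L, c(2L, 10L))
  mesh <- tag_electrode_on_mesh(
    mesh, electrode_spec("anode", "circle", 7, thickness = 4, role = "anode"),
    c(0, 0, 30))
  mesh <- tag_electrode_on_mesh(
    mesh, electrode_spec("cathode", "circle", 7, thickness = 4,
                         role = "cathode"), c(0, 0, -30))
  expect_setequal(unname(attr(mesh, "electrode_labels")), c(3L, 4L))
  expect_true(all(c("anode_outer", "anode_contact", "cathode_outer",
                    "cathode_contact") %in% names(mesh$patches)))
  # anode outer faces point up (positive polar component)
  f <- mesh$patches$anode_outer$faces
  p1 <- mesh$points[f[, 1], ]; p2 <- mesh$points[f[, 2], ]
  p3 <- mesh$points[f[, 3], ]
  nrm <- tesfvm:::cross3(p2 - p1, p3 - p1)
  expect_true(all(nrm[, 3] > 0))
  # contact faces separate the electrode from the scalp layer
  faces <- mesh_faces(mesh)
  idx <- tesfvm:::match_patch_faces(faces, mesh$patches$anode_contact$faces,
                                    nrow(mesh$points))
  labs <- cbind(mesh$cell_labels[faces$owner[idx]],
                mesh$cell_labels[faces$neighbour[idx]])
  expect_true(all(apply(labs, 1, function(x) 3L %in% x && any(x != 3L))))
  # antipodal electrodes have disjoint patch face sets
  ka <- tesfvm:::face_keys(tesfvm:::sorted_triples(
    mesh$patches$anode_contact$faces), nrow(mesh$points))
  kc <- tesfvm:::face_keys(tesfvm:::sorted_triples(
    mesh$patches$cathode_contact$faces), nrow(mesh$points))
  expect_length(intersect(ka, kc), 0)
  expect_error(tag_electrode_on_mesh(
    mesh, electrode_spec("x", "circle", 5, thickness = 2), c(0, 0, 500)),
    "footprint")
})

test_that("contact and outer areas agree for thin wide electrodes", {
  # wide footprint, 1 mm thickness: the lateral interface ring (perimeter
  # x thickness) is a small fraction of the footprint area, so the contact
  # patch area approaches the outer patch area
  mesh <- generate_slab_mesh(c(46, 46, 2), 1)
  mesh <- tag_electrode_on_mesh(
    mesh, electrode_spec("pad", "rect", c(44, 44), thickness = 1,
                         role = "anode"), c(23, 23, 2))
  area <- function(f) {
    a <- mesh$points[f[, 1], ]; b <- mesh$points[f[, 2], ]
    c_ <- mesh$points[f[, 3], ]
    sum(0.5 * tesfvm:::rownorm(tesfvm:::cross3(b - a, c_ - a)))
  }
  ao <- area(mesh$patches$pad_outer$faces)
  ac <- area(mesh$patches$pad_contact$faces)
  expect_equal(ao, 44^2, tolerance = 1e-9)
  expect_lt(abs(ao - ac) / ao, 0.10)
})
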