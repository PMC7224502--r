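#' Labeled voxel image
#'
#' A regular voxel grid carrying one non-negative integer tissue label per
#' voxel (0 = background/air). World coordinates follow the voxel-center
#' convention: the center of voxel (i, j, k) (0-based) lies at
#' `origin + c(i, j, k) * spacing`. No rotation part is carried (ANALYZE
#' headers have none).
#'
#' @param labels 3-D integer array of labels, all >= 0.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm position of the center of voxel (0,0,0).
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  if (length(origin) != 3L) stop("origin must have length 3")
  labels <- array(as.integer(labels), dim(labels))
  if (anyNA(labels) || any(labels < 0L)) stop("labels must be non-negative integers")
  structure(list(labels = labels, spacing = spacing, origin = origin),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_image> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Triangulated surface
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param name identifier string.
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, triangles, name = "surface") {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL; dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(triangles) != 3L) stop("triangles must be m x 3")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles, name = name),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface> '%s': %d vertices, %d triangles, watertight: %s\n",
              x$name, nrow(x$vertices), nrow(x$triangles),
              is_watertight(x)))
  invisible(x)
}

#' Tetrahedral volume mesh
#'
#' The computational domain: tetrahedral cells with an integer compartment
#' label per cell and named face patches. Boundary patches are sets of
#' exterior faces; interface patches are sets of internal faces separating
#' two compartments. Faces are stored as vertex index triples.
#'
#' @param points n x 3 numeric matrix (mm).
#' @param cells m x 4 integer matrix of 1-based point indices; each cell must
#'   be positively oriented (signed volume > 0) -- `tet_mesh()` reorders
#'   negative cells automatically.
#' @param cell_labels integer compartment id per cell.
#' @param patches named list; each element a list with `faces` (k x 3 vertex
#'   index triples) and `type` ("boundary" or "interface").
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(points, cells, cell_labels = NULL, patches = list()) {
  points <- as.matrix(points); storage.mode(points) <- "double"
  cells <- as.matrix(cells); storage.mode(cells) <- "integer"
  dimnames(points) <- NULL; dimnames(cells) <- NULL
  if (ncol(points) != 3L) stop("points must be n x 3")
  if (ncol(cells) != 4L) stop("cells must be m x 4")
  if (min(cells) < 1L || max(cells) > nrow(points)) stop("cell indices out of range")
  if (is.null(cell_labels)) cell_labels <- rep(1L, nrow(cells))
  cell_labels <- as.integer(cell_labels)
  if (length(cell_labels) != nrow(cells)) stop("one label per cell required")
  v <- tet_signed_volumes(points, cells)
  neg <- which(v < 0)
  if (length(neg)) {           # swap two vertices to restore positive orientation
    tmp <- cells[neg, 3L]; cells[neg, 3L] <- cells[neg, 4L]; cells[neg, 4L] <- tmp
  }
  if (any(tet_signed_volumes(points, cells) <= 0))
    stop("mesh contains degenerate (zero-volume) cells")
  structure(list(points = points, cells = cells, cell_labels = cell_labels,
                 patches = patches),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d points, %d cells, labels: %s\n",
              nrow(x$points), nrow(x$cells),
              paste(sort(unique(x$cell_labels)), collapse = ", ")))
  if (length(x$patches))
    cat("  patches:", paste(sprintf("%s[%d,%s]", names(x$patches),
                                    vapply(x$patches, function(p) nrow(p$faces), 1L),
                                    vapply(x$patches, function(p) p$type, "")),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Hybrid classification domain
#'
#' An ordered list of closed surfaces (each with an output label) optionally
#' combined with a labeled image. Point queries ask each surface in entry
#' order, then the image; the label of the last positively responding
#' domain wins (so the image, queried last, overrides the surfaces wherever
#' its label is non-zero).
#'
#' @param surfaces list of `list(surface = tri_surface, label = integer)`.
#' @param image optional [labeled_image()].
#' @return An object of class `hybrid_domain`.
#' @export
hybrid_domain <- function(surfaces = list(), image = NULL) {
  for (s in surfaces) {
    if (!inherits(s$surface, "tri_surface")) stop("each surface entry needs $surface")
    if (is.null(s$label)) stop("each surface entry needs $label")
  }
  if (!is.null(image) && !inherits(image, "labeled_image"))
    stop("image must be a labeled_image")
  structure(list(surfaces = surfaces, image = image), class = "hybrid_domain")
}

#' Concentric layered sphere model
#'
#' Radii are given outermost first and must be strictly decreasing; layer i
#' occupies radii (radii[i+1], radii[i]] with conductivity conductivities[i],
#' the innermost layer reaching the center.
#'
#' @param radii strictly decreasing radii, mm (outer -> inner).
#' @param conductivities one conductivity (S/m) per layer, all > 0.
#' @param center sphere center, mm.
#' @return An object of class `layered_sphere_model`.
#' @export
layered_sphere_model <- function(radii, conductivities, center = c(0, 0, 0)) {
  radii <- as.numeric(radii); conductivities <- as.numeric(conductivities)
  if (any(diff(radii) >= 0)) stop("invalid model: radii must be strictly decreasing")
  if (any(radii <= 0)) stop("invalid model: radii must be positive")
  if (length(conductivities) != length(radii)) stop("one conductivity per layer")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  structure(list(radii = radii, conductivities = conductivities,
                 center = as.numeric(center)),
            class = "layered_sphere_model")
}

#' Three-layer sphere head phantom parameters
#'
#' The scalp/skull/brain sphere model used for analytic verification:
#' radii 92/85/80 mm (the simulated mesh uses 90 mm for the outer scalp
#' boundary so that surface point electrodes remain outside the numerical
#' domain) and conductivities 0.465/0.01/0.33 S/m.
#'
#' @param numerical if `TRUE`, the outer radius is 90 mm (the simulated
#'   sphere); if `FALSE` (default) 92 mm (the analytic model).
#' @return A [layered_sphere_model()].
#' @export
three_layer_head_model <- function(numerical = FALSE) {
  layered_sphere_model(radii = c(if (numerical) 90 else 92, 85, 80),
                       conductivities = c(0.465, 0.01, 0.33))
}

#' Tissue conductivity table
#'
#' Maps compartment labels to scalar conductivities in S/m. The default
#' table carries the standard head-tissue values: skin 0.465, skull 0.01,
#' CSF 1.654, grey matter 0.275, white matter 0.126, electrode material
#' 29.4 and air 1e-15 (an explicit insulator sentinel).
#'
#' @param values named numeric vector, names = compartment labels (coerced
#'   to character), values = conductivity in S/m.
#' @return An object of class `tissue_table`.
#' @export
tissue_table <- function(values) {
  values <- unlist(values)
  if (is.null(names(values)) || any(names(values) == ""))
    stop("tissue_table values must be named by compartment label")
  if (any(values <= 0)) stop("conductivities must be > 0 (use 1e-15 for air)")
  structure(as.list(values), class = "tissue_table")
}

#' @rdname tissue_table
#' @export
default_tissue_table <- function() {
  tissue_table(c(skin = 0.465, skull = 0.01, csf = 1.654, gm = 0.275,
                 wm = 0.126, electrode = 29.4, air = 1e-15))
}

#' Solver configuration
#'
#' @param inner_tol relative residual tolerance of the inner linear solve.
#' @param outer_tol normalized residual tolerance of the outer
#'   non-orthogonality correction loop.
#' @param max_outer maximum outer iterations.
#' @param max_inner maximum inner (PCG) iterations.
#' @param correction `"none"`, `"corrected"` (default) or `"limited"`.
#' @param alpha blending factor in `[0, 1]` for `correction = "limited"`
#'   (1 = fully corrected).
#' @param face_interp `"arithmetic"` (distance-weighted linear, default) or
#'   `"harmonic"` face conductivity interpolation.
#' @param relax under-relaxation factor of the outer correction iteration
#'   in `(0, 1]`; answer-invariant (the converged solution does not depend
#'   on it), smaller values stabilize strongly non-orthogonal meshes with
#'   large conductivity contrasts.
#' @param exclude_insulator drop cells whose conductivity is at or below the
#'   insulator sentinel from the linear system (default `TRUE`).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(inner_tol = 1e-6, outer_tol = 1e-5,
                          max_outer = 100L, max_inner = 20000L,
                          correction = c("corrected", "none", "limited"),
                          alpha = 1, face_interp = c("arithmetic", "harmonic"),
                          relax = 0.5, exclude_insulator = TRUE) {
  correction <- match.arg(correction)
  face_interp <- match.arg(face_interp)
  if (inner_tol <= 0 || outer_tol <= 0) stop("tolerances must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (relax <= 0 || relax > 1) stop("relax must lie in (0, 1]")
  structure(list(inner_tol = inner_tol, outer_tol = outer_tol,
                 max_outer = as.integer(max_outer),
                 max_inner = as.integer(max_inner),
                 correction = correction, alpha = alpha,
                 face_interp = face_interp, relax = relax,
                 exclude_insulator = exclude_insulator),
            class = "solver_config")
}

#' Boundary conditions for the potential solve
#'
#' Dirichlet potentials are attached either to named boundary patches
#' (`dirichlet`, the +/- 5 V electrode surfaces) or to explicit boundary
#' faces (`dirichlet_faces`, used by the analytic percentile construction).
#' Every unlisted boundary face receives a zero-gradient Neumann condition.
#'
#' @param dirichlet named numeric vector: patch name -> potential (V).
#' @param dirichlet_faces optional list with `faces` (k x 3 vertex triples)
#'   and `values` (k potentials, V).
#' @param target_current target electrode current I_target in ampere.
#' @param contact_patches character vector of interface patch names over
#'   which the delivered current is integrated (anode contact first).
#' @return An object of class `boundary_spec`.
#' @export
boundary_spec <- function(dirichlet = c(anode_outer = 5, cathode_outer = -5),
                          dirichlet_faces = NULL,
                          target_current = 1e-3,
                          contact_patches = character()) {
  if (is.null(dirichlet_faces)) {
    if (length(dirichlet) == 0) stop("at least one Dirichlet patch required")
    if (!(any(dirichlet > 0) && any(dirichlet < 0)) && length(dirichlet) < 2)
      stop("well-posedness requires at least two distinct Dirichlet potentials")
  }
  if (!is.null(target_current) && target_current <= 0)
    stop("target_current must be > 0")
  structure(list(dirichlet = dirichlet, dirichlet_faces = dirichlet_faces,
                 target_current = target_current,
                 contact_patches = contact_patches),
            class = "boundary_spec")
}

#' Electrode specification
#'
#' @param name electrode name (used for patch names `<name>_outer`,
#'   `<name>_contact`).
#' @param shape `"rect"`, `"circle"` or `"polygon"`.
#' @param size for `"rect"`: `c(width, height)` mm; for `"circle"`: radius
#'   mm; for `"polygon"`: k x 2 matrix of footprint vertices (mm, convex,
#'   counter-clockwise) in the local tangent plane.
#' @param thickness electrode thickness, mm (>= 1).
#' @param position a 10-20 label (e.g. `"C3"`) or an explicit scalp point.
#' @param role `"anode"` or `"cathode"`.
#' @return An object of class `electrode_spec`.
#' @export
electrode_spec <- function(name, shape = c("rect", "circle", "polygon"),
                           size, thickness = 2,
                           position = NULL, role = c("anode", "cathode")) {
  shape <- match.arg(shape); role <- match.arg(role)
  if (thickness < 1) stop("thickness must be >= 1 mm")
  fp <- footprint_polygon(shape, size)
  if (polygon_area2(fp) <= 0) stop("footprint area must be > 0")
  structure(list(name = name, shape = shape, size = size,
                 thickness = thickness, position = position, role = role),
            class = "electrode_spec")
}

#' Fiducial landmark set
#'
#' The four anatomical landmarks anchoring the 10-20 grid. Points are
#' projected onto the scalp surface before use.
#'
#' @param nasion,inion,tragus_left,tragus_right mm points.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(nasion, inion, tragus_left, tragus_right) {
  pts <- rbind(nasion, inion, tragus_left, tragus_right)
  if (nrow(unique(pts)) != 4L) stop("fiducial points must be distinct")
  a <- as.numeric(inion) - as.numeric(nasion)
  b <- as.numeric(tragus_right) - as.numeric(tragus_left)
  cr <- cross3(matrix(a, 1), matrix(b, 1))
  if (sqrt(sum(cr^2)) < 1e-9 * sqrt(sum(a^2)) * sqrt(sum(b^2)))
    stop("nasion-inion and tragus-tragus chords must not be parallel")
  structure(list(nasion = as.numeric(nasion), inion = as.numeric(inion),
                 tragus_left = as.numeric(tragus_left),
                 tragus_right = as.numeric(tragus_right)),
            class = "fiducial_set")
}

# footprint polygon in local 2-D tangent coordinates (k x 2, CCW)
footprint_polygon <- function(shape, size, n_circle = 64L) {
  switch(shape,
    rect = {
      w <- size[1] / 2; h <- size[2] / 2
      cbind(c(-w, w, w, -w), c(-h, -h, h, h))
    },
    circle = {
      th <- seq(0, 2 * pi, length.out = n_circle + 1L)[-(n_circle + 1L)]
      size[1] * cbind(cos(th), sin(th))
    },
    polygon = {
      p <- as.matrix(size)
      if (ncol(p) != 2L) stop("polygon footprint must be k x 2")
      p
    })
}

# twice the signed area of a 2-D polygon (positive for CCW)
polygon_area2 <- function(p) {
  n <- nrow(p); j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]))
}
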