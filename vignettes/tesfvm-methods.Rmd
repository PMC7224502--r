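---
title: "Finite-volume simulation of transcranial electric stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-volume simulation of transcranial electric stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tesfvm)
```

# The physical model

Transcranial electric stimulation applies weak currents (typically 1–2 mA)
through scalp electrodes. At stimulation frequencies the capacitive and
inductive terms of Maxwell's equations are negligible, so the potential
$\varphi$ inside the head obeys the quasi-static equation

$$\nabla\cdot(\sigma\,\nabla\varphi) = 0,$$

with the electric field $E = -\nabla\varphi$ (V/m) and current density
$J = \sigma E$ (A/m²). $\sigma$ is the tissue conductivity tensor in S/m;
the quasi-static scaling argument makes the same solution valid for tDCS,
tACS and tRNS waveforms up to a multiplicative time course.

Electrodes are represented by the *complete electrode model*: the
electrode body is part of the conductive domain (a very good conductor,
29.4 S/m), its exterior surface is an equipotential Dirichlet boundary at
±5 V, and all remaining exterior surfaces carry a zero-gradient Neumann
condition (the surrounding air acts as a perfect insulator). Because the
problem is linear, the arbitrary ±5 V drive is afterwards rescaled by
$s = I_\mathrm{target}/I_\mathrm{measured}$, where $I_\mathrm{measured}$
is the current integrated over the electrode–scalp contact surface. This
two-step procedure captures current shunting through the electrode body
without needing an a-priori contact impedance.

Default tissue conductivities (S/m): skin 0.465, skull 0.01, CSF 1.654,
grey matter 0.275, white matter 0.126, electrode 29.4, air $10^{-15}$
(an explicit insulator sentinel; cells at the sentinel are excluded from
the linear system by default).

# Discretization

The computational domain is an unstructured tetrahedral mesh with
cell-centered unknowns. Integrating the divergence over each cell and
applying the Gauss theorem reduces the equation to a sum of face fluxes
$F_f = (\sigma\nabla\varphi)_f\cdot A_f$.

**Implicit part.** For an internal face between owner $O$ and neighbour
$N$ with area vector $A_f$ and centroid offset $d = c_N - c_O$, the
orthogonal (two-point) flux coefficient is

$$a_f = \sigma_{f,n}\,\frac{|A_f|^2}{A_f\cdot d},$$

the over-relaxed decomposition of the face area vector along the centroid
line. $\sigma_{f,n} = \hat n\cdot\sigma_f\,\hat n$ projects the
distance-weighted linear interpolation of the two cell tensors onto the
face normal. A harmonic-mean option (`face_interp = "harmonic"`, with
normal-projected distance weights) exists behind a flag and is *off* by
default; it is exact for layered media whose interfaces coincide with
faces (see the slab analysis below).

**Explicit correction.** The non-orthogonal remainder of the flux is
evaluated from least-squares cell gradients $g$:

$$r_f = \big[(\sigma_f g_f)\cdot A_f - (\hat n\cdot\sigma_f g_f)\,|A_f|\big]
      + \sigma_{f,n}\big[(g_f\cdot\hat n)\,|A_f| - (g_f\cdot d)\,\tfrac{|A_f|^2}{A_f\cdot d}\big].$$

Both brackets vanish identically when $A_f \parallel d$ (an orthogonal
face), and the total flux $a_f(\varphi_N-\varphi_O) + r_f$ is exact for
affine potentials on any conforming mesh — the basis of the solver's
linear-exactness tests. Dirichlet faces contribute a half-cell flux with
the same structure, using the face-centroid distance.

**Outer loop.** The correction is iterated: gradients and $r_f$ are
recomputed from the current iterate, the symmetric positive-definite
system is re-solved (IC(0)-preconditioned conjugate gradients, relative
residual $10^{-6}$, zero initial guess on the first pass, warm-started
afterwards), and the loop stops when the residual of the *fully corrected*
system, normalized by the RHS norm, falls below $10^{-5}$. The correction
RHS is under-relaxed between outer iterations (`relax`, default 0.5); the
relaxation only damps the fixed-point iteration and does not change the
converged solution. This damping is needed on strongly non-orthogonal
meshes with large conductivity contrasts (electrode/scalp is 63:1), where
the undamped deferred-correction iteration can diverge. `correction =
"limited"` blends the correction magnitude by a factor $\alpha$ (that
*does* change the scheme; default is fully corrected, $\alpha = 1$), and
`"none"` gives the plain two-point scheme, which is an M-matrix and hence
satisfies a discrete maximum principle. The corrected scheme is not
strictly monotone: overshoots of order the outer tolerance can occur near
Dirichlet boundaries, which is why the maximum-principle property test
runs on configurations where the correction vanishes.

**Gradients.** Cell gradients solve a weighted least-squares fit of
potential differences to centroid offsets over face neighbours, with
weights $1/\mathrm{dist}$ and Dirichlet faces acting as pseudo-neighbours
at the face centroids. Cells with fewer than three independent neighbour
directions (corner cells of thin voxel bars) are augmented with
second-ring neighbours, which preserves exactness for affine fields; a
cell that is still rank-deficient afterwards raises an error. The
field is $E = -g$; this least-squares route is deliberately independent
of the face-flux route, so comparing the two (e.g. in current
integration) is a meaningful internal check.

**Current integration.** Two integrators are provided. The generic one
sums face-interpolated $J\cdot \hat n\,|A|$ over a patch and is exact for
uniform fields; across high-contrast contact interfaces, however,
interpolated cell fields are not conservative. The flux integrator
(`integrate_current(..., sys =, phi =)`) sums the discrete face fluxes of
the solved system, which are conservative by construction — anode and
cathode currents then agree to the outer solver tolerance, and
`solve_tes()` uses it for the scaling current. When a solution has been
rescaled, the Dirichlet values embedded in the system must be rescaled
alongside (`dirichlet_scale = sol$s`).

## Why the slab fixture is face-orthogonal

The package ships a dedicated slab mesher (`generate_slab_mesh()`) that
splits every cubic voxel into 12 tetrahedra — one pyramid per voxel face
with its apex at the voxel center, each face split along the diagonal
through its even-parity corners. With this choice every internal face
separates two mirror-image cells, so the centroid line is parallel to the
face normal: the mesh has *zero* non-orthogonality. On such a mesh the
explicit correction vanishes identically and the two-point scheme is
complete. Combined with harmonic face conductivities at material
interfaces, the discrete solution of a layered slab reproduces the
series-resistance closed form to solver tolerance ($10^{-8}$ and better)
— a sharp end-to-end oracle that no generic tetrahedral mesh can provide,
because interface-adjacent least-squares gradients are polluted by the
kink in the potential and feed spurious corrections on non-orthogonal
faces. The general-purpose voxel mesher (`tetrahedralize_labeled_image()`,
6 tetrahedra per voxel around the main diagonal) and the body-fitted
sphere mesher are used everywhere else.

# The analytic verification engine

For concentric spheres with a surface point source and sink, the
potential separates into Legendre harmonics: in layer $\ell$,

$$\varphi_\ell(r,\gamma) = \sum_{n\ge 1}\big[A_{\ell n} r^{\,n} + B_{\ell n} r^{-(n+1)}\big]
  \big(P_n(\cos\gamma_\mathrm{src}) - P_n(\cos\gamma_\mathrm{snk})\big),$$

with $\varphi$ and $\sigma\,\partial_r\varphi$ continuous at the
interfaces, $B = 0$ innermost, and the surface condition
$\sigma\,\partial_r\varphi|_R = (2n+1)\,I/(4\pi R^2)$ per harmonic (the
point-source pair expanded in Legendre polynomials). Coefficients are
propagated inner→outer per degree in radius-scaled form (no overflow up
to a few thousand degrees), and terms are accumulated with Kahan
compensation. The default truncation is $N = 300$; verification runs use
$N = 800$ because the series converges geometrically in $r/R$ and the
numerical sphere's boundary sits at $r/R \approx 0.978$, where several
hundred terms are needed for eight significant digits. The homogeneous
limit has an independent closed form,
$\varphi = \tfrac{I}{4\pi\sigma R}\big[\tfrac{2}{S} + \log\tfrac{2}{1 - tc + S}\big]$
with $t = r/R$, $c=\cos\gamma$, $S=\sqrt{1-2tc+t^2}$, coded separately
and used as the equivalence oracle (agreement to $4\times10^{-14}$).

**Percentile Dirichlet construction.** A point electrode cannot be
represented in the finite-volume mesh, so the numerical sphere is 2 mm
smaller than the analytic electrode sphere and the analytic potential is
imposed as Dirichlet data on the boundary faces whose $|\varphi|$ exceeds
its 85th percentile over all boundary faces (the two polar caps); the
remaining 85 % of the boundary gets zero-gradient Neumann. Reading the
percentile on $|\varphi|$ (not signed $\varphi$) keeps the construction
antisymmetric — both caps are selected. The Neumann closure on the
equatorial band is an approximation (the true analytic field has a small
radial component there) and is part of the modeled error.

**NRMSD.** $100\cdot\mathrm{RMS}(a-b)/(\max b - \min b)$ with the
analytic field as reference $b$. The range normalizer is the common
convention; because the choice matters (the mean-normalized value is
far larger when the domain average is near zero), `sphere_verification()`
reports all three normalizers (range, mean |·|, max |·|).

**Study conditions.** The three-layer head phantom: analytic radii
92/85/80 mm (scalp/skull/brain), conductivities 0.465/0.01/0.33 S/m,
numerical outer radius 90 mm, antipodal point electrodes, 1 mA. The
verification mesh uses icosphere subdivision 4 with radial layers
(2, 2, 32) — 542,720 cells, about 2.5 mm radial resolution and 6 mm
angular resolution — chosen as the smallest body-fitted mesh above half a
million cells; the measured range-normalized NRMSD is ≈ 0.2 %, and the
error decreases monotonically under refinement (subdivision 2 → 3 → 4).
Smoke-level runs in the test-suite use subdivisions 2–3 (8,000–32,000
cells), where the NRMSD is still below 1 %.

# Electrode geometry

The 10–20 grid is constructed from the four fiducials by the standard
arc-fraction scheme: Cz is the fixed point of alternately bisecting the
nasion–inion and tragus–tragus arcs (converged when successive estimates
move < 0.1 mm; an error after 100 iterations), midline and central
positions sit at 10 %/20 % arc-length fractions, and the outer positions
lie on the 10 % circumferential ring through Fpz/Oz. Arcs are measured
along plane–surface intersection polylines (the plane through the two
end points and a third reference point), which on a sphere are great
circles; F3/F4 and P3/P4 are placed at midpoints of the Fz–F7/F8 and
Pz–T5/T6 arcs, one of several conventions in use. Arcs are measured on
the surface as provided — if a smoothed scalp is wanted, smooth before
positioning.

Footprints (rectangle, circle as a 64-gon, convex polygon) are clipped
from the scalp by Sutherland–Hodgman clipping against the prism swept
along the outward normal at the center (no geodesic wrapping; this
matches cutting with a box), followed by duplicate-vertex merging and
collapsing edges shorter than $10^{-3}$ mm. Extrusion proceeds in 1 mm
steps along per-vertex normals, the last step sized to reach the exact
thickness (2.5 mm → layers of 1, 1, 0.5 mm), so electrode side walls
avoid long thin triangles; the final offset copy is the equipotential
outer face set. For volume meshes, `tag_electrode_on_mesh()` realizes the
complete electrode model without re-meshing: cells under the footprint
are relabeled to the electrode compartment down to the electrode
thickness, measured inward from the *local* boundary surface (so the
tagged slab follows a curved scalp), producing the `<name>_outer`
boundary patch and the `<name>_contact` interface patch. An optional gel
layer can be modeled as a second, thicker tagging pass with its own
conductivity before the electrode pass; it is omitted by default.

# Conductivity tensors

Isotropic compartments get $\sigma\,\mathbb{I}$ from the tissue table.
White-matter anisotropy uses the volume-constraint mapping from a
co-registered diffusion tensor $D = S\Lambda S^\top$: the conductivity
tensor shares the eigenvectors,
$\sigma_T = S\,\mathrm{diag}(\sigma_\mathrm{main},\sigma_\mathrm{aux},\sigma_\mathrm{aux})\,S^\top$,
with the two constraints
$\sigma_\mathrm{WM}^2 = \sigma_\mathrm{main}\sigma_\mathrm{aux}$ and
$\sigma_\mathrm{main} = 10\,\sigma_\mathrm{aux}$, i.e.
$\sigma_\mathrm{main} = \sigma_\mathrm{WM}\sqrt{10}$,
$\sigma_\mathrm{aux} = \sigma_\mathrm{WM}/\sqrt{10}$. The geometric mean
of the extreme eigenvalues is pinned to the scalar tissue value, so no
unreasonable conductivities can result regardless of the diffusivity
units. Both transverse eigenvalues are set to $\sigma_\mathrm{aux}$ by
construction (the stated diagonal form), even where $\lambda_2 \neq
\lambda_3$ in $D$. Eigenvalues are sorted descending; eigenvector signs
are fixed deterministically (largest-magnitude component positive) for
reproducibility — the output tensor is invariant to this choice except
on exactly degenerate inputs. Tensors are transferred to cells by
nearest-voxel sampling at the centroid (no tensor interpolation, which
would raise swelling questions the mapping is not designed to answer);
NaN tensors and out-of-grid centroids fall back to isotropic
$\sigma_\mathrm{WM}$ with a reported count, and `spd_repair()` clamps
eigenvalues below $10^{-12}$.

# Synthetic data, and what the tests do not show

All fixtures are generated in code: layered-sphere label images (voxel
labels by the innermost covering layer), body-fitted sphere meshes with
exact interface radii, the orthogonal slab, and synthetic tensor volumes
(uniform, and an azimuthal "swirl" whose principal direction is known
analytically). These phantoms have smooth, nested, analytically known
geometry; passing the verification suite demonstrates the correctness of
the discretization, the analytic series, the tensor mapping and the
bookkeeping, but *not* the anatomical fidelity of any real head model:
segmentation, registration, and DWI preprocessing are explicitly out of
scope, and real cortical geometry (thin CSF sheets, skull holes, gyral
folds) stresses mesh quality in ways a sphere cannot. Mesh quality is
reported per run (non-orthogonality per internal face — angle between the
face area vector and the centroid line — skewness, and the count of faces
above 70°, beyond which the two-point flux degrades and the correction
loop carries more weight).

# Numerical choices and known limitations

* Percentiles use linear interpolation between closest ranks (R type 7),
  stated wherever reported; statistics are per-cell by default with a
  volume-weighted option.
* Point-in-polyhedron queries use three jittered ray directions with a
  majority vote; points within numerical distance of a face follow the
  surface entry order. Non-nested overlapping surfaces are resolved by
  entry order — the behavior of the reference meshing library for partial
  overlaps is not specified, so surfaces should be provided nested.
* The isosurface extractor is a marching-tetrahedra contouring of the
  0/1 indicator at iso-level 0.5 on the 6-tet dual-grid split; it always
  yields watertight, outward-oriented surfaces. Its single-voxel chord
  behavior differs from classic marching cubes (the enclosed volume of an
  isolated voxel is half the voxel volume); for structures a few voxels
  across and larger the volume error is well under 5 %.
* GMSH output is format 2.2 ASCII with physical volume tags carrying
  compartment labels and physical surface tags carrying patch ids; newer
  GMSH format versions are rejected explicitly. ANALYZE carries spacing
  but no origin; NIfTI carries both (axis-aligned only, no oblique
  orientations).
* Taubin smoothing uses uniform umbrella weights (λ = 0.5, μ = −0.53,
  50 step pairs), the common mesh-tool default; cotangent weights are not
  implemented.
* The deferred-correction loop's residual normalization is the RHS norm;
  other codes normalize differently, so outer iteration counts are not
  directly comparable across implementations even at the same nominal
  tolerance.
* `integrate_current()` on interpolated cell fields across high-contrast
  interfaces is not conservative (differences of tens of percent are
  possible at electrode contacts); use the flux-based form for electrode
  currents, as `solve_tes()` does.
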