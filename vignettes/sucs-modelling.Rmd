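---
title: "Volume-conductor modelling of subdural cortical stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-conductor modelling of subdural cortical stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sucsim)
```

## The model

Subdural cortical stimulation (SuCS) injects current through disc
electrodes placed beneath the dura, directly on the cortical surface. At
stimulation frequencies the tissue behaves as a passive resistive volume
conductor, so the potential $V$ obeys the quasi-static conduction equation

$$\nabla \cdot (\sigma \nabla V) = 0 \quad \text{in } \Omega,$$

with $V = V_0$ on the active electrode contact(s), $V = 0$ on the grounded
reference surfaces, and $\mathbf{J}\cdot\mathbf{n} = 0$ (insulation) on all
other outer boundaries. The current density is
$\mathbf{J} = -\sigma\nabla V$. Capacitive and electrode-interface effects
are deliberately absent: the model is purely resistive, and the 50 Hz
qualifier on the activation threshold below is metadata, not physics.

`sucsim` realizes this model on a parametric *extruded-slab* geometry of
the precentral gyrus region: a box with a CSF layer under the top
(subdural) surface, a gray-matter sheet of constant thickness draped over
a folded cortical profile, and white matter beneath. The fold profile is a
periodic cosine-walled groove (gyral crowns of width `gyral_width`
separated by sulci of width `sulcal_width` and depth `sulcal_depth`),
extruded along the y axis. The gray-matter sheet is defined by true
Euclidean distance to the fold surface in the cross-sectional plane, so
both banks of a narrow sulcus are cortex, as in real anatomy. The exact
crown curvature of this stand-in profile is a modelling choice, not an
anatomical reconstruction; anyone replicating a specific published slab
should treat the profile function as the thing to swap.

### Geometry and mesh parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `extent_x/y/z` | 60 x 60 x 40 | mm | slab bounding box (z up, top at `extent_z`) |
| `gyral_width` | 12 | mm | width of a gyral crown |
| `sulcal_width` | 3 | mm | width of the sulcal groove |
| `sulcal_depth` | 15 | mm | fold depth below the crown |
| `gm_thickness` | 2.5 | mm | cortical sheet thickness |
| `csf_thickness` | 2 | mm | CSF between crown and subdural plane |
| `resolution_h` | 0.8 | mm | target element edge length |

Defaults are typical human precentral-gyrus dimensions at desk scale (the
default mesh has 1.69M tetrahedra and 295k nodes). `resolution_h` must not
exceed `gm_thickness` so the cortical sheet is at least one element thick;
violating this raises an error rather than silently mislabeling tissue.

Meshing is a structured hexahedral grid split six tetrahedra per cell
(Kuhn subdivision). This is deliberate: meshes are deterministic,
tessellate the box volume exactly (to round-off), refine by exactly 8x
when `resolution_h` halves, and make point location an integer
computation. The cost is that tissue interfaces are voxelized at the
element scale rather than conforming — see *Convergence* below for where
that matters. Electrodes are disc patches on the top surface: the facets
whose centroids fall inside the disc define the patch geometry and area,
while the Dirichlet (equipotential) node set is the top-surface nodes
inside the disc radius. The distinction matters: constraining every
vertex of the selected facets would grow the effective disc by up to one
cell and biases the spreading resistance low by tens of percent at coarse
resolution (the half-space benchmark below made this visible). The
five-contact paddle is a quincunx (four corner contacts at
`contact_spacing` = 10 mm from the middle contact), all five wired to the
same potential; single-electrode mode drives only the middle contact. The
slab's side and bottom surfaces are grounded, providing the distant
unipolar return.

### Conductivity

Isotropic tissue values (S/m): white matter 0.126, skull 0.01, scalp/body
0.465 (standard reported values for this model family), gray matter 0.276
and CSF 1.65 (conventional literature defaults — the model family this
package follows cites them from external sources, so treat them as
editable defaults, not measured constants). White matter can instead carry
a symmetric positive-definite tensor per element, built from a fiber
eigensystem two ways:

* **Volume-constraint normalization**: raw (diffusion) eigenvalues
  $\lambda_i$ are scaled to conductivity eigenvalues
  $\sigma_i = \sigma_{iso}\,\lambda_i / (\lambda_1\lambda_2\lambda_3)^{1/3}$,
  preserving the tensor determinant at $\sigma_{iso}^3$ while keeping the
  input anisotropy shape.
* **Fixed ratio**: prescribed longitudinal:transverse ratio $r$ (2, 5 or
  10) under the same volume constraint, giving
  $\sigma_{long} = r^{2/3}\sigma_{iso}$ and
  $\sigma_{trans} = r^{-1/3}\sigma_{iso}$.

Whether the fixed-ratio convention should instead pin one eigenvalue at
$\sigma_{iso}$ is not determinable from the sources this package follows;
the volume-preserving convention is used because it keeps both families
determinant-consistent, and it is isolated in `fixed_ratio_eigenvalues()`
so it can be swapped in one place. The longitudinal eigenvector is the
fiber direction; the two transverse eigenvalues are equal (axial
symmetry), so the transverse basis is an arbitrary orthonormal
completion. Fractional anisotropy summarizes the eigenvalue dispersion;
for fixed-ratio tensors it depends only on $r$ (0.41, 0.77, 0.89 for
r = 2, 5, 10).

### Synthetic fiber fields

The package downloads nothing: fiber fields stand in for what DTI would
provide. `uniform` is a constant direction (used in the anisotropic bar
oracle), `random_smooth` a seeded, spatially correlated random unit field
(correlation length 5 mm), and `u_fiber` the anatomically motivated
default: directions normal to a smoothed copy of the fold surface, so
fibers run up the gyral stalk and bend outward under the sulcal walls.
The surface is smoothed with a 5 mm Gaussian before taking normals — a
fiber-curvature scale chosen so the field turns by less than 30 degrees
between neighboring elements at the default resolution instead of
following the near-vertical sulcal wall. The synthetic raw eigenvalues
(default prolate shape $(1.2, 0.4, 0.4)\times 10^{-3}$) only matter
through their ratios after volume-constraint normalization; they are
stand-ins, not measurements, and the package labels them as such. What
these fields do *not* emulate: crossing fibers, the corpus callosum and
internal capsule architecture, and subject-specific variability — so
passing tests validate the tensor machinery and the qualitative
anisotropy effects, not any subject-level prediction.

## The solver

First-order (P1) tetrahedral finite elements; the element matrices are
assembled vectorized over all elements, and with geometry in mm and
conductivity in S/m the stiffness entries come out in mS, so nodal
reactions are directly in mA. Dirichlet conditions are eliminated
symmetrically (no penalty terms), keeping the reduced system symmetric
positive definite, and constrained nodes carry their prescribed values
exactly. Two solver paths share that reduction:

* `cholesky` — supernodal sparse Cholesky (CHOLMOD), used automatically
  below 80k unknowns; exact to round-off.
* `mg` — conjugate gradients preconditioned by a geometric multigrid
  V-cycle (trilinear prolongation between the nested structured lattices,
  Galerkin coarse operators, damped-Jacobi smoothing), used automatically
  above 80k unknowns. Default relative-residual tolerance 1e-8; the
  295k-node default slab solves in a few seconds, and results agree with
  the direct path to well below 1e-6 of the applied voltage.

Electrode current uses the residual method by default — summing the nodal
reactions $(KV)_i$ over the constrained patch nodes — which is the
consistent discrete flux and conserves charge to round-off; a direct
surface integral of $\mathbf{J}\cdot\mathbf{n}$ over the patch facets is
available for cross-checking. A small overshoot of the discrete maximum
principle (up to about $10^{-6} V_0$) is tolerated; the structured
right-angle tets keep it at round-off level in practice.

Solver validation rests on closed forms: a homogeneous bar (P1 reproduces
the linear field exactly, so impedance matches $L/(\sigma A)$ to 1e-8),
an affine patch test, an anisotropic bar with axial fibers (axial current
$\sigma_{long} V_0 / L$), and a 4 mm disc on a large homogeneous block
versus the half-space spreading resistance $1/(4\sigma a)$ (7% at 1 mm
resolution, 3.4% at 0.5 mm, within 5% as required at the validated
resolution; the grounded box at 10 disc radii itself accounts for a few
percent of the remaining gap).

## Stimulation metrics

A motor current-density threshold (MCT) of 2.5 A/m² defines passive
activation. **Effective volume** sums the volume of gray- and
white-matter elements with $|\mathbf{J}|$ at or above threshold
(inclusive at equality — the boundary case is stated because it is
otherwise easy to implement inconsistently), reported in cm³. CSF is
excluded by default: it carries the highest current density but contains
no excitable tissue; the eligible-region set is configurable.
**Effective depth** is the distance from the (middle) electrode center
along the inward surface normal to the farthest suprathreshold sample,
with the ray sampled at every grid-plane crossing plus a fixed 0.1 mm
step, in cm. **Impedance** is $V_0/I$ with $I$ the measured electrode
current, and current-controlled stimulation is realized by linear
rescaling of the 1 V solution — exactly the Ohm's-law conversion the
model family uses, and exact here because the problem is linear.

Amplitude sweeps (0.5–5 V in 0.5 V steps; 1–16 mA in 2 mA steps) use the
threshold-rescaling identity: at scale $k$, the suprathreshold set equals
$\{|\mathbf{J}_{1V}| \ge \text{MCT}/k\}$, so one linear solve serves the
whole table; tests verify this against brute-force re-solving at several
amplitudes.

## Convergence design

`run_convergence()` compares solutions across mesh levels by
interpolating the coarse solution at the fine nodes and reporting the
maximum absolute difference as a percentage of the applied voltage. Two
design points matter:

1. **Refinement is nested along the depth axis** (the top two thirds of
   the z-layers are halved, growing the element count by 5/3). The
   rectilinear grid keeps the fine cells exactly inside coarse cells.
2. **The material model is frozen**: fine elements inherit the tissue
   label of the parent element, and the top-surface triangulation (hence
   the electrode Dirichlet set) is untouched.

Both are needed for the metric to measure discretization error at all.
Re-voxelizing the tissue labels at the finer resolution moves the CSF/GM
interface by a fraction of a cell and re-selecting electrode facets moves
the disc rim; either change modifies the *problem*, not just its
discretization, and the maximum nodal difference is then dominated by
those modelling shifts (an order of magnitude larger at the rim). On the
default slab the remaining inter-level difference concentrates in the
first element layers under the electrode, where the disc-rim field is
singular and the uniform 0.8 mm mesh is coarse relative to the 2 mm disc
radius; a three-level study shows the metric decreasing level over level,
i.e. the discretization is consistent. Convergence-class checks in this
package run the default slab (1.69M elements) against a 2.80M-element
refinement; all other tests use a reduced slab (30 x 24 x 24 mm, ~100k
elements) that keeps every geometric feature.

## Degenerate inputs and numerical choices

Non-SPD conductivity tensors are rejected at assembly naming the first
offending element; zero or negative raw diffusion eigenvalues are
rejected before normalization; a solve without any grounded node is
refused as singular; an electrode whose disc captures no facet centroid
or no surface node errors out (resolution/position mismatch) instead of
silently shrinking; ray queries that miss the mesh error out. Ties in
point location (points exactly on cell faces or Kuhn diagonals) resolve
deterministically toward the lower permutation index; depth-ray samples
bracket each grid-plane crossing at ±1e-6 mm so element-constant fields
are sampled on both sides. All randomness (only the `random_smooth`
generator consumes any) flows through one seed, with the caller's RNG
state restored.

## Known limitations

* The slab is a stand-in geometry: absolute effective volumes/depths are
  not comparable to realistic-anatomy models, which is why the package's
  checks of published values are restricted to Ohm's-law conversions of
  the published impedance table and to directional (ordering) properties
  — paddle vs single contact, strong anisotropy vs isotropy.
* Tissue interfaces are voxelized, not conforming; near-interface fields
  carry first-order geometric error at the element scale.
* Quasi-static and purely resistive; no electrode-tissue interface
  impedance, no frequency dependence, no neuron models — the MCT
  threshold is a bulk current-density criterion, uniform across regions.
* One printed row of the published impedance table
  (slab/isotropic/single, 467.3 Ω with 2.70 mA) does not satisfy
  $V = IZ$ at 1 V; the package ships the table with that row flagged
  `self_consistent = FALSE` and excludes it from worked examples.

## A worked example

```{r example, eval = FALSE}
spec <- slab_spec()                      # default precentral-gyrus slab
mesh <- build_slab_mesh(spec)
paddle <- place_paddle_array(mesh)       # five 4 mm contacts, quincunx
ref <- designate_reference(mesh)         # grounded side + bottom
field <- build_conductivity_field(mesh)  # isotropic tissue table
sys <- assemble_system(mesh, field)
sol <- solve_potential(sys, boundary_conditions(paddle, ref, V0 = 1))
I <- electrode_current(sol, sys, paddle)
estimate_impedance(1, I)
sweep_metrics(sol, mesh, paddle[[3]], I0 = I)
```

The same pipeline, driven from a single configuration, is
`run_experiment(experiment_config(), "outdir")`, which archives the
configuration, the sweep table, the solved field (VTU) and a run log.
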