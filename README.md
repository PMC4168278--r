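# sucsim

Finite-element simulation of subdural cortical stimulation (SuCS) on a
parametric volume-conductor model of the precentral gyrus region.

Subdural cortical stimulation drives current through disc electrodes
placed beneath the dura, directly on the cortical surface, to treat motor
disorders and pain. How much tissue a given amplitude actually recruits —
and how that depends on the electrode configuration (a 5-contact paddle
vs a single contact), on white-matter anisotropy, and on
voltage-controlled vs current-controlled stimulation — is a
volume-conductor question. `sucsim` is for researchers who want a fully
self-contained, deterministic R implementation of that pipeline: no
imaging data, no external mesher, no downloads.

## The model

The tissue is a passive resistive medium, so the potential obeys the
quasi-static conduction (Laplace) equation

∇·(σ∇V) = 0 in Ω,  V = V₀ on the electrode contact(s),  V = 0 on the
grounded reference surfaces,  J·n = 0 elsewhere,

with current density J = −σ∇V. The domain is an extruded-slab model of
the gyral anatomy: CSF under the subdural plane, a 2.5 mm cortical sheet
folded over cosine-walled sulci, white matter beneath; side and bottom
surfaces are grounded as the distant unipolar return. White matter is
isotropic (0.126 S/m) or anisotropic via tensors built from a fiber
field: volume-constraint normalization of raw eigenvalues
(σᵢ = σ_iso·λᵢ/(λ₁λ₂λ₃)^⅓) or a fixed longitudinal:transverse ratio r
with σ_long = r^⅔ σ_iso, σ_trans = r^(−⅓) σ_iso. The solver is P1
tetrahedral FEM on a structured Kuhn-subdivided grid (sparse Cholesky
below ~80k unknowns, geometric-multigrid CG above). Stimulation effect is
quantified against a motor current-density threshold (MCT, 2.5 A/m²):

* **effective volume** — cm³ of gray/white matter with |J| ≥ MCT;
* **effective depth** — cm from the electrode center along the inward
  normal to the farthest suprathreshold point;
* **impedance** — V₀/I with I the measured electrode current, linking
  voltage mode and current mode through Ohm's law (V = I·Z).

## A worked example

A reduced slab (30 × 24 × 24 mm, 1 mm resolution — the full default is
60 × 60 × 40 mm at 0.8 mm) with the 5-contact paddle at 1 V:

```r
library(sucsim)
spec <- slab_spec(extent_x = 30, extent_y = 24, extent_z = 24,
                  gyral_width = 12, sulcal_width = 3, sulcal_depth = 10,
                  gm_thickness = 2.5, csf_thickness = 2, resolution_h = 1)
mesh <- build_slab_mesh(spec)
#> labeled_tet_mesh: 19375 nodes, 103680 tets
#>   regions: CSF=12960, GM=22560, WM=68160
paddle <- place_paddle_array(mesh)          # five 4 mm discs, quincunx
ref    <- designate_reference(mesh)         # grounded side + bottom
field  <- build_conductivity_field(mesh)    # isotropic tissue table
sys    <- assemble_system(mesh, field)
sol    <- solve_potential(sys, boundary_conditions(paddle, ref, V0 = 1))
I      <- electrode_current(sol, sys, paddle)
1000 * I                                    # 48.0 mA at 1 V
estimate_impedance(1, I)                    # 20.8 ohm
sweep_metrics(sol, mesh, paddle[[3]], I0 = I)
#>     mode amplitude effective_volume_cm3 effective_depth_cm
#>  voltage       0.5                 5.47                0.9
#>  voltage       1.0                 8.33                1.5
#>  voltage       1.5                10.15                2.0
#>  voltage       2.0                11.63                2.4
#>  ...
```

Reading: at 1 V the paddle drives 48 mA through this small grounded slab
and recruits 8.3 cm³ of cortex/white matter above 2.5 A/m², reaching
1.5 cm below the middle contact. Absolute numbers scale with the slab
geometry and the proximity of the grounded boundary — the small demo slab
has a much lower impedance than the default one — which is why
comparisons across electrode configurations or conductivity models are
done on a common geometry (`compare_models()`), and only *ratios and
orderings* should be read as anatomy-independent.

The same pipeline from one config object, with archived outputs
(`summary.csv`, solved field as VTU, log):

```r
run_experiment(experiment_config(electrode_mode = "paddle",
                                 conductivity_model = "ratio_10"),
               "runs/paddle_r10")
```

A thin CLI wraps the same functions:
`Rscript inst/cli/sucsim.R sweep --config cfg.yaml --out rundir`.

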