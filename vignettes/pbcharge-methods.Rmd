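---
title: "pbcharge: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pbcharge: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbcharge)
```

# The physical model

`pbcharge` treats a molecule in monovalent electrolyte at the mean-field
continuum level. Three nested descriptions of its charge are computed.

**Structural charge.** Each ionizable group `i` (pK_i, valence z_i = ±1)
contributes `z_i / (1 + 10^{z_i (pH − pK_i)})` elementary charges; the sum
is the ideal-solution value `q_str`, with no electrostatics at all.

**Regulated charge.** A globular molecule is a uniform dielectric sphere
(radius R, interior dielectric constant ε_p) carrying its groups as
uniform volume densities. The sphere is transparent to protons but
impervious to salt ions. The ionized fraction of a group at position r is

α(r) = 1 / (1 + 10^{z (pH − pK_a)} · exp{z ψ̃(r) + φ_s + φ_0}),

where ψ̃ = eψ/k_BT is the local dimensionless potential, φ_0 an optional
non-electrostatic offset (0 by default), and

φ_s = p · (l_B,m / 2 r_A) · (ε_m/ε_p − 1) ≥ 0

is the Born penalty for holding the ionized form (radius r_A, default
0.25 nm) in the low-dielectric interior; `p ∈ (0, 1]` attenuates the
penalty to absorb contributions the continuum picture omits (H-bonding,
local polarizability). For ε_p = 40 in water this is ≈ 1.4 k_BT for a
carboxylate; at ε_p = 10 it reaches ≈ 9.8 k_BT and buried acids are
essentially discharged at neutral pH. The potential solves

* interior (Poisson): ∇·(ε_p/ε_m ∇ψ̃) = −4π l_B,w Σ_i z_i α_i(ψ̃) ρ_i,
* electrolyte (nonlinear PB): ∇²ψ̃ = κ² sinh ψ̃,

with ψ̃ and ε ∂ψ̃/∂n continuous at the surface and a zero-flux outer
boundary 10 Debye lengths out (overall electroneutrality). The regulated
charge `q_s` integrates Σ z_i α_i ρ_i over the molecule, and
η_g = q_s/q_str. Linear polyelectrolytes (polypeptides, ssDNA, dsDNA) are
rigid hollow cylinders of diameter 0.5 / 1 / 2 nm at full extension
(0.38 nm per residue, 0.34 nm per base or base pair), their groups a
uniform *surface* density regulating against the local surface potential;
no interior dielectric constant enters. Screening uses the salt only —
protons contribute to the chemistry but not to κ, a good approximation
between roughly pH 3 and 11 at millimolar-and-up ionic strengths.

**Effective (interaction) charge.** A far-field probe sees less than
`q_s`: the strongly bound part of the counterion cloud travels with the
molecule. We adopt the interaction definition: place the object, held at
constant charge Q, at the mid-plane of a parallel-plate slit whose walls
carry like-signed constant charge, compute the object–slit interaction
free energy F_os from the constant-charge functional

F = ∫ { ε ε₀ E²/2 − 2 c₀ k_B T (−ψ̃ sinh ψ̃ + cosh ψ̃ − 1) } dV,

as F_os = F(slit + object) − F(bare slit) − F(isolated object), and set

q_eff = F_os / ⟨ψ̃′(s)⟩,

where ⟨ψ̃′(s)⟩ averages the *bare-slit* potential over a virtual contour
tracing the object's surface. For weak charges F_os → Q⟨ψ̃′⟩ and
η_n = q_eff/Q → 1; for strongly charged objects F_os falls below Q⟨ψ̃′⟩
and η_n < 1 — charge renormalization. Regulation is frozen during these
runs (the regulated charge in a slit with κz* ≳ 3 is essentially the free-
solution value, so Q = q_s is imposed as constant charge).

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| temperature | 298.15 | K | enters l_B and κ |
| solvent dielectric ε_m | 78.5 | — | water at 25 °C |
| ion radius r_A | 0.25 | nm | Born penalty scale (carboxylate) |
| Born attenuation p | 1 | — | softens φ_s (0.25 fits buried-lysine data) |
| interior dielectric ε_p | per model | — | the one genuinely tunable knob for folded proteins; inferable from a measured charge via `infer_interior_dielectric()` |
| slit gap κz* | 4 | — | extraction is insensitive over ≈ 1–8; 3–5 optimal |
| wall potential | 0.5 | k_BT/e | keeps walls in the linear regime; q_eff moves < 5% when halved |
| lateral truncation | 10 | Debye lengths | domain size; < 0.5% effect on q_s |
| pKa table | shipped YAML | — | Asp 4.0, Glu 4.3, Lys 10.4, Cys 8.2, His 6.0, Arg 12.0, Tyr 10.0, termini 8.0/3.6, phosphate 2.0; all overridable |

# Numerics

All solvers are vertex-centred finite-volume discretizations on graded
meshes, with the nonlinearity handled by damped Newton iteration
(line-searched, charge-ramped continuation; convergence when the maximum
potential update falls below 1e-8). The Jacobian `−L + diag(κ² cosh ψ̃ V)`
is symmetric positive definite and solved sparsely via the Matrix
package. A damped Picard iteration with a Debye–Hückel preconditioner is
implemented alongside as an independent cross-check of the Newton path
(they agree to < 1e-7 on test problems).

Meshes anchor fine spacing at charged surfaces — the target spacing
resolves the local Gouy–Chapman length (1/(2π l_B σ), down to a few
hundredths of a nm for DNA-like charge densities) — and coarsen linearly
away from anchors, capped at a quarter Debye length. Spheres in the 2-D
tensor-product grids are staircase-represented: control volumes crossing
the surface get fractional electrolyte volumes by subsampling, and the
surface charge is deposited from a deterministic Fibonacci lattice
(bilinear, 4000 points). Cylinders are grid-aligned and exact.

**Free energy in dual form.** The functional above is evaluated as

F = Σ_i q_i ψ̃_i − Σ_faces C_f (δψ̃_f)²/(8π l_B) − Σ_i κ² V_i (cosh ψ̃_i − 1)/(4π l_B),

which equals the field-gradient + ionic integral at a converged solution
but is *exactly* compatible with the discrete operator. This matters: the
three-run difference F_os then obeys the discrete work identity, and the
(large) object self-energy discretization errors cancel between the
slit+object and isolated-object runs, which share one mesh. With a naive
cell-gradient quadrature the weak-charge limit of q_eff was biased by
~15%; in dual form it is exact to the cavity-depletion term (below).

A consequence of the staircase spheres: their raw self-energy converges
only linearly with mesh size (≈ 2% change on halving), but the extracted
q_eff converges to < 1% because the error cancels in the difference. The
grid-convergence tests therefore assert convergence of F for grid-aligned
geometry and of q_eff for spheres.

**Orientation of cylinders in the slit.** Finite fragments (tens of nm)
sit on the symmetry axis, perpendicular to the walls — the axisymmetric
geometry. A quasi-infinite rod must instead lie *parallel* to the walls
so that its whole length interacts; this is the translationally invariant
planar problem (circle cross-section between two lines), solved per unit
length. A long perpendicular rod interacts only through its ends and
reports end-condensation, roughly twice the Manning fraction — a geometry
artifact, not physics of the infinite rod.

**Problem sizes.** The 1-D solves use 70–300 nodes (< 0.1 s). The 2-D
slit runs use roughly 50×100 to 100×250 nodes and complete in 0.5–3 s
each; an effective-charge extraction is three such solves. The full test
suite runs in ≈ 40 s, the benchmark script in ≈ 1 min, on one CPU.

# Design choices where the design was open

* **Reference state for F_os.** F(z* → ∞) is realised as bare-slit plus
  isolated-object energies on the shared mesh (the isolated run reuses
  the slit box with uncharged walls; residual image coupling decays as
  e^{−2κz*} ≈ 3·10⁻⁴ at the default gap). The z*-independence of q_eff
  (< 5% over κz* ∈ [3, 5], < 1% in the benchmark cases) validates the
  decomposition.
* **Ion-excluding cavity and the weak-charge limit.** Even an uncharged
  object perturbs the slit (it expels screening charge), so η_n exceeds 1
  slightly for weakly charged objects at κR ≳ 0.5 — by ≈ 1% at κR = 0.16,
  ≈ 3% at κR = 0.33, ≈ 15% at κR = 1. This is a property of the
  interaction definition itself (the denominator uses the *bare* slit
  potential), consistent with η_n > 1 reported for weakly charged rods at
  κR = 1 in the renormalization literature.
* **Manning comparison regime.** The classical condensed-fraction formula
  min(1, λ/l_B) is the zero-radius limit. The PB effective line charge of
  a finite-radius rod is genuinely larger: at κR = 0.1 the saturated
  λ_eff l_B plateaus near 1.2, and our sweep at ξ = l_B/λ ∈ [2, 6] sits
  12–13% rms above the Manning fraction; the deviation falls below 5%
  only for κR ≲ 0.05. The package reports the rms against Manning as
  computed and ships the sweep machinery; finite-κR condensation
  formulas can be plugged in as additional comparators.
* **Core–shell self-interaction.** A single buried residue smeared over a
  0.5–0.6 nm core titrates partly against its own reaction field. Two
  modes are exposed: `self_interaction = "included"` (default) keeps the
  coupling — it reproduces the upward ≈ 0.1 pKa shift on shrinking the
  core from 0.6 to 0.5 nm and leaves a residual ≈ +0.25 shift in a
  bulk-like environment; `"excluded"` titrates against the environment
  potential only (shell charge + electrolyte), recovering the nominal
  pKa exactly when there is no dielectric contrast and no shell charge.
  The Born term, computed from the core dielectric with attenuation p,
  carries the self-solvation physics in either mode.
* **Regulation of finite cylinders** uses the infinite-cylinder surface
  potential scaled to the full inventory; end effects on regulation are
  neglected (they matter for renormalization, which is treated in full
  2-D, but regulation of low-pKa surface groups is a percent-level
  correction to begin with).
* **Thresholds.** The regulation-onset potential |ψ̃_t| floors at zero
  when the Born penalty exceeds the chemistry term, and the result is
  flagged degenerate (the group regulates at any potential). The
  rule-of-thumb criterion |Q_t| l_B,p/R exposes the assumed
  surface-potential contribution explicitly (default 2 k_BT, a high-salt
  estimate).

# What the benchmark fixtures do and do not show

The canonical fixture set (`generate_fixtures()`) is built entirely from
closed forms and idealized geometries: uniform spheres, uniform
cylinders, printed group inventories. Passing them shows that the coupled
regulation/renormalization machinery reproduces the analytic limits
(Debye–Hückel, Bessel-function cylinder, Gauss's law, electroneutrality,
superposition in the slit) and the published benchmark numbers for those
idealized models. It does not show that a real protein is a uniform
sphere: spatially resolved charge placement, local dielectric
heterogeneity beyond the two-domain core–shell, ion–ion correlations,
ion-specific and finite-size effects, dielectric saturation at
interfaces, and conformational flexibility are all outside the model. The
interior dielectric constant absorbs much of this and should be read as
an effective folded-state parameter, not a material constant.

# Known limitations

* Mean-field PB: no ion–ion correlations; monovalent salt only; validity
  degrades when the Debye length approaches the Bjerrum length (≫ 100 mM).
* Tensor-product meshes staircase curved surfaces; raw sphere
  self-energies are first-order accurate (differences are what converge).
* Strong wall potentials (|ψ̃_wall| ≫ 1) are outside the validated
  extraction regime; the default keeps walls linear.
* The pI and ε_p-inference machinery needs the molecule's composition;
  compositions of specific proteins are not shipped.
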