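# pbcharge

Mean-field continuum electrostatics for biomolecular charge in solution.
Given a molecule's ionizable-group inventory (or its sequence), the pH and
the monovalent salt concentration, `pbcharge` computes the three distinct
"charges" that govern its solution electrostatics:

* **structural charge** `q_str` — the ideal Henderson–Hasselbalch sum
  `q_str = Σ_i z_i / (1 + 10^{z_i (pH − pK_i)})` over all ionizable
  groups, ignoring electrostatic feedback;
* **regulated (true net) charge** `q_s` — obtained by coupling each
  group's ionization equilibrium,
  `α = 1 / (1 + 10^{z (pH − pK_a)} exp(z ψ̃ + φ_s + φ_0))`,
  to the local dimensionless potential ψ̃ from a self-consistent solution
  of the interior Poisson equation and the exterior nonlinear
  Poisson–Boltzmann (PB) equation `∇²ψ̃ = κ² sinh ψ̃`, including the Born
  penalty `φ_s = p (l_B,m / 2 r_A)(ε_m/ε_p − 1)` for groups buried in a
  low-dielectric interior;
* **renormalized (effective, interaction) charge** `q_eff` — the charge
  that reproduces the molecule's electrostatic interaction free energy
  with a like-charged parallel-plate slit,
  `q_eff ⟨ψ̃′(s)⟩ = F_os(z*)`, where `⟨ψ̃′(s)⟩` is the bare-slit potential
  averaged over a virtual contour tracing the object surface and `F_os` is
  a difference of constant-charge free-energy functionals
  `F = ∫ { ε ε₀ E²/2 − 2 c₀ k_B T (−ψ̃ sinh ψ̃ + cosh ψ̃ − 1) } dV`.

It is aimed at biophysicists who need fast, structure-free estimates of
protein and nucleic-acid charge: charge-regulation factors η_g = q_s/q_str
for globular proteins, counterion-condensation factors η_n = q_eff/Q for
polyelectrolytes (with the classical Manning fraction min(1, λ/l_B) as a
built-in comparator), titration curves and isoelectric points, interior
dielectric constants inferred from measured charges, and pKa shifts of
buried residues from a core–shell model.

The solvers are graded-mesh finite-volume discretizations with damped
Newton iteration: 1-D radial (sphere, multilayer core–shell, infinite
cylinder), 1-D planar (slit), 2-D axisymmetric (sphere or finite cylinder
in a slit) and 2-D planar (infinite cylinder parallel to the slit walls).
Typical solves take well under a second.

## Worked example

A compact globular protein is modelled as a dielectric sphere of radius
5.1 nm with interior dielectric constant 20, carrying 12.75 acidic groups
(pK_a 4) as a uniform volume density — a charge-to-size ratio Q/R = 2.5
e/nm typical of folded proteins:

```r
library(pbcharge)

cond <- solution_conditions(pH = 7, salt_molarity = 0.1)
cond
#> Electrolyte: pH 7.00, 0.1 M monovalent salt, T = 298.15 K, eps_m = 78.5
#>   Bjerrum length lB = 0.7140 nm, Debye length 1/kappa = 0.9620 nm

m <- sphere_model(radius = 5.1, interior_dielectric = 20,
                  groups = group_set(list(ionizable_group(4, -1, label = "acid")),
                                     12.75))
regulated_charge(m, cond)
#> Charge report (pH 7.00, 0.1 M salt):
#>   q_str = -12.7373 e, q_s = -10.1610 e, eta_g = 0.7977
#>   surface potential -0.2244 kBT/e
```

Although essentially every group is ionized in the ideal picture
(q_str ≈ −12.74 e), the negative interior potential and the Born penalty
push the protonation equilibria back: the molecule actually carries only
q_s ≈ −10.16 e, i.e. about 80% of its structural charge.

Renormalization is the complementary phenomenon, seen by a far-field
probe. A 60-bp DNA fragment (hollow cylinder, diameter 2 nm, length
20.4 nm) held at its regulated charge of −121.4 e in 1 mM salt:

```r
cond1 <- solution_conditions(pH = 8.8, salt_molarity = 0.001)
dna60 <- cylinder_model(radius = 1, length = 20.4, constant_charge = -121.4)
effective_charge(dna60, cond1)
#> Effective charge: q_eff = -47.588 e (Q = -121.400 e, eta_n = 0.3920)
#>   F_os = 0.366 kBT, <psi'(s)> = -0.007692, kappa z* = 4
```

In an interaction it behaves as if it carried only ~48 e — less than 40%
of its true charge — because the tightly bound counterion layer screens
the rest.

Sequence-based building, titration and the command line:

```r
m <- build_from_sequence("EEEE", "protein")   # 4 Glu + termini, D = 0.5 nm rod
structural_charge(m$surface_groups, pH = 7)   # -4.08 e
```

```sh
inst/cli/pbcharge qs --sequence EEEEEEEE --kind protein --ph 7 --salt-mM 100
# q_s = -7.2237 e (eta_g = 0.8946)
```

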