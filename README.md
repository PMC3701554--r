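# opcharge

Optimal point charge approximations of molecular charge distributions.

## The problem

Biomolecular electrostatics constantly trades detail for speed: a charge
group (an amino-acid side chain with its backbone atoms, a water
molecule) is replaced by something cheaper before its potential is
evaluated at a distance. The classical replacement — a truncated point
multipole expansion — is accurate in the far field but awkward in
point-charge-based software and degrades quickly in the *mid-field*, a
few multiples of the group's spatial extent, exactly where amino acids
in a folded protein see each other.

`opcharge` implements the alternative: replace the distribution with a
small number of **optimally placed point charges** whose multipole
moments reproduce the original's to the highest order the charge count
allows. The approximation is found by *sequentially* minimizing the
terms of the moment-discrepancy expansion

$$\varepsilon^2(R) = \sum_{l} w_l(R) \sum_{m} \bigl|q_{lm} - q'_{lm}\bigr|^2,$$

monopole first, then dipole, and so on ($q_{lm}$ are spherical multipole
moments; the weights follow from the orthonormality of the spherical
harmonics). If moments agree through order $n$, the potential error is
guaranteed to fall off at least as fast as $R^{-(n+2)}$ — the far-field
behavior of the multipole expansion, retained by a plain set of point
charges. Closed forms are provided for the common cases:

* `opca1()` — one charge for a charged group: the net charge at the
  *center of charge* (monopole and dipole terms vanish);
* `opca2_neutral()` — a symmetric pair about the *center of dipole*
  along the dipole direction, charge magnitude from the closed-form
  octupole minimization, with a small-separation fallback when that
  solution would be imaginary;
* `ppca2_neutral()` / `ppca2_charged()` / `ppca2()` — the *practical*
  two-charge constructions with empirical constants (fixed separation
  0.1 Å; principal-axis placement with distance ratio 1.5; a 1.5 ×
  extent position bound protecting the mid-field);
* `solve_opca()` / `solve_opca_constrained()` — the general numeric
  solver for any charge count, also usable against target moments under
  symmetry constraints;
* `solve_water_c2v()` — the symmetric three-charge solution for a C2v
  target such as the water molecule: monopole, dipole and quadrupole
  matched exactly, octupole error minimized over the remaining freedom.

Charge sets are tibbles (`x`, `y`, `z` in Å, `q` in e); results come
with `tidy()`, `glance()` and `autoplot()` methods. Moments, potentials
(`coulomb_potential()`, `multipole_potential()`), error metrics
(`moment_discrepancy()`, `shell_error_quadrature()`, `rms_error()` on
`sphere_grid()` evaluations), PQR/xyzq I/O and a synthetic generator of
amino-acid-like charge groups round out the toolkit. A thin CLI lives at
`inst/cli/opcharge.R` (subcommands `moments`, `opca`, `ppca`, `water3`,
`evaluate`, `synth`).

## Worked example: a three-charge water model from gas-phase moments

The gas-phase water molecule (frame: origin at oxygen, molecule in the
y–z plane, z bisecting the hydrogens) has dipole 1.81 D, quadrupole
diagonal (0.08, −2.53, 2.45) D·Å and octupole components
(−1.35, −1.25, 2.61) D·Å². Three charges under C2v symmetry match
everything through the quadrupole exactly; the octupole term fixes the
last degree of freedom:

```r
library(opcharge)
sol <- solve_water_c2v(water_qm_moments())
sol
#> <c2v_solution> three-charge C2v optimal point charge approximation
#>   pair:    q = +14.4589 e at (0, -0.1546, 0.4872) and (0, +0.1546, 0.4872) A
#>   central: q = -28.9178 e at (0, 0, 0.4741) A
#>   octupole (D.A^2): zzz -1.17, xxz -1.44, yyz 2.61
cartesian_moments(sol$charge_set)$p / 0.2082   # back in debye
#> [1] 0.00 0.00 1.81
```

The three charges cluster ~0.5 Å from the oxygen on the hydrogen side —
nothing like atom-centered models, and a direct consequence of matching
the octupole: for fixed dipole and quadrupole, the spatial extent of the
model is controlled by the octupole, and the small separation forces the
large magnitudes. The achieved moments reproduce the targets —
`p_z = 1.81` D, `Q_xx = −2.53` D·Å by construction, and the octupole
(−1.17, −1.44, 2.61) D·Å² as close as the remaining freedom allows. The
conventional atom-centered baseline (`water_atom_centered()`: −0.643 e
on O, +0.322 e on each H, dipole-matched) gets the quadrupole badly
wrong; `rms_profile()` shows what that costs in potential at any radius.

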