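---
title: "Optimal point charge approximations: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal point charge approximations: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opcharge)
```

## The problem

Molecular electrostatics calculations routinely replace a detailed charge
distribution — the partial charges of an amino-acid side chain, or the
electron density of a water molecule — with something cheaper. The
classical tool is the truncated point multipole expansion: keep the
monopole, dipole, maybe the quadrupole, and accept an error that decays
with distance. Point multipoles are, however, awkward to bolt onto
software built around point charges, and their accuracy deteriorates
quickly in the *mid-field*, at distances comparable to a couple of times
the spatial extent of the group.

`opcharge` implements the alternative: approximate the distribution by a
small number of *optimally placed point charges* whose multipole moments
reproduce those of the original to the highest achievable order. Such an
approximation keeps the far-field asymptotics of the multipole expansion
— if moments agree through order $n$, the potential error falls off at
least as fast as $R^{-(n+2)}$ — while remaining a plain set of point
charges, and, being spatially extended, it can beat the point expansion
in the mid-field.

## Moments, potentials and the error metric

For charges $q_i$ at positions $\mathbf r_i$ the package computes the
monopole $M$, dipole $\mathbf p$, and traceless quadrupole and octupole
in the Buckingham ($\tfrac12$-prefactor) convention:

$$\Theta_{ab} = \tfrac12 \sum_i q_i\,(3 r_a r_b - r^2\delta_{ab}), \qquad
\Omega_{abc} = \tfrac12 \sum_i q_i\,\{5 r_a r_b r_c -
r^2(r_a\delta_{bc} + r_b\delta_{ac} + r_c\delta_{ab})\}.$$

Units are $e$ and Å throughout; potentials are reported in $e/\text{Å}$
with the $1/4\pi\varepsilon_0$ factor dropped; dipole moments convert to
debye at $1\,\mathrm{D} = 0.2082\,e\cdot$Å. Spherical moments
$q_{lm} = \sum_i q_i r_i^l Y^*_{lm}(\theta_i,\varphi_i)$ use orthonormal
complex spherical harmonics (Condon–Shortley phase); `cart_to_spherical()`
is the exact linear bridge for $l \le 3$, and every tensor object carries
its convention string.

The error between two truncated expansions about a common center is
measured order by order. By orthonormality of the $Y_{lm}$, the mean
squared difference of the truncated potentials over a sphere of radius
$R$ (or a shell, when an inner radius is supplied) decomposes as

$$\varepsilon^2(R) \;=\; \sum_l w_l(R) \sum_m \lvert q_{lm} - q'_{lm}\rvert^2,$$

with closed-form, $R$-dependent weights per order. `moment_discrepancy()`
implements this decomposition and `shell_error_quadrature()` — a
Gauss–Legendre radial rule crossed with a Gauss–Legendre-in-$\cos\theta$
× trapezoid-in-$\varphi$ angular rule, exact for the low-order spherical
polynomials involved — serves as its independent oracle; the two agree to
$10^{-6}$ relative and better in the test suite. Because each order
carries its own power of $R$, minimizing the per-order terms does not
depend on $R$: the method needs no arbitrary "fitting surface", which is
its key advantage over potential-derived charge fitting.

## The sequential (lexicographic) principle

The optimal $n$-charge approximation minimizes the error expansion
*sequentially*: first the monopole term, then — within that minimizer
set — the dipole term, and so on. Matching a term exactly zeroes it;
when a term cannot be zeroed (a two-charge pair cannot reproduce a full
quadrupole tensor), its minimum value is locked in before the next order
is considered. With as many charges as the original distribution the
original itself is a solution, and the approximation becomes exact.

### Closed forms

* **One charge, charged group** (`opca1()`): charge $M$ at the center of
  charge $\sum q_i\mathbf r_i/M$; monopole and dipole terms vanish.
* **Two charges, neutral group** (`opca2_neutral()`): charges $\pm q$
  placed symmetrically about the *center of dipole* along
  $\hat{\mathbf p}$, with $q\,d = |\mathbf p|$. The center of dipole

  $$\mathbf R_0 = \frac{2\,\Theta\mathbf p}{3|\mathbf p|^2} -
    \frac{(\mathbf p^{T}\Theta\mathbf p)\,\mathbf p}{6|\mathbf p|^4}$$

  minimizes the quadrupole term (a symmetric pair has no quadrupole about
  its own center, so the residual is the distribution's own traceless
  quadrupole there, and that norm is minimal at $\mathbf R_0$). The
  remaining freedom — the charge magnitude — minimizes the octupole term,
  giving $q = \sqrt{|\mathbf p|^3 / (4\,\Omega_{\hat p\hat p\hat p})}$
  where $\Omega_{\hat p\hat p\hat p}$ is the octupole about
  $\mathbf R_0$ contracted three times with $\hat{\mathbf p}$. When that
  contraction is negative the closed-form charge would be imaginary:
  shrinking the pair always helps, and the solver falls back to the
  configured small separation (flagged `small_separation`).
* **Two charges, practical variants** (`ppca2_neutral()`,
  `ppca2_charged()`): the *practical* constructions trade the octupole
  optimization for empirical constants suited to repeated evaluation
  inside simulations. The neutral recipe fixes the separation at
  `d_sep` (default 0.1 Å — small against the ≈3 Å extent of amino-acid
  groups, inside the flat region of the error-vs-separation curve) and
  pulls the pair center back towards the center of geometry whenever a
  charge would stray beyond 1.5 × the extent (a mid-field guard for the
  cases where the center of dipole escapes the distribution). The
  charged recipe places both charges on the principal axis of the
  quadrupole with the largest absolute eigenvalue, matches that
  principal component exactly along with $M$ and the center of charge,
  and closes the remaining freedom with the distance ratio
  $r_1 = \kappa\,r_2$, $\kappa = 1.5$ (empirical; the smaller-magnitude
  charge takes the larger distance). When the principal value and the
  net charge have opposite signs an opposite-sign pair on one side of
  the center of charge realises the match; the construction degenerates
  gracefully when the quadrupole vanishes.

### The numeric solver

`solve_opca()` handles any $n$ and also serves as the oracle against
which the closed forms are tested. Two structural observations shape it:

1. *Charges enter every moment linearly.* At fixed positions the charges
   are eliminated exactly by lexicographic linear least squares
   (sequential SVD with nullspace propagation), so the outer search runs
   only over the $3n$ position coordinates.
2. *Stages with a non-zero minimum create flat, curved valleys.* After
   the quadrupole term of a dipole pair is locked, the octupole stage
   moves along a one-dimensional manifold (the pair separation) on which
   naive stiff penalties stall. Each stage therefore runs in two phases:
   a quadratic-penalty continuation to reach the constraint manifold,
   followed by a reduced-space refinement that pins the earlier-order
   *residual channel vectors* (these are constant along the manifold,
   and pinning vectors rather than norms keeps the restoration objective
   smooth and positive semi-definite), reads the tangent space off the
   near-null eigenvectors of its numerical Hessian, and walks the
   tangent directions with re-projection after every step. The
   near-null cutoff is deliberately generous: a wrongly included
   direction merely fails to improve after re-projection, whereas a
   missed tangent direction leaves the stage stuck.

Multi-start (default 16 seeds: center-of-charge/center-of-dipole
constructions, the original positions when $n = N$, and random
placements within the extent sphere, under a fixed seed) guards against
the nonconvexity of the position landscape. Stage minima at the
numerical noise floor are clamped to zero so that tolerance slack cannot
leak into later stages — without the clamp, a $10^{-11}$ residual
recorded as a stage "minimum" lets later stages tilt the solution by
$10^{-4}$ in parameter space. `solve_opca_constrained()` applies the
same stage engine to a reduced parameter vector defined by a symmetry
specification, with targets given as moments rather than as a charge
set.

## The three-charge C2v solution for water

For a C2v target — the gas-phase water molecule in its standard frame
(origin at oxygen, molecule in the $y$–$z$ plane, $z$ bisecting the
hydrogens) — three charges suffice to match monopole (zero), dipole and
the full traceless quadrupole exactly. With a mirror pair $q_1$ at
$(0, \pm y, z_1)$ and $q_3 = -2q_1$ at $(0, 0, z_3)$, the constraints
reduce to

$$q_1 y^2 = \tfrac13(\Theta_{yy} - \Theta_{xx}), \quad
  q_1 (z_1^2 - z_3^2) = -\tfrac13(2\Theta_{xx} + \Theta_{yy}), \quad
  2 q_1 (z_1 - z_3) = p_z,$$

which leave one free parameter; following the sequential principle it is
fixed by minimizing the octupole term. `solve_water_c2v()` parameterizes
the family by $z_3$, scans a bounded bracket (default `[0, 1.2]` Å on a
4801-point grid, restricted to the branch where the mirror offset is
real) and refines the minimum by a golden-section search to $10^{-9}$ Å.
The octupole objective is the rotationally invariant contraction
$\Delta\Omega_{zzz}^2 + 3\Delta\Omega_{xxz}^2 + 3\Delta\Omega_{yyz}^2$,
proportional to the $l=3$ spherical channel norm for traceless
differences; an unweighted component sum is available behind
`objective = "cartesian"` for sensitivity analysis (it is not
rotationally invariant and selects a visibly different family member —
a useful illustration of why the invariant weighting matters).

One numerical subtlety: published moment tables are rounded, and the
printed octupole components may fail the trace identity
$\Omega_{zzz} + \Omega_{xxz} + \Omega_{yyz} = 0$ by a last digit. The
solver projects the target tensors onto exact tracelessness first.
Without the projection the rounding defect — not the physics — would
select the point on the solution family, and the two objective variants
would disagree even in the invariant case.

```{r water}
sol <- solve_water_c2v()
sol
```

The tight clustering of the three charges near ≈0.5 Å from the oxygen —
far from the atom centers — is a genuine feature of the octupole-level
optimization, and the small pair separation forces the large charge
magnitudes (the dipole is fixed while the separation shrinks). The
atom-centered baseline `water_atom_centered()` matches the dipole only
and misses the quadrupole badly; `rms_profile()` quantifies how much
that costs in the potential.

## What the synthetic generator does and does not emulate

`random_charge_set()` draws amino-acid-like groups: 5–30 point charges
uniform in a 3 Å sphere, raw partial charges uniform within ±1 e shifted
so the net charge is exactly the requested integer, and
`random_charge_ensemble()` mixes them 80 % neutral / 20 % charged — the
composition of protein charge-group cohorts. This reproduces the
*statistical shape* of a biomolecular benchmark (extents, net charges,
moment magnitudes) but not its chemistry: real partial charges are
correlated with geometry (bonds, electronegativity), while the generator
is isotropic. Two consequences matter for interpreting the test suite:

* Passing the cohort-level accuracy checks here says the algorithms are
  implemented correctly, not that the error statistics on real proteins
  will be numerically identical.
* The generator occasionally produces geometries rarer in real groups —
  in particular charged sets whose center of charge lies far outside the
  distribution, where the fixed-ratio charged pair lands well outside
  the extent and its neglected octupole inflates the finite-distance
  RMS error relative to the point dipole, even though the order-resolved
  error metric still favors the pair. The far-field acceptance check is
  therefore phrased in terms of the metric (which is what the
  construction guarantees), plus strict RMS dominance in the regime
  where the closed-form pair exists, plus the cohort-level mean
  advantage.

`degenerate_fixtures()` freezes the edge cases every solver must handle:
a pure physical dipole, a neutral zero-dipole quadrupole (square of
alternating charges, for which two-charge constructions are undefined by
design), a weak-dipole/strong-quadrupole set whose center of dipole
escapes the extent (exercising the practical bound shift), and a set in
the negative-octupole-contraction regime (found by rejection sampling
over generator seeds and frozen by seed).

## Numerical choices and limitations

* **Tolerances.** A set is neutral when $|M| < 10^{-8}$ e; a dipole
  below $10^{-10}$ e·Å is treated as absent (force-field charges are
  rounded; exact-zero tests are brittle). Stage residuals below
  $10^{-10}$ (squared moment units) count as pinned.
* **Eigen-decomposition determinism.** Principal quadrupole axes are
  ordered by descending $|\lambda|$; each eigenvector is flipped so its
  largest-magnitude component is positive; magnitude ties within
  $10^{-12}$ break by descending signed eigenvalue, then
  lexicographically.
* **Grids.** Sphere sampling uses a deterministic Fibonacci spiral with
  equal solid-angle weights (no seams, no poles); every evaluation
  carries a grid descriptor. The benchmark-style RMS evaluations use
  7200 points; property tests use 300–1000 points, which changes RMS
  values by well under the tolerances asserted.
* **Problem sizes.** The test suite runs the numeric solver on 2–8
  charge instances with 2–4 restarts and the wide equivalence sweep on
  100 instances; the constrained water cross-check runs from a single
  structured start. These sizes were chosen to probe every code path at
  full precision while keeping the suite comfortably interactive.
* **Out of scope.** Moments above the octupole; continuous charge
  densities (consume their printed moments instead); periodic boundary
  conditions, reaction fields, forces; analytic three-charge solutions
  for arbitrary non-symmetric targets (use `solve_opca()`); simulation
  -ready water models — the three-charge solution here reproduces gas
  -phase moments, which is a statement about electrostatics, not about
  liquid-water thermodynamics.
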