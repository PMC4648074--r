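---
title: "Continuum electrostatics on a grid: models, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum electrostatics on a grid: models, numerics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

`fdpb` treats a solute as a rigid set of atoms — positions, van der Waals
radii, fixed partial charges — embedded in a dielectric continuum. Three
regions have distinct physics:

* **solute interior**: low dielectric (ε_in, default 2.0), Poisson equation
  with the atomic point charges as sources;
* **solvent**: high dielectric (ε_out, default 80.0) with mobile ions whose
  density follows a Boltzmann distribution; linearized (sinh Φ ≈ Φ, valid
  for |Φ| of a few kT/e) this adds the screening term κ²Φ with
  κ² = 8π N_A e² I_s / (1000 ε_out k_B T);
* **ion-exclusion (Stern) layer**: solvent dielectric but no mobile ions,
  within `radius + ion_radius` of any atom center.

An implicit membrane is a planar slab zmin ≤ z ≤ zmax carrying its own
dielectric ε_mem and, like the solute, no mobile ions: a lipid interior of
ε ≈ 2 cannot dissolve ions, so the screening map is zeroed there (this is a
modelling choice; the slab is otherwise treated as just another bulk
medium). Where the solute spans the slab, solute midpoints keep ε_in — the
protein, not the lipid, occupies that volume. The slab can be given
explicitly (`mem = zmin,zmax,eps`) or derived from an atom selection
(e.g. the phosphorus atoms of the lipid headgroups): the selection is split
at its median z and the mean z of each leaflet becomes the slab face. Atom
masses are not part of any input format the package reads, so the leaflet
"center" is the unweighted mean; selections whose leaflet means are closer
than 10 Å are rejected as single-leaflet input, since no bilayer is that
thin.

Internal units are Å for length, elementary charges, and kT/e for the
potential; energies are reported in kcal/mol and kT. Every conversion goes
through one constant, f = e²/(4π ε₀) = 332.0637 kcal mol⁻¹ Å e⁻²
(`physical_constants()`), as f/(k_B T) — the vacuum Bjerrum length — which
multiplies charge/distance into kT/e.

## Discretization

All fields live on a uniform cubic grid: charge and screening at the
nodes, dielectric values at the midpoints of the three staggered
half-grids. The box is a cube centered on the solute's bounding box;
`filling` (default 80%) sets how much of the box edge the solute's largest
dimension occupies, `spacing` (default 1 Å) the resolution, and the point
count per axis is kept odd so the box center is a node. Exactly two of
{filling, spacing, grid size} are free; the third follows.

Atomic point charges are spread onto the eight corners of the enclosing
cell with trilinear (cloud-in-cell) weights. This conserves total charge to
machine precision and reduces grid-placement artifacts relative to
nearest-node assignment; the assignment rule is a discretization choice
with no single canonical answer, and trilinear is the common one in
finite-difference Poisson–Boltzmann codes.

The finite-difference form of the LPBE at a node is

Φ₀ = (Σₖ εₖ Φₖ + 4π q₀ f/(h k_B T)) / (Σₖ εₖ + (κ₀h)²)

with the six neighbor potentials Φₖ and midpoint dielectrics εₖ. Solvent
nodes carry the *modified* screening value ε_out·κ² in the (κ₀h)² term;
with that convention the discrete solution decays with the physical Debye
constant κ, which the Debye–Hückel validation below pins down (an extra
factor of ε_out, the plausible alternative reading, produces a visibly
wrong decay length).

## The molecular surface on the grid

Dielectric assignment follows the solvent-excluded surface (SES), not the
bare van der Waals (vdW) surface:

1. each midpoint is inside iff it lies strictly within some atom's vdW
   sphere (scanned per atom over the atom's bounding sub-box);
2. outside midpoints adjacent to boundary nodes are tested against the
   solvent-accessible surface (SAS, atom radii + probe, default water
   probe 1.4 Å): a midpoint deeper below the SAS than the probe radius
   cannot be touched by any probe sphere and is flipped to inside;
3. node labels (internal / boundary / external) are recomputed and step 2
   repeats until nothing flips. Flips are one-directional, so termination
   is guaranteed; passes proceed front-by-front into reentrant regions.

The SAS depth uses nearest-point projection with overlap rejection: the
radial candidate on each probe-extended sphere is discarded when it falls
inside another extended sphere; when all candidates are rejected the
nearest SAS point lies on an intersection seam and the distance to the
two-sphere seam circle is used (exact for pairwise overlaps). The cruder
fallback — deepest single-sphere penetration — systematically
underestimates the depth near the neck between atoms and misclassifies a
few percent of midpoints there; the seam distance brings the disagreement
with a brute-force probe-placement oracle to well under 1% at h = 0.5 Å on
the two-sphere fixture. For a convex (single-atom) solute the SES equals
the vdW surface and reclassification is exactly a no-op, which is asserted
in the tests.

Boundary nodes are projected onto the SES for the induced-charge energy:
along the line to the generating atom's center when the nearest SAS point
lies on a single extended sphere (convex case — the two-step projection
reduces to exactly this), or via the seam circle and back by one probe
radius onto the reentrant probe patch otherwise. Ties between equidistant
atoms break to the lowest atom index, deterministically.

## Solver

The discrete system is solved by Gauss–Seidel with successive
over-relaxation in red-black (checkerboard) ordering: all even-parity
nodes are updated, then all odd-parity ones, newly computed values being
used immediately. The sweep kernel is compiled (Rcpp); the per-node
denominator and source are precomputed, which makes the general stencil
branch-free — the uniform "mean of six neighbors" fast path and its
salt-modified variant are the special cases exposed by `stencil_update()`
for inspection and testing.

Boundary families: fixed zero faces; quasi-Coulombic faces (screened
two-center formula from the total positive and negative charge and their
charge-weighted centroids; pure Coulomb when there is no salt); and
per-axis periodic wrapping, composable (a membrane setup is typically
periodic in x, y and quasi-Coulombic in z). For the homogeneous reference
solve of the energy calculation the quasi-Coulombic face values use ε_in,
consistent with that solve's own analytic far field.

Iteration stops as soon as *any* criterion fires: rms change per sweep
below `rmsc` (default 1e-4 kT/e), maximum change below `maxc` (default
1e-4 kT/e), or `maxit` sweeps (default 500). The fired criterion is
reported. The initial guess is zero except for the fixed faces; a
divergence guard aborts if the rms change grows tenfold over twenty
sweeps.

The relaxation factor defaults to ω = 2/(1+√(1−λ²)) with λ the spectral
radius of the Jacobi iteration operator, estimated matrix-free by power
iteration: deterministic half-sine start vector (constant along periodic
axes), Rayleigh quotient in the diagonally weighted inner product, cap 500
iterations, relative tolerance 1e-7 on successive estimates. The cap and
tolerance are set so the estimate resolves the small eigenvalue gap of
Laplacian-like operators (the measured error against a dense eigensolve on
a 15³ grid is ~1e-15); a looser cap stalls an order of magnitude short.
If the iteration fails to settle, the uniform-grid closed form (mean of
per-axis cosines) is used with a warning. The formula variant
ω = 2/(1+√(1−λ)) — appropriate if λ already denotes the squared radius —
is available as `optimal_omega(variant = "radius_as_squared")`.

## Solvation free energies

**Reference subtraction.** ΔG = ½Σ q(Φ_het − Φ_hom) over the grid, where
the homogeneous solve replaces every dielectric by ε_in and removes the
salt, on the identical grid and charge map. The spread-charge self-energy
— large, unphysical and grid-dependent — cancels exactly between the two
terms. The factor ½ is the linear-response factor of a polarization
(reaction-field) energy; omitting it doubles the Born result, so the Born
validation fixes it unambiguously.

**Induced boundary charges.** One solve. At each boundary node b the
polarization charge is the residual of the uniform-ε_in stencil,

q_ind(b) = h/(4π f′) · (6Φ_b − Σₖ Φₖ) − q_b/ε_in,   f′ = f/(k_B T),

which is exactly zero in a homogeneous medium and, summed over the
boundary shell, telescopes to the continuum surface charge
q(1/ε_out − 1/ε_in) for a Born ion. The normalization of the real-charge
subtraction (q_b/ε_in, not q_b) follows from requiring the residual to
vanish at charged nodes deep inside the uniform interior. Induced charges
are placed at the SES projections of their nodes, and
G = ½ f′ Σ_b q_ind(b) Σ_p q_p/|b_s − x_p| runs over charged grid nodes
only (the term vanishes elsewhere). Pairs closer than h/2 are floored to
h/2 with a warning.

On the Born fixture at h = 0.25 Å the two methods agree to ~1.4% and both
sit within 1.5% of the closed form; on a charged two-atom dumbbell they
agree to ~2%.

## Synthetic fixtures and what the tests show

The package tests itself without external data:

* `make_born_ion()` — the analytic workhorse: closed-form solvation energy
  and, with salt, the Debye–Hückel sphere potential including the Stern
  shell;
* `make_dumbbell()` — the minimal reentrant surface (two r = 2 Å spheres
  5 Å apart leave no room for a 1.4 Å probe between them);
* `make_random_molecule()` — seeded random solutes (radii 1–2 Å, charges
  summing to an integer, 10 Å ball), for conservation and determinism
  properties;
* `make_random_maps()` — seeded structureless dielectric/screening maps,
  compared against `dense_system_oracle()`, an independently assembled
  sparse direct solve (no code shared with the iterative sweep);
* `brute_force_probe_oracle()` — probe placement by exhaustive search on
  an h/4 grid augmented with the exact radial candidates, the arbiter for
  the surface module.

These fixtures emulate the *geometry and physics* regimes of real
calculations — dielectric discontinuities, reentrant surfaces, screening,
membranes — at desk scale. They do not emulate real protein charge
distributions, conformational ensembles, or force-field parameter
variability; passing tests show the numerics are right, not that any
particular force field or structure preparation is.

Problem sizes were chosen to keep the full suite under a minute of compute
for the routine tests and a few tens of seconds for the validation runs:
Born and dumbbell energies at h = 0.25 Å (129³ and 81³ grids), the
screened-potential comparison at h = 0.25 Å, solver-oracle comparisons at
9³–11³, the surface oracle at h = 1.0 and 0.5 Å in full and at h = 0.25 Å
on a seeded 400-midpoint subsample (the exhaustive oracle scales as h⁻⁶
and is disproportionate at fine spacing).

## Numerical choices and degenerate inputs

* Odd grid sizes center the box on a node; fractional point counts round
  *up* to the next odd integer and the spacing is recomputed, so the
  requested box is never truncated.
* Atoms with radius 0 (e.g. unparameterized hydrogens in permissive mode)
  never generate inside midpoints and carry charge 0 when unmatched.
* A quasi-Coulombic boundary with a totally uncharged solute falls back to
  zero boundary with a warning (the formula is undefined).
* An all-periodic, salt-free, net-charged system is singular; with salt the
  diagonal grows and the system is well-posed (the translation-covariance
  test runs at I = 0.1 M for this reason).
* κ² < 0 is rejected; ε ≤ 0 is rejected; membrane slabs entirely outside
  the grid warn.
* Tie-breaks (nearest atom, equidistant projections) go to the lowest
  index; all randomness in fixtures is integer-seeded and restores the
  caller's RNG state.

## Limitations

* Linearized PBE only — no nonlinear solve; potentials far above a few
  kT/e are outside the model's validity.
* Sharp dielectric boundaries — no smoothed/Gaussian dielectric models.
* Flat slab membranes only; no curvature, no surface structure.
* Cubic, uniform, single-level grids — no focusing or multigrid; very
  large solutes at fine spacing pay the full O(N³) memory.
* No nonpolar (SASA) term, entropy, or pKa machinery: the output is the
  electrostatic component of solvation only.
* The induced-charge route assumes the boundary shell is resolvable at the
  chosen spacing; at very coarse grids (h ≳ 1 Å for small solutes) prefer
  the reference route.
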