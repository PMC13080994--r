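---
title: "Rigid-body crystal modelling and gradient-based structure search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body crystal modelling and gradient-based structure search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspkit)
```

## The reduced crystal representation

`cspkit` models homomolecular (Z′ = 1) molecular crystals as rigid bodies in
a 12-parameter chart: six cell parameters, a fractional centroid constrained
to the space group's asymmetric unit, and an axis-angle orientation relative
to the molecule's canonical *standard orientation*. This section records the
modelling choices behind that chart, their assumptions, and their known
limits — the package's tests exercise everything claimed here.

### Standard orientation

The standard orientation places the unweighted center of geometry at the
origin and the principal axes of the *mass-weighted* inertia tensor along
x, y, z with non-increasing moments. Two conventions required a decision:

* **Weighting.** The centroid is unweighted (a purely geometric origin);
  the inertia tensor is mass-weighted (the physical tensor). Either choice
  of weighting for the tensor yields a valid canonical frame; the
  mass-weighted one was chosen and is used consistently.
* **Sign and degeneracy resolution.** Eigenvectors are sign-fixed by the
  third moment of the coordinates along each axis; when that vanishes
  (mirror-symmetric directions) by the first atom with a non-negligible
  component; axes where *no* intrinsic rule decides — e.g. the normal of a
  planar molecule, along which every atom has zero component — are left
  free and used to enforce right-handedness (det = +1). Because every rule
  depends only on intrinsic quantities, the frame is invariant under rigid
  motion of the input, which the tests verify to 1e-8 Å. For molecules
  with exactly degenerate inertia spectra (e.g. ideal benzene) the
  in-plane frame is still deterministic for a fixed input but not
  rotation-invariant; the bundled fixtures deliberately break such
  degeneracies (the planar ring carries two fluorines).

### Molecular volume

There is no universally agreed molecular volume; packing coefficients are
only meaningful relative to one fixed calculator. `cspkit` uses the union
volume of Bondi-radius van der Waals spheres on a regular grid (default
spacing 0.1 Å, ~0.1% accuracy for the fixtures, halving the spacing moves
the estimate by < 1%). The grid is anchored in the standard orientation
with a fixed fractional offset so that no grid point sits exactly on a
sphere surface for lattice-aligned molecules — without the offset the
estimate is discontinuous under 1e-15 coordinate noise. Volume and radius
are therefore rigid-motion invariant to machine precision.

## Symmetry

Twelve space groups covering the dominant settings of organic crystals
(P1, P-1, P21, Pc, Cc, P21/c, C2/c, P21212, P212121, Pca21, Pna21, Pbca)
are hard-coded in their standard settings as general-position operator
lists. A small audited table was preferred to a general generator: closure,
identity membership, multiplicity and Hermann–Mauguin symbols are all
asserted by tests, and non-standard settings are rejected rather than
converted.

Each group stores a parallelepiped asymmetric unit. The boxes were chosen
to be *fundamental domains for the centroid orbit*: for a generic point,
exactly one symmetry image (mod 1) lies inside — a property the test suite
checks by direct orbit enumeration, and which parameter extraction relies
on for uniqueness. Their fractional volume is 1/Z exactly. Corner choices
for a given group are not unique; only these two properties are asserted.

### Cell-angle constraints

Symmetry operators are isometries of the crystal only when the cell metric
is compatible with the group: monoclinic groups (unique axis b) require
α = γ = 90°, orthorhombic groups require all three angles at 90°. The
public parameter chart keeps all six cell parameters so that losses remain
smooth functions of all twelve coordinates, but the random sampler draws
only the free angles and the optimizer projects the constrained ones back
to 90° at every bookkeeping rebuild. Without this, symmetry copies would
not be congruent and the homomolecular invariant would fail.

## Crystal building, clusters, and differentiability

Building applies each operator to the posed molecule's fractional
coordinates and wraps **molecule-wise** (keyed on the centroid), keeping
conformers rigid across cell boundaries. Clusters carve all periodic
images with any atom within a cutoff of the central molecule, enumerating
integer translations out to `cutoff + 2 · molecule radius` via interplanar
spacings.

During optimization the cluster bookkeeping — which (operator, lattice
translation) images are present and how each is wrapped — is **frozen**
and only rebuilt every `rebuild_every` (default 25) steps. Between
rebuilds every atom position is the smooth closed form

    X_m = Y Rᵀ T⁻¹ M_mᵀ T + (x M_mᵀ + s_m) T

(standard coordinates `Y`, Rodrigues rotation `R`, lattice matrix `T`,
operator rotation `M_m`, frozen total shift `s_m`), so every scalar
downstream — pair energies, packing coefficient, the stage losses — has an
analytic gradient in the 12 parameters, assembled by the chain rule with
the Gallego–Yezzi derivative of the Rodrigues map and the closed-form cell
Jacobian. Tests compare these gradients against Richardson-extrapolated
central differences (base step 1e-4 per coordinate) at random jammed
crystals and require 1e-4 relative agreement; the extrapolated oracle is
used because plain central differences at h = 1e-4 carry O(h²) truncation
error above 1e-4 near the steep r⁻¹² contacts of random dense seeds.

## Potentials

* **Lennard-Jones** 12-6 with per-element UFF parameters
  (σ = x_I/2^{1/6}, ε = D_I in kcal/mol; packaged as a YAML table) and
  Lorentz–Berthelot combining. The paper-standard parameter source for
  quick, auditable lattice energies — not a quantitative force field.
* **Softened repulsion** `U(r) = c · silu((σᵢⱼ − r)/w)` with
  `silu(x) = x/(1+e^{−x})`, defaults c = 1 kcal/mol, w = 0.5 Å. Finite at
  r = 0 and strictly decreasing throughout the repulsive core
  `[0, σ + 1.28 w]`, it lets overlapping molecules slide past one another.
  Note one deliberate property of this functional form: silu dips to
  −0.278 before returning to zero, so the potential has a shallow
  attractive well around r ≈ σ + 0.64 Å. In stage 1 this mildly favors
  cohesion and is harmless; monotonicity is only claimed (and tested) on
  the core.
* **Short-range electrostatics** `k qᵢqⱼ/r` with k = 332.06371
  kcal·Å/(mol·e²); charges default to zero and can be supplied via an
  extended-XYZ fifth column. No Ewald summation — this is a short-range
  screened term, tapered like the others.

All three are multiplied by a cosine taper (default width 1 Å) reaching
zero at the cutoff (default 6 Å), keeping cluster energies smooth as pairs
cross the cutoff. Intramolecular pairs never contribute (the central
molecule is excluded from its own neighbor list).

## RDF earth mover's distance

Packing similarity uses per-element-pair radial distribution histograms
(default 100 bins to 6 Å) of intermolecular central-to-neighbor distances.
Element-pair (not atom-index) resolution keeps crystals with different Z
comparable. For the distance, each pair histogram is normalized to unit
mass (all-zero histograms stay zero), the 1-D Wasserstein distance
Σ|CDF_p − CDF_q|·Δr is computed per pair, and the **mean** over the union
of pair keys is returned. Mean aggregation (rather than sum) keeps the
number interpretable as a length in Å independent of how many element
pairs a molecule has; symmetry, identity and the triangle inequality are
tested over random profiles, and the distance grows monotonically with
structural perturbation size on fixture crystals.

## The two-stage search

Random seeds draw the centroid uniformly in the asymmetric unit, a uniform
random orientation (random unit quaternion), free angles ~ N(90°, 8°)
within validity, and log-normal lengths around twice the molecule radius,
then rescale the cell isotropically so the packing coefficient equals the
target exactly. At realistic densities such seeds are essentially always
"jammed" — interpenetrating molecules with enormous LJ energies — which is
why stage 1 optimizes the *soft* potential plus
`w_density (CP − CP*)² + w_cell Σ max(0, len − l_max)²`
(defaults 100 and 1 kcal/mol; l_max 30 Å). Stage 2 refines the LJ energy
plus the same density term. The optimizer is Adam on the 12-vector
(lr 0.01/0.003, 300/200 steps by default) — chosen because the gradient
scales span many orders of magnitude between jammed and relaxed states —
with the chart projection (wrap centroid mod 1, re-branch rotation vector,
clamp angles) applied at every rebuild. Stage 2 applies a cosine
learning-rate decay to zero so the final state settles tightly into its
local minimum; `refine_crystal()` repeats decayed stage-2 rounds until the
per-round loss change falls below a relative tolerance, which is the
protocol used for the perturb-and-recover experiment.

Centroid wrapping during optimization uses lattice translations only
(always proper isometries). Wrapping into the asymmetric-unit box can
require an improper operator image, which for a chiral conformer is not
expressible with the same canonical molecule; final parameters are
re-canonicalized into the box through `extract_parameters()` where a
proper fit exists.

Samples whose final LJ energy lies above the 94th percentile of the batch
are flagged excluded (≈ 6% of samples, configurable); failures of any kind
flag the sample rather than aborting the batch, and the whole search is
bit-reproducible from its seed.

## Problem sizes and what the tests show

The bundled experiments run on synthetic rigid fixtures (a 12-atom planar
difluorinated ring, a 2-atom dumbbell, a seeded 10-atom blob) at modest
scale: 100-crystal roundtrips, 20-point gradient checks, a 64-seed Pna21
mini-search, 20 perturb-and-recover trials. These sizes were chosen to
exercise every code path densely while keeping the default suite quick to
run on one core. Passing them demonstrates internal correctness of the
geometry, symmetry, gradients and optimization machinery on rigid
molecules — it does not demonstrate chemical accuracy: UFF-LJ energies,
zero charges and rigid conformers are deliberate simplifications, and real
CSP additionally needs conformational flexibility, better energetics and
experimental reference data.

## Known limitations

* Z′ = 1, fully rigid molecules, no special (Wyckoff) positions, no
  disorder or partial occupancy.
* Twelve space groups in standard settings; others are rejected.
* Molecules with exactly degenerate inertia spectra lack a
  rotation-invariant canonical frame (fixtures avoid this).
* The CIF dialect is minimal (cell, symmetry strings, fractional sites)
  and intended for trusted files, not CSD-grade curation.
* Energies are classical pairwise with a 6 Å cutoff; no Ewald sums, tail
  corrections, or machine-learned potentials.
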