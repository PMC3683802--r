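---
title: "The coarse-grained capsid/NA assembly model: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coarse-grained capsid/NA assembly model: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(capsidsim)
```

# The model

`capsidsim` implements a coarse-grained model of small icosahedral viruses
that assemble around their single-stranded genome. The capsid is a
dodecahedron of 12 rigid pentagonal subunits, each standing in for a stable
pentameric intermediate. A subunit carries

* five **attractor** (`A`) pseudoatoms at the vertices of a regular pentagon
  (circumradius 1 Du = 5 nm), through which subunits attract each other with
  a Morse potential (minimum `r0` = 1 nm, width `rho` = 2.5, cutoff 10 nm,
  depth `epsilon` per contact);
* one **Top** (`T`) pseudoatom above and one **Bottom** (`B`) pseudoatom
  below the face center. `T`-`T` pairs repel with the repulsive branch of a
  Lennard-Jones potential of diameter `sigma_t` = 10.5 nm, and `B`-`T`
  pairs with diameter `sigma_b` = 9.0 nm. Together these guide bound
  subunits toward the dodecahedral dihedral (~116.6 degrees) and penalize
  upside-down binding;
* a single layer of **excluder** beads (diameter 3 nm for T=1 shells,
  5.25 nm for T=3) hexagonally packed across the pentagon face, dense
  enough that no cargo bead can slip between them: the impassable shell;
* five flexible **ARM** tails (15 for the T=3 parameterization), one bead
  per residue with charge -1, 0 or +1 e, anchored midway along the
  pentagonal radius on the inner face; the anchor bead is part of the rigid
  body, the rest of the tail is a bead-spring chain.

The cargo is either a linear polyelectrolyte (one bead per segment, charge
-1 e, diameter 0.5 nm) or a model nucleic acid with prescribed secondary
structure: single-stranded regions are fully flexible, double-stranded
segments are two adjoined strands joined nucleotide-by-nucleotide by
harmonic bonds, stiffened so an isolated duplex has a persistence length of
about 50 nm.

Electrostatics are screened Debye-Hueckel interactions with the
finite-ion-size prefactor

U_DH(r) = q1 q2 l_B exp(sigma/lambda_D) / (1 + sigma/lambda_D) * exp(-r/lambda_D) / r

in kBT, with Bjerrum length l_B = 0.714 nm and Debye length `lambda_D`
(1 nm at physiological salt). The term is switched smoothly to zero between
2 lambda_D and 3 lambda_D with the XPLOR polynomial
S(r) = (rc^2 - r^2)^2 (rc^2 + 2 r^2 - 3 ron^2) / (rc^2 - ron^2)^3, so both
the energy and force are continuous at the switch and at the cutoff.
Explicit-ion (bare Coulomb) electrostatics are deliberately out of scope;
`u_coulomb()` is a documented stub.

The total energy decomposes into six channels — capsomer-capsomer,
capsomer-polymer, capsomer-ARM, polymer-polymer, polymer-ARM, ARM-ARM — and
`total_energy()` reports exactly that decomposition. There are no
interactions between members of the same rigid body, and directly bonded
pairs are excluded from the nonbonded terms.

# Geometry choices

The printed parameterization fixes diameters and the inradius, not
coordinates, so the following constructions are the package's own:

* **Top/Bottom heights.** With one `T` per subunit on the face axis, the
  `T`-`T` contact condition at the ideal dodecahedral geometry gives the
  height h = sigma_t / (2 sin(psi/2)) - R_in, where psi = acos(1/sqrt(5))
  is the angle between adjacent face normals. Placing `B` at the mirror
  height makes the `B`-`T` distance come out at 8.93 nm, right at
  `sigma_b` = 9 nm — a consistency check that this reading of the geometry
  is the intended one.
* **Shell closure.** Faces are placed at exactly the requested inradius
  (7.3 nm for the standard model, chosen for interior volume). At that
  radius the paired attractors across each edge sit 0.79 nm apart, inside
  the Morse well whose minimum is at 1 nm; the builder reports the gap and
  refuses geometries where subunits interpenetrate or fall out of Morse
  range.
* **Excluders.** A hexagonal lattice with spacing `sigma_x`/2 clipped to
  the pentagon. The largest hole in that packing is far smaller than the
  excluder-polymer contact distance, so the face is impassable; the count
  is whatever the packing yields (~35 for the T=1 face).
* **T=3 shells** reuse the same 12-pentamer machinery scaled to the
  tabulated inradius, with 15 ARMs per subunit spread in a sunflower
  pattern and the larger excluder diameter. The full icosahedral
  asymmetric unit is intentionally not reproduced; the thermodynamically
  relevant degrees of freedom are the charge, its flexibility, and the
  interior volume.
* **Preset ARM sequences.** The preset table carries ARM length and net
  charge only. Charge sequences are synthetic: evenly spaced positive
  residues, except CCMV which uses its documented 11 positive / 1 negative
  split. `capsid_params()` accepts explicit sequences when the real one is
  known.

# The structured-cargo generator

`structure_spec()` fixes the contour length `LC`, base-paired fraction
`fbp` and segment length `Lbp` (typical values 1000 nt, 0.5, 5 nt).
Segments are placed uniformly at random without overlap; pairing is either
*hairpin* (each segment with the next) or *general*: iterating over
unpaired segments, a separation is drawn from an exponential distribution
with rate `lambda` and subtracted from the maximal pseudoknot-free
separation, so large `lambda` yields maximal separations, fully nested
structures and maximal ladder distance (MLD), while small `lambda` yields
hairpins and high-order junctions. Draws are rounded and clamped to the
admissible range.

One amendment proved necessary to honor the generator's contract that the
realized paired fraction equals `fbp` within one segment: the partner index
is adjusted by at most one position so that the number of segments enclosed
by each new pair is even. Without this parity rule, odd enclosed runs
strand one segment each (about 15% of segments at lambda ~ 1), and the
realized `fbp` and maximum MLD fall short.

The analysis side represents a pairing as a tree — one node per loop
(including the exterior), one edge per stem weighted by its base-pair count.
The MLD is the weighted diameter of this tree, the maximum MLD the total
base-pair count, and the junction-order histogram the node-degree
distribution (hairpin loops have order 1; the exterior node is included).
`fit_lambda()` matches ensemble-averaged junction histograms to a target by
1-D least squares, and `lambda_for_mld()` root-brackets the monotone
mean-MLD curve. Structures are geometric ensembles by construction: there
is no thermodynamic folding model, no pseudoknots, and pairing is static
during simulation. Passing tests on these ensembles therefore says nothing
about sequence-specific folding of real RNAs — only about the geometric
consequences of a given pairing statistics.

# Samplers

**Brownian dynamics** (`run_bd()`): overdamped Euler-Maruyama with
per-bead friction `gamma` = 1 kBT tu/nm^2 and time step 1e-4 tu. Rigid
bodies translate under their net force with friction `n gamma` and rotate
under their net torque with an isotropic rotational friction
`gamma sum r_i^2`, via small-angle quaternion updates renormalized each
step. Fluctuation-dissipation holds per degree of freedom, so equilibrium
averages are exact even though the isotropic mobility approximates the true
hydrodynamics; kinetic quantities are meaningful in reduced units only,
since the tu-to-seconds mapping is not fixed by the model. Nonbonded terms
use a Verlet pair list (skin 1 nm, rebuilt when any bead moves half a
skin), split into two groups that never interact across: the long-range
rigid-body types (`A`/`T`/`B`, handled all-pairs) and the short-range bead
types (cell grid at max(sigma_xp, sigma_xa, 3 lambda_D)). A step that would
move a bead farther than half the skin aborts with a diagnostic rather than
silently corrupting the neighbor list.

**Monte Carlo polymer sampling** (`mc_polymer_sampler()`): for unconfined
cargo, mixing (i) single-bead displacements, (ii) crankshaft rotations of a
backbone interval about the axis through its two anchors, and (iii) end
pivots about a random axis. Interval moves are proposed only when every
base-pair partner of the interval's interior lies within the interval
(checked in O(1) with sparse-table range queries) — a consequence of
pseudoknot-free nesting is that such closed intervals are abundant, from
hairpin tips to whole branches. A rigid rotation of a closed interval
changes only the two anchor angles and the moved/fixed cross energy, which
keeps the move cheap and exact. The proposal filter is symmetric (the
pairing is static), so detailed balance holds. Initial coordinates come
from a recursive arc-and-ladder layout (`na_initial_coords()`), relaxed by
a capped push-off before sampling; acceptance below 1% triggers one
amplitude-halving retry with a warning.

**Widom chain-increment insertions** (`widom_mu_r()`): the residual
chemical potential -beta mu_r(Np) = ln < exp(-beta U_I) > is estimated by
inserting a test segment at a chain end, with the bond length drawn from a
normal distribution matched to the bond Boltzmann distribution and
truncated at +-3 sd. The proposal bias is removed a posteriori by
importance weights w = l^2 exp(-beta U_bond(l)) / g(l); the normalizing
single-bond integral is restricted to the same truncation window, which
makes the estimator return exactly zero for a non-interacting chain (the
neglected tail mass is ~0.3% of the bond partition function, well below
sampling error). The new angle term is included in U_I when the chain is
semiflexible. `chemical_potential_curve()` reproduces the growth protocol:
relaxation dynamics between increments, insertions at each recorded length,
growth by a Boltzmann-sampled trial position.

**Replica exchange** (`run_rex()`): a geometric temperature ladder with
neighbor swaps accepted on (beta_i - beta_j)(U_j - U_i); replicas run
sequentially, and the acceptance fraction is reported. The ladder of the
reference protocol (12 replicas, 1 to 1.5 kBT) ships in the run configs.

# Equilibrium estimators

* `equilibrium_length()`: a preassembled shell with one subunit made
  permeable to the polymer (its excluder-polymer term disabled, everything
  else intact) and a long chain threaded through that face; the packaged
  count is the number of bead centers inside the excluder shell's inscribed
  sphere plus half a bead diameter (the margin is exposed and its
  sensitivity reported, since the packaged-segment definition is a
  convention). Averages over at least three seeds after block convergence.
* `encapsidation_free_energy()`: trapezoidal integral of the difference
  between encapsidated and free chemical-potential curves with propagated
  standard errors; `curve_intersection()` locates the optimum from local
  linear fits with a parametric bootstrap CI.
* `dimer_binding()`: two subunits with a single attractive edge (the other
  attractors typed inert) in a periodic box; the dimer fraction gives
  Kd = 4 (1 - p)^2 / (p V N_A) in molar units and
  gcc = -kBT ln(css / Kd) at css = 1 M. A configuration is a dimer when
  any active attractor pair is within the Morse half-depth distance
  (1.49 nm for the standard parameters) — the model states no contact
  cutoff, so the half-depth crossing is this package's declared choice.
  The edge-multiplicity correction ln(25/2) is reported alongside.

# Calibrated constants

Two bonded constants are not fixed by the pair potentials and were
calibrated once, against stated physical targets, then frozen as defaults:

* `kangle_ss` = 0: single-stranded regions and ARMs are fully flexible
  bead-spring chains; their apparent stiffness comes from electrostatics
  and excluded volume. With this choice the unconfined 1000-bead linear
  polyelectrolyte at lambda_D = 1 nm equilibrates to RG ~ 25.5 nm, the
  model's reference coil size, with an apparent persistence length of a
  few nm — the flexible end of the stiffness scan.
* `kangle_ds` = 34 kBT/rad^2, calibrated so that an isolated 100-bp duplex
  (two bonded strands, base-pair rest length 1 nm) has a fitted
  persistence length of 49 +- 3 nm from the exponential decay of its
  bond-vector autocorrelation over separations up to 20 nm, matching the
  ~50 nm dsDNA target. The duplex bends anisotropically (softer out of the
  ladder plane), so the fitted value depends mildly on the fit range; the
  end-to-end statistics of the calibrated duplex match a ~50 nm worm-like
  chain as an independent check.

Other numerical conventions: `kbond` = 200 kBT/nm^2 (bond fluctuations
~0.07 nm, well under a bead diameter); base-pair bonds share `kbond` with
rest length 1 nm (about the helix diameter at this resolution); repulsive
LJ forces are linearly capped below 0.2 sigma (a region ~1e8 kBT uphill,
unreachable in equilibrium, but protective during initialization); the
angle force's fold-back singularity at theta = 0 is magnitude-capped
(such states cost ~k pi^2/2 and never occur in sampling).

# Problem sizes and what the tests show

The shipped test suite and acceptance script run desk-scale versions of
every operation: full geometric and potential-level validation; structure
generation and MLD analysis at LC = 1000; solution RG of the linear
1000-mer (three seeds, ~6e4 MC moves each) and of six MLD-selected
base-paired structures (~8e5 moves each); diffusion, bond-distribution,
replica-exchange and Widom checks on few-bead systems; and toy
semipermeable and dimerization runs. Production-scale protocols — 2e8-step
assembly yield curves, Leq* for every preset, the full Widom curves to
Np ~ 650, the epsilon scan of the dimer free energy — are shipped as
annotated YAML configurations under `inst/configs/` with their expected
values and tolerances, and are meant for cluster time, not test time.

# Known limitations

* Debye-Hueckel screening only; no explicit ions, no divalent-cation
  binding, no counterion-condensation correction (the model argues these
  matter little at >= 100 mM monovalent salt and low interior packing).
* Static base pairing; no folding thermodynamics, no pseudoknots.
* Isotropic rigid-body mobility and free-draining beads: kinetics are
  meaningful in reduced time units only.
* T=3 capsids are thermodynamic stand-ins (scaled 12-pentamer shells), not
  icosahedrally exact reconstructions.
* The packaged-segment, dimer-contact and encapsulation criteria are
  declared conventions; each is exposed as a parameter and the margin
  sensitivity is reported where it matters.
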