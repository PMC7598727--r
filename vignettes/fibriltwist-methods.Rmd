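---
title: "Cluster detection, shape descriptors and the helicity order parameter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster detection, shape descriptors and the helicity order parameter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibriltwist)
library(dplyr)
```

`fibriltwist` analyzes coarse-grained peptide aggregation trajectories:
it detects aggregates under periodic boundary conditions, computes shape
and order descriptors, quantifies fibril twist through a ribbon-based
helicity order parameter, and reduces kinetic curves to scaled master
coordinates and power-law growth fits. This vignette explains the models
and procedures, the tunable constants with their defaults and units, the
numerical choices, and what the synthetic generators do and do not
emulate.

## Data model

Everything is a tidy tibble: one row per bead with `frame`, `time`
(multiples of the model's intrinsic time unit tau), `peptide`,
`residue`, `role` (backbone `N`, `CA`, `C` or side-chain `SC`), `x`,
`y`, `z` and the periodic box edges `box_x`, `box_y`, `box_z`. The
internal length unit is nm everywhere; Angstroms appear only at the PDB
I/O boundary (divided by 10 on input). One internal unit avoids silent
factor-of-ten bugs, since conventions in this field mix both units.

Each coarse-grained residue carries three backbone beads plus one
side-chain bead, except glycine, which has none; all beads have equal
mass. The seven-residue GNNQQNY fragment therefore has 27 beads
(21 backbone + 6 side chains). The topology travels as an explicit
YAML config (sequence, peptide count, designated side-chain residue)
rather than being inferred from atom names, because coarse-grained
bead naming is not standardized across writers.

## Cluster detection under periodic boundaries

Two peptides are linked when **any** bead of one lies within the cutoff
(default 0.5 nm, minimum-image distance) of **any** bead of the other;
aggregates are the connected components of this link graph (single
linkage), and components of size one are free monomers. The criterion is
deliberately bead-center to bead-center, not mass-center based. Because
minimum-image distances are used throughout, it does not matter whether
coordinates arrive wrapped or unwrapped — applying arbitrary
per-peptide integer box shifts changes nothing, and the test suite
asserts this property directly.

Implementation note: candidate peptide pairs are pre-filtered with an
exact bounding-radius test on peptide centroids (a pair can only link if
the centroid distance is below the cutoff plus both bounding radii)
before the all-bead check. This replaces a cell list; at the system
sizes this package targets (tens of peptides) it is simpler and equally
exact, and the brute-force all-pairs computation is retained in the test
suite as an independent oracle.

A cluster crossing a box face is stored split. `unwrap_cluster()`
reassembles it by breadth-first traversal of the link graph, shifting
each newly reached peptide by the integer box vector that realizes the
minimum-image position of its closest linking bead pair. Descriptors are
computed only on unwrapped clusters; the invariance
`descriptor(unwrap(split(X))) == descriptor(X)` is enforced to 1e-10 in
the tests over hundreds of seeded random clusters.

The cutoff must be below half the smallest box edge, otherwise the
minimum image is not unique and an error is raised rather than a guess
made.

## Shape and order descriptors

* **Gyration shape.** The gyration tensor about the centroid gives
  eigenvalues sorted as lx² <= ly² <= lz² (nm²), the radius of gyration
  Rg² = lx²+ly²+lz², and the asphericity b = lz² - (lx²+ly²)/2. The
  literal formula has units of nm², but reported mean asphericities of
  order 0.02 are only consistent with a normalized quantity, so both are
  computed: `b_raw` (nm², the literal formula) and `b_norm` (divided by
  the trace, dimensionless in [0,1]); `b_norm` is the default reported
  column. `b_norm` is 0 for an isotropic eigenvalue spectrum and exactly
  1 in the rod limit.
* **End-to-end correlation.** Cn averages the squared dot products of
  the unit backbone end-to-end vectors over all peptide pairs of a
  cluster; squaring makes parallel and antiparallel equivalent. It is
  exactly 1 for (anti)parallel alignment and tends to 1/3 for isotropic
  orientations. The end-to-end vector runs from the backbone N bead of
  residue 1 to the backbone C bead of the last residue — the plainest
  reading of "backbone" endpoints for a three-bead backbone.
* **Beta-content.** Phi/psi torsions are computed from the three-bead
  backbone with the standard four-point dihedral (IUPAC sign, verified
  against an independent torsion implementation). A residue counts as
  beta when phi is in [-180, -45] degrees and psi in [45, 180] or
  [-180, -120] — a standard broad Ramachandran beta region, configurable
  because no sharper definition is canonical for coarse-grained
  backbones. Only interior residues enter (terminal residues lack one
  dihedral), so the per-peptide count is bounded by residues - 2; the
  value reported is beta residues per peptide of the cluster.
* **Mass-center distance histogram.** All M(M-1)/2 pairwise distances
  between peptide mass centers, binned at 0.02 nm by default (ten bins
  below the ~0.2 nm nearest-neighbor shell) and normalized to sum 1.
  `classify_order()` scores how much of the probability mass beyond the
  first-neighbor peak sits in local maxima and their immediate
  neighbors: ordered (fibril-like) clusters concentrate their mass in
  discrete shells, amorphous ones spread it into a featureless hump.
  Flat stretches are deliberately not counted as maxima so a uniform
  tail scores near zero. The default decision threshold of 0.5 splits
  the two constructed extremes roughly symmetrically; it is a reporting
  aid, not a calibrated classifier.

## The helicity order parameter

Large fibrillar clusters are built of ribbons — runs of peptides stacked
along the fibril axis — twisted about a common core. The cluster
helicity H quantifies that twist:

1. **Axis.** The cluster axis is the first principal direction of a
   representative point per peptide (orthogonal regression). Coordinate
   wise linear regression would depend on an arbitrary independent axis,
   which is why total least squares is used. By default the points are
   the side-chain centers of the designated residue (the tyrosine core
   of GNNQQNY-like fibrils), which is markedly more stable than
   whole-peptide centers when the core is compact. If the top two
   principal values are within 1% the axis is flagged ill-defined. The
   direction's sign is fixed by the input ordering (axis points from the
   first-listed peptide's projection toward the last), making reported
   signs reproducible run to run; the sign of H itself is intrinsic
   (see below).
2. **Ribbons.** Peptide mass centers are projected on the axis and
   sorted; a consecutive sorted pair belongs to the same ribbon when its
   axial gap and its perpendicular offset are both within size-dependent
   cutoffs. The reference spacing is dm2(M) = a/M + b with defaults
   a = 9.6192 nm, b = -0.0009 nm (fitted for a 72-peptide system; they
   are configuration, not constants of nature), scaled by s_par = 0.88
   and s_perp = 0.47. Because the fitted constants are system-specific,
   `second_maximum()` of the distance histogram can supply an empirical
   spacing instead. Note s_par² + s_perp² = 0.9953, not exactly 1; the
   printed factors are used verbatim.
3. **Twist.** For consecutive ribbon peptides i, i+1, the twist is
   h = g_i . e_{i+1}, with g_i the unit radial vector of peptide i
   (center minus its axis projection) and e_{i+1} the unit tangential
   vector of peptide i+1, e = (r x A)/|r x A|. The tangential vector is
   built from the *radial* vector, not the absolute position: a cross
   product with the absolute position would make h depend on the
   coordinate origin, which is physically untenable. h is 0 for an
   untwisted stack and its sign encodes handedness.
4. **Averaging.** A ribbon's helicity is the mean pair twist; the
   cluster helicity H is the mean over ribbons with at least two
   peptides. Singleton ribbons are a 0/0 contribution and are excluded.
   Pairs with undefined twist (radial vector vanishing or parallel to
   the axis) are skipped and counted on the result.

For an ideal fibril whose azimuth advances by -dphi per rise step,
H = -sin(dphi) exactly, independent of rise, radius and ribbon count —
the package's central oracle, satisfied to 1e-6 by the noise-free
generator. Holding the ribbon decomposition fixed, flipping the axis
direction flips every h (the documented antisymmetry of the twist
formula). Run through the full pipeline, however, flipping the axis also
reverses the sort order and the two flips cancel: H is a genuinely
intrinsic, chirality-sensing quantity — proper rotations and
translations leave it unchanged to 1e-10 and mirror-imaging flips its
sign, both asserted in the tests.

**Known limitation.** The sorted-consecutive chaining cannot recover
ribbons that interleave along the axis (staggered multi-ribbon fibrils):
every consecutive sorted pair then crosses ribbons and the decomposition
fragments. This is a property of the published assignment rule, not of
this implementation; the pipeline therefore accepts an externally
supplied ribbon membership (the synthetic generator provides its ground
truth), and automatic assignment is exercised on geometries where the
rule is well-posed (stacks, single-ribbon helices).

## Kinetic reductions and scaling fits

`kinetic_counts()` tabulates per frame the monomer count Nm, cluster
count Nc, and largest-cluster size M. The half-time t1/2 is the first
crossing of Nm = N0/2, linearly interpolated between frames (no rule is
canonical; first-crossing interpolation is the least-surprising choice).
The cluster-peak time tmax is the maximum of Nc after centered
moving-average smoothing (default window 5 frames, since the raw peak is
noisy when aggregation is fast); ties resolve to the earliest frame.
Scaling Nm/N0 against t/t1/2 and Nc/N0 against t/tmax collapses curves
from different system sizes and concentrations when the aggregation
mechanism is unchanged; `collapse_gap()` quantifies collapse as the
maximum vertical gap on a common logarithmic time grid.

Cluster compactness follows two regimes: below the critical size
(default M* = 25) the mean radius of gyration grows as Rg ~ M^alpha
(alpha = 1/3 would be constant-density 3D growth), and above it as
Rg - Rg* ~ (M - M*)^beta with Rg* = 1.332 nm (13.32 Angstroms), the
pseudo-one-dimensional elongation of fibrils (beta = 1 for end growth).
Both fits are unweighted least squares in log-log space, matching the
usual practice of fitting a line on a double-logarithmic plot; both
recover exact exponents to machine precision and are unbiased under 5%
multiplicative log-normal noise (asserted over 50 seeded replicates).
M* and Rg* are configuration: this package analyzes trajectories, it
does not re-derive the critical size, which requires the underlying
molecular dynamics data.

Box/concentration utilities convert between peptide count, cubic box
edge and molar concentration (20 peptides in a 13.05 nm box are
14.94 mM), and `equilibrium_concentration()` converts the tail-mean
monomer count — from the first frame at which the largest cluster
attains its final size — into the equilibrium monomer concentration.
The intrinsic time unit tau is treated as an opaque user-supplied
constant for time conversions: its derivation from the model's
mass/length/energy units is ambiguous, so no value is hard-coded.

## Synthetic generators and what they (do not) show

The generators produce structures with analytically known descriptor
values, standing in for molecular dynamics output in every test:

* `build_helical_fibril()`: rigid peptide copies with mass centers on
  n_ribbons helices about z (azimuth advancing by -dphi per rise step;
  positive twist builds a left-handed fibril so H = -sin(dphi) is
  negative, the sign convention of amyloid-like twists). Side-chain ends
  point inward, forming the core that the axis fit uses. With two or
  more ribbons the azimuthal sums cancel exactly and the fitted axis is
  the z axis to machine precision; the 1e-6 helicity oracle uses three
  ribbons for this reason. Defaults (rise 0.5 nm, radius 1.2 nm, twist
  8 degrees, 3 ribbons) give inter-peptide spacings around 0.45-0.5 nm,
  the contact scale of the clustering criterion.
* `build_parallel_sheet()`: identical extended copies stacked at a given
  spacing, parallel or antiparallel; Cn = 1 for both by construction.
* `build_amorphous_cluster()`: centers uniform in a ball with
  minimum-separation rejection sampling and uniformly random
  orientations — isotropic in expectation (normalized asphericity near
  0, Cn near 1/3).
* `build_monomer_gas()`: the initial condition of an aggregation run.
* `split_across_boundary()`: wraps a translated frame back into the box,
  deliberately splitting clusters across faces for round-trip tests.
* `simulate_coalescence()`: exact Gillespie simulation of well-mixed
  binary coalescence (constant and sum kernels by default, both with
  closed-form references; the constant-kernel entity count is a pure
  death chain whose master equation the tests solve independently) plus
  optional monomer detachment. It reproduces the qualitative stages of
  aggregation — rapid dimerization, a rising-then-falling cluster
  count, coalescence into one aggregate — and feeds the kinetic
  reductions.

The peptide template is an idealized rigid chain built from internal
coordinates (0.13 nm backbone bonds, 111 degree angles, requested
phi/psi); only relative geometry matters for every descriptor, so no
claim is made that it matches any force field's equilibrium geometry.

Passing tests on these fixtures demonstrate that the implementations
compute their defining formulas correctly and respect the stated
invariances. They do not demonstrate anything about real aggregation
kinetics or thermodynamics: the generators contain no forces, no
Boltzmann statistics and no solvent, and headline empirical quantities
(critical sizes, steady-state helicities, equilibrium concentrations)
require the underlying simulations, which are out of scope here.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite: clusters of 4-10 peptides for the
  boundary round trips (200 seeded cases), 72-monomer coalescence runs
  with 200 replicates, 50-seed fit-recovery simulations. These sizes
  make every statistical assertion decisive (3.5 standard errors or
  better) while the full suite stays quick to run.
* Degenerate geometry errors: identical points (no shape), zero-length
  end-to-end vectors (named peptide), radial vectors parallel to the
  axis (skipped, counted), all-singleton ribbon decompositions
  (undefined helicity), cutoff at or above half the box edge
  (ambiguous minimum image). Errors state what is wrong and where;
  nothing silently returns NA except explicitly documented per-frame
  NAs in trajectory sweeps.
* Tie-breaks are deterministic everywhere: cluster ids order by size
  then smallest member, largest-cluster tracking prefers membership
  overlap then the smallest member index, the cluster-peak time takes
  the earliest tie, and the axis orientation follows the input order.
* Seeded generation is bit-reproducible; the command-line layer writes
  byte-identical outputs for identical inputs, configuration and seed,
  and echoes the effective configuration into every output header.
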