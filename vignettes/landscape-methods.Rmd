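---
title: "Energy-landscape methods for knotted coarse-grained chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape methods for knotted coarse-grained chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(knotpath)
```

# The model

`knotpath` explores the potential energy surface of a coarse-grained,
native-centric protein model in which each residue carries three sites:
the alpha-carbon (CA), the beta-carbon (CB, absent for glycine) and the
carbonyl oxygen (O).  The potential is

\[ V = V_\mathrm{backbone} + V_\mathrm{interaction}. \]

**Interaction term (Gō form).**  Every CA–CA and CB–CB pair with sequence
separation \(|i-j| > 3\) contributes a Gaussian well centred on its
distance in the reference (native) structure,

\[ V_\mathrm{int} = -\lambda \sum_{|i-j|>3} \gamma_{|i-j|}\,
   \exp\!\left(-\frac{(r_{ij}-r^{N}_{ij})^2}{2\sigma_{ij}^2}\right),
   \qquad \sigma_{ij} = |i-j|^{0.15}\,\text{\AA}. \]

The well weights \(\gamma\) take one of three values by sequence-separation
class (\(|i-j| \in [4,8]\), \([9,12]\), \(\ge 13\); defaults 0.177, 0.048,
0.430), chosen to split the native interaction energy roughly equally
between the classes.  The scaling \(\lambda\) is fixed by the calibration
condition that the native state has interaction energy exactly
\(-N\varepsilon\), which defines the energy unit \(\varepsilon\) (1
kcal/mol by default); see `calibrate_epsilon()`.  Because every well peaks
at the native geometry, no conformation can have a lower interaction
energy than the calibrated native value — the landscape is minimally
frustrated by construction.

**Backbone term.**  Peptide-like stereochemistry is maintained by smooth
terms only (the model is C¹ everywhere, which is what makes tightly
converged stationary points and normal-mode analysis possible):

* harmonic bonds on CA–CA (3.80 Å), CA–CB (1.53 Å) and CA–O pairs, with
  the CA–O equilibrium (≈ 2.40 Å) derived from ideal trans-peptide
  geometry so that ideally built conformations sit exactly at the bond
  minimum;
* a Ramachandran-like term: two Gaussian wells (helical and extended) in
  each virtual CA dihedral;
* trans-peptide planarity: a harmonic in the O(i)–CA(i+1) distance plus a
  harmonic dihedral that pins each carbonyl O into its local peptide
  plane.  The dihedral part (and a terminal O–CA(N−1) distance) is a
  deliberate extension of the classic three-term planarity description:
  without it each O could rotate freely about its CA–CA axis, giving ~N
  spurious zero modes in every Hessian;
* chirality: a harmonic penalty on the normalised scalar triple product
  of (CA(i−1)−CA(i), CA(i+1)−CA(i), CB(i)−CA(i)).  This uses only stored
  sites (no reconstruction of the absent amide nitrogen) and flips sign
  under mirror inversion, which is the property the term exists to
  penalise;
* excluded volume: \(\tfrac12 h\,[1-\tanh(s\,(r - r_\mathrm{ex}))]\) over
  CA–CA pairs, a smooth step rather than a hard sphere.

All constants are configurable (`default_params()`, YAML round-trip via
`write_params()`).  Two default choices deserve comment.  The torsional
stiffness (Ramachandran depth 2 ε, width 0.7 rad; chirality constant 20)
was chosen at the stiffer end of the plausible range: with weak torsional
terms the regions between native wells become anharmonically flat, the
Hessian spectrum at barrier regions collapses toward zero, and
stationary-point location becomes ill-conditioned.  The stiffer defaults
keep the landscape funnel-like while restoring usable curvature scales.

**Units.**  Energies are in ε, lengths in Å, masses in amu (12 per site).
The reduced temperature is \(k_BT/\varepsilon\) (≈ 0.59 at 298 K for ε =
1 kcal/mol, `reduced_temperature()`); the reduced frequency unit is
\(\sqrt{\varepsilon/(m\,\text{\AA}^2)} \approx 5.9\times10^{12}\,
\mathrm{s}^{-1}\), applied only when rates are reported in 1/s
(`rate_to_per_second()`).

# Stationary points

Minimisation uses L-BFGS (`stats::optim`) on the analytic gradient.
Transition states are located by a doubly-nudged elastic band (DNEB)
between two minima followed by refinement of the interior energy maxima:
a climbing image tracks the highest image during the final third of the
band iterations, and each candidate is then polished by an
eigenvector-tracking walker (uphill along the lowest non-zero Hessian
eigenmode, FIRE relaxation in its orthogonal complement, Newton polish
near the stationary point).  Saddles are accepted only when full
diagonalisation of the Hessian, after projecting out the six rigid-body
modes, shows exactly one negative eigenvalue.

Two numerical tolerances matter:

* minima are converged to RMS gradient 1e-6 ε/Å, tight enough for the
  identity test used for deduplication (energies within 1e-8 ε, aligned
  RMSD below 1e-4 Å);
* saddle points use a working tolerance of 1e-2 ε/Å.  The ridge regions
  of this potential contain directions whose curvature is of order
  1e-3–1e-2 ε/Å² and strongly anharmonic; along them the stationary point
  is displaced by ångströms while the energy changes by less than the
  residual-gradient bound (|g|·δ ≲ 0.01 ε).  Driving the gradient further
  down does not change any barrier or rate at the precision the harmonic
  rate model supports, so the package treats the index test (which is
  sharp) as the defining criterion and the gradient as a working
  tolerance.  On well-conditioned systems — the analytic test surfaces in
  the unit tests — the same machinery converges to 1e-8 and better.

# Chain-crossing avoidance

Linear interpolation between two minima whose chains lie on opposite
sides of another strand produces bands that thread one chain through the
other.  The avoidance scheme follows three stages over the band
iterations:

1. conserved-distance restraints are built from the aligned endpoints
   (site pairs within 10 Å in both structures whose separations agree
   within a tolerance), giving an elastic-network surrogate potential;
   crossings are diagnosed on the initial interpolation from pairs of
   atom-disjoint restraints whose midpoint-joining vectors reverse
   between images (midpoints within 10 Å in both images, with at least
   3 Å of midpoint-separation motion relative to the nearest endpoint);
   the outer (faster-moving) restraint targets are shrunk and the inner
   expanded, and a truncated inverse-distance repulsion is added between
   the four atoms of each crossing pair;
2. the restraint targets are relaxed linearly back to their endpoint
   values;
3. the full model potential takes over.

Two implementation choices sharpen the published recipe.  First, the
diagnosis is restricted to backbone-segment restraints (CA–CA pairs at
most two residues apart): their midpoints lie on the chain, so a side
swap tracks actual threading, whereas midpoints of long-range contact
pairs float in empty space and reverse during perfectly benign
rearrangements.  Second, the audit of a refined band
(`audit_band_crossings()`) does not reuse the midpoint heuristic but
checks the geometric ground truth: between adjacent images, the signed
volume spanned by every pair of non-adjacent backbone segments is swept;
a sign change at an instant where the segments also intersect is an
actual pass-through.  On the two-strand crossing fixtures, guarded bands
audit clean while plain DNEB (guard disabled: every iteration on the
model potential from the straight interpolation) retains at least one
pass-through in the majority of seeds.

The two-strand crossing fixture itself went through several design
iterations worth recording.  The static barrier is L-shaped, because the
optimal rigid-body alignment of the two endpoints will otherwise simply
rotate the "crossing" away (a straight barrier lies on the rotation
axis); all strands zig-zag at a 135° virtual angle so that no four CAs
are collinear (collinear quadruples make the dihedral terms singular);
the moving strand crosses one step away from the barrier's free end, so
that the physically correct detour exists at a length the band can
resolve; and both endpoints are energy-minimised before banding.  A
crossing in the middle of a long barrier defeats both the guarded and
the unguarded method at this scale — the detour around the barrier end
is then many ångströms longer than the through path and the band simply
cannot discover it; this mirrors the published observation that naive
parameter changes cannot fix crossing, and bounds what the desk-scale
fixture can demonstrate.

# Kinetics

Each transition state contributes harmonic TST rates
\(k = \exp(\sum\log\nu_\mathrm{min} - \sum\log\nu_\mathrm{ts})\,
  e^{-\Delta E/T}\) in reduced frequency units; detailed balance with the
harmonic occupation probabilities is exact by construction and verified
in the tests to 1e-10.  Mean first-passage times are computed by graph
transformation — iterative elimination of intermediate minima with
renormalisation of branching probabilities and waiting times — which is
exact and is validated against dense linear solves on random networks.
Free energies use the harmonic superposition form \(F = E + T\sum\log\nu\)
(constants common to all minima cancel); recursive regrouping merges
groups whenever a transition state lets them interconvert across a
barrier below the chosen threshold in both directions, iterating from the
lowest barriers to a fixed point.  The phenomenological two-state rate
weights each reactant-group minimum by its conditional equilibrium
occupancy: \(k = \sum_b w_b / \mathrm{MFPT}_b\).  The discrete path with
the largest contribution to this rate maximises the product of branching
probabilities (shortest path under \(-\log P\) weights, ties broken by
fewer steps then lowest id).

Disconnectivity graphs are built by a union-find sweep over transition
states on an energy-threshold ladder; every leaf terminates at its
minimum's energy and merge energies are non-decreasing toward the root.

# The scaled-down study driver

`run_dps()` wires the pieces into a deterministic, checkpointed pipeline:
basin-hopping from the native structure for the global minimum, a second
high-temperature run whose lowest-overlap (Q) visited minimum serves as
the unfolded endpoint, missing-connection DNEB attempts (Dijkstra over
the minima graph with zero-weight edges for connected pairs, squared
aligned RMSD otherwise, failed gaps penalised and eventually reroute),
optional untrap/shortcut expansion, then regrouping, two-state rates,
the largest-contribution path with its energy profile against integrated
path length, and the disconnectivity tree.

Two bookkeeping choices matter on this landscape.  First, basin identity
in the growing database is family-level (energies within 0.05 ε and
aligned RMSD within 3 Å): the wide soft-mode valleys mean one physical
state re-minimises to slightly different geometries and energies, and a
strict identity rule floods the graph with near-twins; a guard ensures
the two descended sides of a genuine saddle are never merged into one
node.  Second, if the primary unfolded endpoint fails to connect within
the attempt budget, the driver falls back to the most unfolded minimum
(lowest Q, required Q < 0.9) inside the global minimum's connected
component, so the run still reports an unfolded-to-folded path across
the region the sampling actually connected — the run log records when
this fallback is taken.

The default problem sizes (9-residue chains, a dozen basin-hopping steps,
a ten-attempt connection budget, 15-image bands with 300 iterations) were
chosen so a complete study runs on a single CPU in minutes while still
producing a connected unfolded-to-folded path with a physically sensible
rate; they are configuration, not constants.  What such a run
demonstrates is the machinery — funnel-shaped landscapes, index-1
saddles, two-state kinetics.  What it cannot demonstrate is the
production-scale phenomenology of a deeply knotted 58-residue chain
(hundreds of thousands of stationary points, slow absolute folding
times): those require cluster-scale sampling and are explicitly out of
scope.  Likewise the synthetic fixtures emulate geometry (ideal helices,
parametric knots, crossing endpoints), not the statistics of real
protein conformations; passing tests establish correctness of the
algorithms, not realism of any particular protein's landscape.

# Knot classification

A conformation's CA trace is closed by extending both termini radially
away from the centroid to a sphere ten times the chain's extent and
joining them along a discretised great-circle arc (a minimally
interfering closure; small seeded tilts of the rays are retried if a ray
happens to graze the chain).  The closed curve is simplified by
triangle-elimination (a vertex is deleted when no other segment crosses
the triangle of its neighbours — segments sharing a vertex with the
triangle cannot cross it transversally), projected along a random
direction, and the Alexander determinant \(|\Delta(-1)|\) is computed
from the crossing diagram via the standard crossing-matrix minor.  At
\(t=-1\) the matrix entries do not depend on crossing handedness, so no
over/under sign bookkeeping beyond the underpass/overpass distinction is
needed.  The determinant is 1 for the unknot, 3 for the trefoil and 5
for the figure-eight knot, and is invariant under projection direction,
rigid motion and chain reduction (tested over many random projections).
Landscape basins are labelled `native_knotted` when the trefoil is
present, and otherwise by the highest structural overlap Q against
supplied representatives of the N-free, C-free and unfolded ensembles —
an operational rule standing in for by-eye classification.

# Known limitations

* Barrier regions of the default potential contain near-flat,
  anharmonic directions; saddle locations along them carry ångström-scale
  uncertainty (their energies do not).
* The crossing guard is demonstrated on crossings near a barrier's free
  end; deep mid-barrier crossings are beyond what a 15–23 image band can
  circumnavigate at this scale.
* Harmonic densities of states everywhere; no anharmonic or
  quantum corrections, and rates in 1/s inherit the order-of-magnitude
  character of the frequency-unit conversion.
* Single chains only; no solvent; sequence enters only through glycine's
  missing CB.
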