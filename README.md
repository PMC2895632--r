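# knotpath

Energy landscapes, folding pathways and kinetics of knotted
coarse-grained protein chains, in R.

Proteins with knotted backbones fold orders of magnitude more slowly
than unknotted chains of the same size: the chain must thread a terminus
through a loop, and the large barriers this creates are invisible to
methods that only simulate downhill dynamics. `knotpath` implements the
geometry-optimisation route to this problem for a coarse-grained,
native-centric (Gō-type) model with three sites per residue (Cα, Cβ, O):

* a smooth potential `V = V_backbone + V_interaction`, where the
  interaction term is a sum of Gaussian wells centred on the native pair
  distances, `V_int = −λ Σ_{|i−j|>3} γ_{|i−j|} exp(−(r_ij − r_ij^N)² /
  2σ_ij²)` with `σ_ij = |i−j|^0.15 Å`, calibrated so the native state
  has energy `−Nε` (this defines the energy unit ε);
* basin-hopping global optimisation, L-BFGS minimisation and
  transition-state location by doubly-nudged elastic bands (DNEB) with
  climbing-image and eigenvector-following refinement — every saddle is
  validated to have exactly one negative Hessian eigenvalue;
* a chain-crossing avoidance scheme for band interpolations whose
  endpoints lie on opposite sides of another strand: conserved-distance
  restraints diagnose the crossing, the outer chain's restraints shrink
  while the inner chain's expand, and a repulsive guard steers the band
  around rather than through;
* kinetic transition networks with harmonic transition-state-theory
  rates, exact graph-transformation mean first-passage times, recursive
  free-energy regrouping, phenomenological two-state rate coefficients,
  largest-contribution discrete paths and disconnectivity graphs;
* knot classification of any backbone trace through the Alexander
  polynomial determinant `|Δ(−1)|` (1 = unknot, 3 = trefoil, 5 =
  figure-eight), with KMT-style chain reduction and outward-ray closure.

It is aimed at people studying folding kinetics of topologically
non-trivial chains with discrete path sampling at desk scale, and at
anyone who needs the individual pieces (the potential, the band methods,
the network kinetics, the knot detector) as reusable components.

## A worked example

```r
library(knotpath)

# a 9-residue helical chain as the native structure
native <- make_fixture("helix", n = 9)
ref    <- reference_structure(native)
params <- calibrated_params(ref)
pot    <- amh_potential(ref, params)

# native interaction energy is -N epsilon by calibration
interaction_energy(native, ref, params)
#> [1] -9

# reduced temperature of 298 K at epsilon = 1 kcal/mol
reduced_temperature(298)
#> [1] 0.5921856

# knot states of two fixtures
classify_knot(make_fixture("trefoil_chain", n = 60))
#> Knot report: trefoil (|Delta(-1)| = 3, reduced loop length 6)
classify_knot(native)
#> Knot report: unknot (|Delta(-1)| = 1, reduced loop length 3)
```

A complete scaled-down discrete-path-sampling study — basin-hopping
endpoints, DNEB/eigenvector-following connection, regrouping, rates,
path profile and disconnectivity tree — runs in minutes:

```r
res <- run_dps(native, dps_default_config(seed = 1), out_dir = "dpsrun")
print(res)
```

The printed summary reports the database size, whether the
unfolded-to-folded endpoints were connected, the exact mean
first-passage time, and the two-state rate coefficient in reduced
frequency units (multiply by `rate_to_per_second()`'s factor,
`sqrt(ε/(m Å²)) ≈ 5.9e12 s⁻¹`, for 1/s).  The run directory contains
the plain-text stationary-point database (`min.data`, `ts.data`,
`points.min`, `points.ts`), the energy-versus-path-length profile
(`profile.tsv`) and a resumable checkpoint.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/knotpath fixtures --kind trefoil_chain --n 60 --seed 1 --out chain.pdb
Rscript inst/cli/knotpath knot --conf chain.pdb
Rscript inst/cli/knotpath run --native native.pdb --out rundir
```

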