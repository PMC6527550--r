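---
title: "Models and methods: product egress from a pocket-shaped active site"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: product egress from a pocket-shaped active site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Exo-acting glycoside hydrolases with deep pocket-shaped active sites face a
topological puzzle: the monosaccharide product sits at the bottom of a
pocket more than a dozen angstroms deep, and an incoming substrate binds
directly above it. If the product had to leave the way the substrate comes
in, every catalytic round would require full dissociation. The alternative
— a transient lateral conduit, opened by side-chain and backbone motions,
through which the product slips out while the substrate stays bound —
turns such an enzyme into a processive catalyst. This package implements,
at desk scale, the computational machinery with which that scenario can be
interrogated: elastic-network normal modes, a multi-objective genetic
search for sterically feasible exit paths, Metropolis Monte Carlo ligand
migration, Cremer–Pople ring-puckering analysis with a classical
well-tempered metadynamics engine, and the binding-affinity and
inhibition-kinetics fits that anchor the energetics.

Everything runs on synthetic systems generated by the package itself, so
all claims are testable without downloading structures. The generator
encodes the *qualitative* geometry the problem requires — a deep pocket
with a bottom binding well, a three-residue constriction ("toll-like
barrier") between that well and the exit channel, a polar way-station
("lateral cavity") between barrier and mouth, and a polar pair at the rim
(the solvent gate) — not the atomistic reality of any particular enzyme.

# The synthetic pocket and what it does and does not emulate

`make_toy_pocket()` builds a cylindrical pocket of pseudo-beads
(default radius 5 Å, product site to mouth 13 Å, matching the depth quoted
for the study system) with:

* a **−1 binding well**: three polar site beads near the pocket bottom
  whose strengths are calibrated *by construction* so the ligand's polar
  energy at the start pose equals minus the requested well depth
  (default 3 kcal/mol);
* a **toll-like barrier**: three side-chain arms (anchor–mid–tip beads,
  tip radius 1.2 Å from the axis, bead radius 1.9 Å) at the channel base.
  Each arm has one hinge torsion about a vertical axis through its anchor;
  `gate_opening` is the radial tip retraction available to a mobile gate;
* a **lateral cavity station**: inward-protruding polar beads on one side
  of the channel between barrier and mouth, calibrated to the requested
  cavity well depth (default 2.5 kcal/mol);
* a **solvent gate**: a polar bead pair at the mouth rim;
* a **plinth**: an outer collar and ground apron around the lower pocket.
  A real active-site wall is the interior of a globular protein, not a
  free-standing tube; without the plinth the softest normal modes are
  cantilever sways of the tube, which are not the motions of interest.

Three properties are certified at build time by exhaustive pose-grid
scans (orientations × lateral offsets × heights, C++ kernel): the −1
placement is clash-free; with gates at reference positions **every** pose
crossing the barrier slab clashes (the closed channel aperture is smaller
than the ligand, so no rigid exit exists); and with gates displaced by
`gate_opening` — or deleted — a clash-free corridor of 0.5 Å waypoints
runs from the well past the mouth. Construction fails if any certificate
fails, so downstream claims ("the rigid search finds no exit") rest on a
proved property of the system, not on a search having tried hard enough.

What the toy does **not** emulate: hydrogen-bond directionality, water,
electrostatics, sequence, real rotamer statistics, and the absolute
energetics of any enzyme. Passing tests therefore demonstrate that the
*algorithms* behave as specified on systems with the right qualitative
topology; they are not evidence about any particular protein.

# Interaction model

Receptor–ligand energies are a 12-6 Lennard-Jones sum plus a switched
polar well for flagged donor–acceptor pairs (full below 3.0 Å, cosine
switch to zero at 3.5 Å), with a 12 Å non-bonded cutoff. Pair σ comes
from the van der Waals radii (minimum at radius contact). Two numbers
matter:

* `epsilon` (default **0.02 kcal/mol**): with hundreds of bead pairs in
  range, a conventional per-pair well depth would integrate into tens of
  kcal/mol of unspecific attraction and make thermal product release
  impossible. At 0.02 the walls stay firmly sealed (the repulsive branch
  still costs many kcal at clash distances — verified by the frozen-gate
  control, which never releases the product in 20 × 40,000-step chains)
  while specificity comes from the calibrated polar wells.
* `overlap_factor` (default 0.7): a pair "clashes" below 70 % of the
  radii sum. It is a configuration parameter, not a fitted constant.

A clash is a property of distances only, so the certificates are
independent of `epsilon`.

# Elastic modes and the displacement convention

The anisotropic network model uses one node per residue; springs of
stiffness γ connect nodes within the cutoff; rigid modes are identified
by |λ| below 10⁻⁸ of the spectral range and excluded. Two deliberate
choices:

* **Side-chain clustering.** All non-backbone beads (the three gate arms)
  are pooled into a single cluster node. Sparse side-chain beads on
  near-collinear arms would otherwise produce spurious near-zero modes —
  a known failure mode of distance-spring networks — and clustered
  normal-mode setups are standard practice for exactly this reason. The
  cluster node sits on the channel axis; the wall ring in the gate plane
  is laid out so its springs to that node are horizontal (with a small
  second-harmonic ripple giving the flap a finite stiffness), which makes
  the collective vertical flap of the barrier assembly the softest
  non-rigid mode by two orders of magnitude.
* **Amplitude convention.** `displace_structure()` rescales a mode so the
  largest *backbone-node* displacement equals the requested amplitude in
  Å; 2.2 Å is the canonical value used in the two-stage analysis. Because
  the barrier flap is strongly localised on the (non-backbone) gate
  cluster, a 2.2 Å backbone displacement carries the gate arms far out of
  the channel — which is precisely the point: a modest backbone motion
  translates into a large side-chain gate opening. Both displacement
  signs are tried; a sign that squeezes the start site simply counts as
  "no exit for that sign".

# Exit-path search

`evolve_exit_paths()` is an NSGA-II over fixed-length waypoint chains
(default 9 poses; consecutive translations bounded by 2 Å so a discrete
path cannot step over the certified barrier slab, whose blocked width
exceeds the step bound). The two objectives are the summed clash count
(minimised) and the reach (maximised); selection is binary tournament on
non-domination rank and crowding distance, with one-point crossover over
waypoint index and Gaussian mutation at 0.3 per gene. Half the initial
population are coherent "rays" (straight probes in random directions with
a shared orientation), and two smoothing mutations (copy the predecessor
waypoint's step or orientation) encode the continuity of physical paths.
The search is deterministic in its seed and can stop early once a
clash-free candidate attains a target reach. `clash_vs_separation()` bins
all waypoints of the final non-dominated set into 0.5 Å separation bins
and reports the minimum clash per bin; on the rigid receptor the
barrier-slab bins never reach zero, after the 2.2 Å lowest-mode
displacement they do.

# Monte Carlo migration

`run_migration()` iterates a Metropolis kernel: random rigid-body
perturbation of the ligand (translation uniform in a 1 Å ball, rotation
up to 20°), a redraw of a bounded backbone "breathing" displacement along
one of the six lowest modes (amplitude uniform in ±0.5 Å, *absolute* from
the reference structure so the proposal stays symmetric and bounded), a
best-of-5 rotamer trial per mobile gate hinge scored on the ligand–gate
energy, and Metropolis acceptance on the total interaction energy at
`kT = 1.7` kcal/mol. A trajectory terminates when both the
centre-of-mass and the C4-hydroxyl-marker separations from their start
exceed 15 Å, or at 40,000 steps; the cap is a compute budget -- the emulated protocol terminates on distance.

`kT` deserves a note: it is a free effective-temperature parameter of the
kernel, not a physical temperature. At 1.7 the acceptance rate on the
default pocket is ≈ 0.4, about 90 % of seeds release the product within
the step budget when the gates are mobile, and the frozen-gate control
remains sealed (0 of 20). Smaller values under-sample the climb out of
the engineered wells without changing the qualitative contrast.

`energy_distance_profile()` bins accepted states by separation and flags
*dwell bins*: local minima of the mean energy, at least 0.25 kcal/mol
below their ±2-bin neighbourhood, with a visit count above the
neighbourhood median. With the cavity station set deeper than ≈ kT a
dwell bin appears between barrier and exit; with a flat channel none
does.

# Ring puckering and the metadynamics engine

`cremer_pople()` implements the standard construction (centroid
translation, mean plane from the two Fourier sums, out-of-plane
projections, amplitudes q2/q3). Conventions, stated once: the ring is
ordered O5, C1…C5; the mean-plane normal is oriented so **θ = 0 is the
4C1 chair** under this ordering; qx = Q sinθ cosφ, qy = Q sinθ sinφ,
qz = Q cosθ, with the chair/inverted-chair distinction carried by the
sign of qz. The 38 canonical conformers (2 chairs, 6 boats, 6 skew-boats,
12 envelopes, 12 half-chairs) are not hard-coded as angle tables:
`classify_conformer()` derives each vertex by building the ideal
geometric pattern (which atoms lie above/below the residual plane) and
running it through `cremer_pople()` itself, then classifies by
great-circle proximity on the (θ, φ) sphere. This makes the label set
self-consistent with the package's own conventions by construction, and
the generator→classification round trip over all 38 labels is part of
the test suite.

`run_wt_metadynamics()` is a classical engine: an overdamped Langevin
walker on an analytic 2-D potential with history-dependent bias.
Gaussians (height 1 kcal/mol initially, width 0.1 CV units, deposited
every 200 steps) decay with the well-tempered rule at bias factor γ = 10;
the free energy estimator is −γ/(γ−1) times the bias, **time-averaged
over the final half of the depositions** and **filtered at the Gaussian
width** — the estimator is only defined down to the resolution of the
hills, and both steps are standard variance-reduction practice. Validation
is entirely against independent oracles on analytic surfaces: pointwise
agreement in a harmonic well, basin free-energy differences against
direct Boltzmann quadrature, barriers against the exact minimax saddle of
the true surface. The quantum-chemical free-energy landscapes of real
sugars are explicitly out of scope; the engine's contract is the biasing
algorithm.

`fel_extrema()` reports grid-local minima and the inter-basin barrier as
the minimax saddle — the smallest energy threshold at which the two basin
cells become connected through cells at or below it, found by a sorted
flood fill. This is exactly "the maximum along the lowest-cost path", and
computing it by threshold connectivity is simpler to verify than a
node-cost shortest-path formulation.

# Affinity and kinetics

The competitive-inhibition model v = Vmax·S / (KM(1 + I/Ki) + S) is fitted
by Levenberg–Marquardt least squares with uniform weights (no weighting is
stated for the assays), alongside the Dixon construction (1/v against I
per substrate level; the lines intersect at I = −Ki, exactly so in the
noise-free limit — an identity the tests assert to 10⁻⁶). The SPR
steady-state model Req = Rmax·C/(KD + C) is fitted to geometric dilution
series spanning 0.1–10 × KD with one duplicated concentration. The
generators reproduce the published assay designs: six substrate
concentrations spanning 0.8–6.6 mM crossed with six inhibitor
concentrations spanning 0.4–3 × Ki in duplicate, multiplicative Gaussian
noise (rate and response errors scale with signal).

Free energies use ΔG = −RT ln(1/K) = RT ln K with K the dissociation
constant in molar, R = 8.314 J mol⁻¹ K⁻¹, reported in kJ/mol — negative
for sub-molar K, zero at the 1 M standard state. This sign convention is
the one consistent with the published values the package reproduces.
Temperatures are assigned per measurement: SPR rows at 298.15 K (25 °C),
inhibition rows at 303.15 K (30 °C); that assignment reproduces every
published ΔG to the printed precision.

# Problem sizes and numerical choices

The study-condition sizes used throughout the tests and the acceptance
script are: a ≈ 900-bead receptor; NSGA-II with population 60 for up to
250 generations (early stop at the exit distance); migration ensembles of
20 seeds × 40,000 steps; metadynamics runs of 250,000–300,000 steps
(1,250–1,500 hills) on 77 × 49 grids; and 100-replicate recovery studies
for the fits. Fits use analytic starting values and positivity bounds;
eigen-solves use the dense symmetric solver; numerical gradients in the
pose minimiser are central differences (10⁻⁴ Å, 10⁻³ deg) with
backtracking line search, so the energy never increases along the
descent. Degenerate inputs (planar rings for the mean-plane construction,
coincident nodes, empty fronts, non-finite proposal energies) raise
errors or auto-reject rather than propagate.

# Known limitations

The pocket is axially symmetric and its lateral cavity is a polar station
rather than a sterically hidden antechamber; the gate mode engineering
(cluster node + in-plane gate ring) is a deliberate construction that
makes the barrier flap the softest mode, mirroring — not deriving — the
domain-motion phenomenology of real systems. The Monte Carlo kernel has
no detailed-balance correction for the best-of-k gate trial (the trial is
a greedy side-chain relaxation, as in the energy-landscape exploration
tools it emulates), so the chain's stationary law is only approximately
Boltzmann when gates are mobile; the equilibrium checks in the test suite
therefore use fixed-gate systems. Absolute energies are model units:
only contrasts (rigid vs displaced, mobile vs frozen, well vs flat) are
claimed.
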