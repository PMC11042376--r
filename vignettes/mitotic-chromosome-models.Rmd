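---
title: "Models and methods: SMC rules of engagement and bottlebrush chromatids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: SMC rules of engagement and bottlebrush chromatids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

During mitotic entry, interphase chromatin — organized by loop-extruding
cohesin into CTCF-anchored loops (TADs and focal "dots") and partitioned
into A/B compartments — is refolded within minutes into rod-shaped
chromosomes built from dense arrays of condensin loops. Four SMC species
act on the same substrate at once: extrusive cohesin, cohesive cohesin
(which topologically tethers the sister chromatids), condensin II (nuclear,
active from prophase onset) and condensin I (cytoplasmic, gaining access at
nuclear envelope breakdown, NEB). What happens when these motors collide
determines the outcome: whether interphase structure is erased, whether
sisters individualize while staying cohesed, and what the mature chromatid
looks like.

`mitobrush` implements the computational machinery needed to study this
transition at desk scale: a 1D lattice engine for loop extrusion with
configurable *rules of engagement* between species; constructive 3D
builders for coarse-grained chromatid conformations; Hi-C-style contact
analysis of those conformations, centered on the contact-frequency curve
P(s); estimators of in-vivo extrusion speeds from loop-size and
spiral-period kinetics; and a grid-search fitter of the chromatid model's
free parameters against a target P(s). Everything runs on synthetic,
seeded inputs.

# The lattice engine and the rules of engagement

The genome is a 1D lattice (default 1 kb per site; the 3D builders use
10 kb beads, and the features of interest all live at or above 100 kb, so
1 kb resolution keeps 100 Mb runs cheap without losing anything the
analysis can see). An extruder occupies one site per leg; both legs of a
two-sided extruder translocate outward, each at half the complex's
extrusion speed, so an unobstructed loop grows at the configured speed —
the same convention the in-vivo speed estimators use. The engine time step
is 1 s, shortened automatically so no leg moves more than one site per
step; an explicit time step that would imply a per-step move probability
above 1 is rejected as a configuration error.

When a moving leg reaches an occupied site, a `collision_policy()` decides
among five outcomes: `bypass` (step over the obstacle), `stall`,
`unload_obstacle`, `push_obstacle` (contiguous chains of pushable
obstacles displace as a unit; pushing into a chromosome end converts to a
stall), and `unload_self`. The default policy encodes the rules inferred
for mitotic chromosome formation:

* condensins **bypass cohesive cohesins** — the rule that lets each sister
  individualize into its own bottlebrush while staying cohesed;
* condensins **remove extrusive cohesins** — the rule behind the rapid
  condensin-driven erasure of TADs, dots and compartments in prophase;
* condensins **stall at one another** — which makes their loops
  consecutive, not overlapping, and is why the loop array stops coarsening
  once the chromosome is saturated.

Where the biology is silent the defaults are explicit and configurable:
condensin I vs condensin II encounters stall (only condensin-condensin
stalling within one species is directly supported by the loop-size
plateau; treating the two condensins alike is the conservative choice and
is exposed as ordinary policy entries); a pushed cohesin loses its CTCF
anchoring (its anchoring is positional, so displacement removes it);
cohesive cohesin is not pushable by default because it tethers the sister
chromatid (configurable). Tie-breaks when two legs contest one site are
resolved by the seeded random order in which legs are processed each step;
the tiny-lattice tests marginalize over this order exactly and verify the
engine against full transition-matrix enumeration.

CTCF sites are barrier annotations rather than occupants: an extrusive
cohesin leg is blocked only when it tries to move past a site whose motif
orientation faces it ('+' sites block leftward legs), so convergent
'+'...'-' pairs trap cohesin loops — the standard phenomenology that makes
dots form only at convergent pairs. Condensins ignore CTCF. Two further
kinetic choices matter for the G2 fixture: a cohesin loop whose both legs
are anchored at matching CTCF sites is protected from stochastic unloading
while the barriers persist (without some stabilization, dots never
accumulate: at a 1 kb/s extrusion speed and ~150 kb processivity, almost
no cohesin lives long enough to reach both anchors of a 100-300 kb pair
and the steady-state dot occupancy is near zero); and in prophase runs
unloaded cohesin does not rebind, while CTCF sites decay by a slow
first-order background process — the condensin-independent pathway that
removes interphase features even without condensin.

# The G2 fixture and the prophase scenarios

`make_g2_fixture()` generates the substrate: CTCF sites with
exponentially distributed spacing (mean 250 kb) and random orientations,
an A/B label track with geometric domains, and an extrusive cohesin
species with density 12 complexes/Mb, speed 1 kb/s and processivity
150 kb. The density is the G2 level: quantitative chromatin proteomics
puts the prometaphase residual at ~3-6 cohesins/Mb after an approximately
3-fold prophase loss, so the G2 starting point is ~3x that. The
processivity sets the ~100 kb loop scale that produces the characteristic
shoulder in G2 P(s). Equilibrating the engine on this fixture
(`g2_equilibrate()`, 4000 s) yields CTCF-anchored loops, with most
convergent pairs carrying a stably double-anchored cohesin.

`run_prophase_scenario()` then loads condensins at t = 0 and applies one
of the four rules to condensin-cohesin encounters (`unload`, `push`,
`bypass`, `stall`). Dot persistence is scored on synthetic contact maps
built by `frame_to_contact_map()`: a power-law background plus focal
enrichment at loop anchor pairs. Because the map stands for a
cell-population average, only loops anchored at deterministic positional
cues (CTCF sites) are focal by default; anchors that vary from cell to
cell — condensin loops — average into the distance background. Under
`unload` and `push` the normalized dot strength collapses within minutes;
under `bypass` and `stall` it persists at the slow background rate, the
ordering the package's acceptance tests assert seed by seed.

# The chromatid models

The mature chromatid is modeled on four principles: a bead chain (10 kb
per bead; bead geometry follows from the chromatin volume density), folded
by condensins into an array of consecutive loops separated by small
spatial gaps, packed into a cylindrical body, and — for condensin
II-containing chromosomes — nudged into an irregular helix with a fixed
number of turns and ends pinned to the cylinder caps.

Three parameters are free: the average **loop size** (bp), the **gap**
between adjacent loop anchors along the scaffold (nm), and the **linear
density** of chromatin along the axis (Mb/um). Two are fixed from
experiment: the genomic length of one helical **turn** (from the position
of the second diagonal in Hi-C) and the **volume density** (from electron
microscopy; 44 Mb/um^3 for the fuzzy condensin II-only chromosomes, 77
Mb/um^3 otherwise). The presets are the two best-fit models:
`"condensin_II"` — 400 kb loops, 80 nm gaps, 17 Mb per turn at a 400 nm
pitch, helical cylinder; `"condensin_I"` — 100 kb loops, 20 nm gaps, no
helix, a weakly stretched random walk with a 4 um end-to-end distance per
100 Mb at periodic-boundary density.

Construction is direct rather than Brownian dynamics: loop interiors are
Gaussian bridges between anchor points, confined by reflection at the
cylinder wall, with loop bellies bowed outward so that the cross-section
fills to the measured volume density (the radial target of each belly is
drawn so bead density is approximately uniform over the disk); ensemble
averaging over seeds stands in for time averaging. This is the choice
that makes a 100 Mb chromatid buildable in milliseconds, at the price of
no explicit excluded volume — see Limitations.

The helical scaffold is deliberately *disordered*. Anchor positions
follow the ideal helix in phase (winding number = length / turn length)
but carry smooth AR(1) noise in phase (sd 0.3 rad), radius (15%), and —
most importantly — axial position (sd 0.75 x pitch, correlation length
8 Mb). The axial wander means gyres interdigitate instead of stacking as
flat rings: that is what lets loops two turns apart touch and produce the
third diagonal at twice the turn length, while the angular period keeps
the half-turn dip. The gap size enters as the scaffold's contour budget:
the smooth helix path consumes part of the inter-anchor spacing, surplus
becomes fine-scale scaffold roughness, and a gap too short for the smooth
path pulls the scaffold taut (shrinking the helix radius and axial
wander). In the periodic (condensin I) mode the backbone is a random walk
conditioned on the imposed end-to-end vector, with an effective step per
loop of `gap + 0.5 * bead_step * sqrt(beads_per_loop)` — the bottlebrush
excluded volume that spaces anchors beyond their bare gap.

Sister pairs follow the two competing hypotheses directly: in `stall`
mode the loop arrays are truncated at cohesive-link positions (condensins
cannot pass), links sit at loop bases, and both sisters share one axis;
in `bypass` mode each sister is an independent bottlebrush, axes ~1.1
radii apart, with the links (inside loops, distal from anchors) pinned at
the inter-sister interface. Cross-section line scans
(`cross_section_profile()`) then show the diagnostic difference: two
separated condensin axes with interfacial cohesin versus a single merged
axis.

# Contact analysis

Contacts are pairs of beads within a capture radius of twice the bead
diameter (~120 nm at 44 Mb/um^3), found with a cell-list search. P(s) is
the contact count over the number of locus pairs per log-spaced
separation bin (>= 8 bins per decade; 20 by default where sharp peak
localization matters), normalized to unit sum over bins — a convention
that cancels in every ratio and derivative the analysis uses. In the
periodic mode, contacts are computed on unwrapped coordinates: contacts
between box replicas model background (inter-chromatid) interactions,
which Hi-C analysis masks below the background floor, so they are
excluded from intra-chain statistics by construction.

The log-derivative d log10 P / d log10 s is estimated by Gaussian-weighted
local linear regression in log-log space (kernel sd of one bin), which is
exact for power laws including at the range ends. Three diagnostics are
built on it:

* **Loop size** (`estimate_loop_size()`): a dense loop array leaves a
  bump in the derivative near the loop size. The bump apex fluctuates
  between realizations, so the estimator locates the *knee* — where the
  derivative has climbed 70% of the rise from its preceding minimum to
  the apex — and maps it through `loop_kb = 0.83 * knee_kb^1.16`. The
  calibration was measured once on simulated consecutive-loop arrays of
  known loop size (100-800 kb, three seeds each; maximum deviation 15%)
  and frozen as package constants. On sparse, polydisperse interphase-like
  arrays (the G2 fixture at ~70% coverage) the knee sits further right of
  the loop scale and the estimate is order-of-magnitude rather than
  quantitative; the calibrated regime is the dense mitotic array.
* **Periodic diagonals** (`detect_periodic_diagonals()`): peaks of the
  residual after subtracting a local one-decade power-law trend. A band
  must clear a topographic prominence of 0.3 (2-fold above baseline) *on
  both flanks* — the two-sided rule is what keeps cliff edges at the end
  of data support, and broad curvature from the stretched-walk tail, from
  being called in condensin I-only curves, which genuinely have no
  periodic pattern. Peaks weaker than half the strongest peak are dropped
  (genuine band series have comparable prominences; detrending ripples
  near the loop shoulder do not), positions are refined by parabolic
  interpolation, and bins with fewer than 30 contacts are ignored.
* **Band slope** (`mean_ps_slope()`): the OLS slope of log10 P over a
  band, used for the random-walk (-1.5 over 2-8 Mb) and fractal-globule
  (-1) regimes. The finite, end-to-end-conditioned chain decays slightly
  shallower than the infinite-chain -1.5 (the bridge variance factor
  1 - s/L), which is visible as ensemble means near -1.45.

Compartment strength is distance-stratified: at every separation with
both same- and different-type pairs present, the ratio of mean
frequencies is taken (expected-at-distance cancels within a stratum) and
strata are averaged weighted by the rarer type's count — this makes a
checkerboard with within = 2 x between score exactly 2, and label
shuffles score 1. Dot strength is a pileup: observed/expected averaged
over a 3x3 center divided by a background ring (outer 3 bins of a +/- 10
bin window, stated explicitly because no standard window exists); dots
closer to the diagonal than the window are skipped and counted.

# Kinetics estimators

All estimators live in one unit-checked module (minutes at the interface,
seconds internally, speeds in kb/s): the endpoint estimate (loop size /
elapsed time), the increment estimate between two time points of one time
course (flagged as a lower bound when loops may have saturated inside the
interval), the gap-closure estimate (mean loop x multiple / time to rod
appearance; the multiple defaults to 4.5 with the plausible range 4-5
exposed, since closing most gaps requires each condensin to extrude
several loop lengths), the spiral growth rate from the second-diagonal
period series, and the isotropic area-to-volume conversion
(volume fold = area fold^(3/2), so a 2-fold area decrease is the
"approximately 3-fold" volume decrease after rounding 2.83). Because the
exact activation time after release from the G2 block is unknowable, the
endpoint estimator exposes a time-offset parameter rather than asserting
one.

The engine-level counterpart, `gap_closure_experiment()`, loads a fixed
cohort of condensins simultaneously and asks how much each must extrude
before the loop array covers the chromosome. For random loading the
per-condensin extrusion capacity at coverage c is close to
`log(1/(1-c))` mean loop lengths: "most gaps closed" — the rod-shape
criterion — corresponds to ~98% coverage and hence the 4-5x multiple
(note that at 90% coverage the same theory gives only 2.3x; the package
measures at 0.98 by default, with the target exposed). Reported ratios
average ~3.9 over seeds, with single-seed spread of roughly 3-6 because
the time to close the *last* gaps is an extreme-value statistic of the
largest loading gap.

# Model fitting

`fit_grid()` reproduces the model-selection procedure: an exhaustive grid
over the three free parameters (default grids: loops 100-800 kb, gaps
10-160 nm, linear density 10-80 Mb/um, all in 2-fold steps), each point
evaluated by simulating an ensemble, pooling its P(s), and scoring the
root-mean-square of log10(model/target) over 30 kb to 0.6 x the chromosome
length. Bins below the background floor or with fewer than 10 contacts on
either side are masked — the synthetic analogue of masking below the
experimental inter-chromosomal background, and necessary because the
inter-gyre dips of helical models carry pure counting noise. The
goodness-of-fit is a premetric (zero for identical curves, symmetric);
the surface is returned whole, near-tied surfaces are flagged as
degenerate, and failed grid points (e.g. loops too large for the cylinder
geometry) are recorded and skipped. Self-recovery on self-generated
targets is within one grid step per parameter in both modes; the gap
size, whose P(s) signature is intrinsically the subtlest of the three at
10 kb bead resolution, is the parameter that most often lands on the
adjacent step.

`combine_nested_model()` builds the two-condensin chromosome: condensin
II defines the outer array and helical scaffold, condensin I subdivides
each outer loop into size-ratio-many inner loops whose anchors bridge
along the outer loop's path. The 400/100 kb loop sizes of the combined
model mirror the measured abundance ratio (~2.5 condensins II vs ~10
condensins I per Mb) — the additivity argument the tests assert.

# What the generators emulate, and what they do not

The synthetic data carry the statistical structure the analysis assumes:
exponential CTCF spacing with orientation-dependent blocking, Poisson
cohesive links (1 per 500 kb by default), geometric A/B domains,
gamma-distributed loop sizes (shape 4) as the heterogeneity a stalling
array settles into, planted-fold contact maps for scorer calibration, and
lognormal multiplicative noise for fitting targets. Passing tests on
these inputs demonstrates that the *machinery* is correct — that the
estimators recover known ground truth and the models produce the folding
signatures they are built to produce. They do not demonstrate agreement
with any real chromosome: real Hi-C carries balancing artefacts, coverage
biases, inter-chromosomal background and cell-cycle heterogeneity that
the generators deliberately omit, and the experimental feature values of
real cell lines (e.g. the wild-type second diagonal moving from ~6 to
~8 Mb on cohesin depletion) require the deposited data, not these
fixtures.

# Numerical choices and degenerate inputs

Log bins: >= 8 per decade, geometric centers; derivative kernel 1 bin
(2.5 for the loop-size knee). Capture radius 2 x bead diameter. Realized
volume density is measured on an occupancy grid with 2.5-bead-diameter
cells (resolving the body outline without counting internal voids) and
held within 15% of the target in all modes. Zero-loop inputs reduce to
confined random walks; all-zero maps, single-type label tracks, empty
ensembles and disjoint fit ranges raise errors naming the problem;
featureless P(s) yields an empty diagonal set and loop-free fibers yield
`NA` loop-size estimates with a diagnostic, both valid outcomes. An
imposed end-to-end distance beyond the backbone contour, cohesive links
outside the chromatid, and oversized loops for the cylinder geometry are
rejected with the violated constraint named. Seeds: every generator and
builder takes one; ensembles are seed ranges; identical seed and state
reproduce bit-identically through R's RNG (the C++ engine draws from it
too).

Problem sizes used throughout the tests and the acceptance script — 100
Mb single chromosomes at 10 kb beads with 20-60 replicates for the model
ensembles, 40-50 Mb lattices for the extrusion experiments, 20 Mb G2
fixtures, 50 Mb fitting targets with 6 replicates per grid point — were
chosen as the smallest sizes at which the measured quantities are stable
against seed choice (ensemble sds well inside the asserted bands); they
run in seconds to a few minutes on one core.

# Known limitations

No excluded volume beyond geometric confinement and density-targeted
construction: entanglement, topoisomerase action and catenation are out
of scope, and P(s) exponents carry the finite-chain corrections noted
above. The engine has no chemical ATPase cycle, force-dependent speeds,
or diffusive sliding of passively bound cohesin. The constructive builder
approximates a relaxed ensemble, not dynamics: spiral-period *growth* is
therefore estimated from period time series (as in vivo), not simulated.
Dot scoring on lattice trajectories uses a constructive 1D-to-map bridge,
not 3D contacts. Matrix balancing is limited to none; compartment labels
and dot lists are inputs, never called from data. Real-data import is
limited to dense text matrices and BED/BEDPE; the optional HDF5 container
format for binned matrices is not read — the pipeline operates on one
chromosome at a time in dense form.
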