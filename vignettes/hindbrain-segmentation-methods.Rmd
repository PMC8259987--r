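---
title: "Modeling rhombomere formation and boundary sharpening in the zebrafish hindbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling rhombomere formation and boundary sharpening in the zebrafish hindbrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological problem

Between 11 and 14 hours post fertilization (hpf) the zebrafish hindbrain
resolves into rhombomeres r2-r6: five segments of similar size with sharp
gene-expression boundaries, starting from rough, noisy initial expression.
During the same window the neural plate converges dramatically along the
left-right (L-R) axis — from 283 um at 11 hpf to 162 um an hour later and
104 um by 14 hpf — while elongating slowly along the anterior-posterior (A-P)
axis. `rhombosim` implements a stochastic multiscale cell-based model of this
process: continuum morphogen fields on the deforming tissue, a stochastic
gene-regulatory network in each of 345 discrete cells, and subcellular-element
cell mechanics with identity-selective sorting, together with the
boundary-location / sharpness-index / dislocated-cell quantification used to
score the resulting pattern.

## Model structure

### Geometry

The morphogen domain is a rectangle `[0, L1(t)] x [-L2(t)/2, L2(t)/2]` whose
dimensions follow monotone-cubic interpolants of stage-resolved measurements
(`hindbrain_dimensions()`; the three printed widths are measured, the A-P
lengths and the 13-hpf width are documented fixture assumptions). The RA
production region occupies `x1 > p(t)`; cells live in the tissue sub-rectangle
`[r1 L1, r2 L1]` with `r1 = 0.115`, `r2 = 0.691`, chosen so the tissue spans
about five rhombomeres (190 um at 14 hpf). Growth enters through the affine
velocity field `V(x) = (L1' x1 / L1, L2' x2 / L2)`.

Three L-R convergence schedules share their endpoint widths: `rapid` is the
measured curve, `medium` the straight line between the endpoints, and `slow`
the mirror image of the rapid graph across that line. In coordinates
normalized so the chord runs from (0,1) to (1,0) the mirror is
`(u, v) -> (1 - v, 1 - u)`, i.e. the slow curve is the flipped inverse of the
rapid one — single-valued and monotone by construction, and an exact
involution. The alternative pointwise reflection `2*linear - rapid`
(`slow_mode = "pointwise"`) is kept for comparison; it overshoots the initial
width and needs monotonicity clipping.

### Morphogens

Extracellular and intracellular retinoic acid (RA) and free/receptor-bound FGF
obey stochastic convection-reaction-diffusion equations. RA is produced in a
steep Hill-shaped region posterior of `p(t)` (`vr / (1 + (x1/p)^-20)`),
exchanged between compartments at rate `kr`, degraded extracellularly at
`beta_r * kr` and intracellularly at `k0` in the hindbrain or `kmax` inside
the production region; it is absorbed at the anterior limit (the
midbrain-hindbrain boundary acts as a sink) and reflected elsewhere. FGF is
produced at rate `vf H^2 / (1 + ahf H^2)` from the local hoxb1a level `H`,
binds and unbinds its receptor (`kf`, `krf`) and decays (`df1`, `df2`), with
no-flux boundaries.

The moving rectangle is mapped to a fixed computational unit rectangle whose
mesh moves exactly with the affine growth field, so the mesh-relative
advection vanishes identically and the transformed equations carry only the
metric factors `1/L1^2`, `1/L2^2` and the uniform dilution term
`-(L1'/L1 + L2'/L2) C`. During rapid narrowing the dilution term is negative
(a concentration effect): RA and FGF levels surge to a peak near 12 hpf and
relax afterwards, which is the mechanism by which the convergence schedule
reaches the gene network. An upwinded counter-advection term is applied only
in the ablation that removes intracellular convection
(`advect_intracellular = FALSE`), where the intracellular species must stay
put while the mesh moves.

Time stepping is explicit Euler-Maruyama with a centered second-order
Laplacian, sub-cycled to the diffusion stability limit with safety factor 0.4.
Spatiotemporal white noise is discretized as independent Gaussians per node
and step scaled by `sqrt(dt / dA)`; negative excursions are clipped to zero so
fields remain interpretable as concentrations. The default grid is 64 x 32
cells reduced to 64 x 16 in this implementation; halving the spacing changes
the deterministic steady fields by under 2% in L2 norm over the tissue region
(see the test suite), and a 48 x 12 grid — used for the heavier ensemble tests
— reproduces the same segment lengths within the seed-to-seed spread.

### Gene network

Each cell carries four levels: hoxb1a (H), krox20 (K), vhnf1 (V), irx3 (I).
H is activated by intracellular RA and itself and repressed by K and V; K is
activated by FGF signal and itself and repressed by H; V is an RA readout
without self-activation, repressed by I; I is constitutive and repressed by V.
All regulation uses second-order Hill terms; each species carries additive
white noise (multiplicative optionally) and is clipped at zero.

The H/K pair is a classic toggle switch: with self-activation gain 1.5 and a
maximal-to-degradation ratio of 2 each gene is bistable over a window of its
activating input, with a high state near 1.6 (above the classification
threshold 1.2) and an ignition fold at input `~0.05`. Boundary positions
follow from where each gene's activating input crosses its ignition fold in
the *commitment-time* signaling environment (around the 12-12.5 hpf morphogen
peak), because ignition is self-locking:

* r3/r4 — anterior limit of hoxb1a ignition (`arh * RA^2` crosses the fold),
  refined by competition with FGF-driven krox20;
* r4/r5 — the anterior-most excursion of the vhnf1 switch (`arv * RA^2`
  against the irx3-locked branch); cells that lose hoxb1a to rising vhnf1
  switch to krox20 identity, the model's r4-to-r5 identity switching;
* r2/r3 and r5/r6 — the FGF ignition contour of krox20
  (`afk * FGF^2` at the fold), limited anteriorly by residual (transit-level)
  hoxb1a and posteriorly by partial hoxb1a under vhnf1 repression
  (`bvh = 2` deliberately leaves that residual level in r6; with much stronger
  repression the posterior krox20 band overruns r6).

All rate constants are package calibrations (documented in
`gene_params()`, `ra_params()`, `fgf_params()`): they were anchored first on
the 1D steady-state model against the boundary positions implied by the
measured segment lengths, then re-anchored on the full model's
commitment-time RA levels, and finally verified as ensemble-mean lengths
within the measured bands. Kinetic rates are fast (degradation 5-10 per hour)
so commitment completes by about 12.5 hpf, consistent with the observed
timing; uniform rate scaling leaves every threshold and fixed point unchanged.

### Initialization

Simulations start at 11 hpf from a two-stage burn-in on the geometry frozen at
its 11-hpf shape (the pre-11-hpf geometry is not modeled): RA starts at its
deterministic equilibrium (the gradient is established much earlier); for one
simulated hour only vhnf1/irx3 evolve from zero (their mutual-inhibition
border predates the rest of the pattern); for a second hour all species
evolve, with krox20 and FGF from zero and hoxb1a from the constant pre-pattern
level 0.21.

### Cell mechanics

Each of the 345 cells (a 23 x 15 lattice at 11 hpf) is a subcellular-element
cluster: two concentric hexagonal layers of six nodes (outer radius 3.6 um,
inner 1.8 um) tied by linear springs toward three rest lengths (outer ring,
inner ring, same-angle cross-layer). Inter-cell forces act between the outer
(membrane) layers: short-range exponential repulsion independent of identity
plus a longer-range exponential term scaled by `2F - 1`, where the similarity
weight `F = 1 - s_i(1 - s_j) - s_j(1 - s_i)` (with `s` a logistic function of
the krox20 level centered on the classification threshold) is 1 for two
krox20-high or two krox20-low cells (attraction), 0 for a mixed pair
(repulsion) and 0.5 at indeterminate levels (neutral; forcing `F = 0.5`
everywhere removes selectivity). Every node also rides the convergent-
extension velocity evaluated at its cell's centroid. The overdamped update
sub-cycles three times per macro step; a guard rejects steps that move any
node more than one cell radius.

### Metrics

Cells are classified hoxb1a / krox20 / non-expressing by the 1.2 threshold
(ties between two supra-threshold levels go to the larger, then krox20). For a
candidate boundary position `k`, a misplaced cell's penalty is the penetration
depth of its distal edge (`ReLU` of centroid offset plus radius). The boundary
location `m` minimizes the root-sum-square of penalties over cells within
three cell diameters (`6r`), the sharpness index SI is the minimum, and cells
deeper than `6r` are dislocated cells (DC), excluded from the objective and
counted separately; more than 8 DCs marks the pattern failed. The four
boundaries are found by splitting the tissue at the mean hoxb1a position,
locating r3/r4 and r4/r5 on either side, then r2/r3 and r5/r6 in the flanking
intervals. The minimization is an exhaustive scan on a 0.1-um grid with
midpoint tie-breaking (the objective is piecewise smooth with discontinuities
where cells cross the `6r` cutoff, so derivative-based optimizers are
unsuitable); a brute-force 0.01-um oracle in the tests confirms the optimizer.
`r` and the DC cutoff radius are identified with the nominal outer cell
radius.

### Reduced models

The 1D gene-expression model integrates the same network on a fixed A-P
segment matching the 14-hpf morphogen domain (256 nodes), with RA held at its
quasi-static equilibrium, vhnf1/irx3 initialized from their RA-conditioned
equilibrium, and FGF (two-morphogen variant) stepped explicitly. Because the
fixed domain never experiences convergent narrowing, RA production is scaled
by 1.7 so the 1D profile matches the full model's commitment-time signaling
environment. In the one-morphogen variant krox20 is activated by
`ark * RA^2` (gain 0.54, calibrated so the r4-forming bifurcation sits at
initial hoxb1a 0.2) and FGF is dropped; the variant can only specify three
boundaries, and its r4 length is strongly sensitive to the initial hoxb1a
level — the package reproduces the no-r4-below-0.2 threshold and a more than
two-fold r4 expansion between initial levels 0.20 and 0.23. Steady states are
reached by time integration (tolerance `1e-5` on the maximal rate of change,
horizon 12-24 h) rather than root finding, so bistable basin selection follows
the stated initial conditions.

The sorting-only model freezes identities sampled from a position-conditional
five-component Gaussian mixture (components at the equal-fifths segment
centers, spread half a segment length) and runs mechanics alone.

### Orchestration

Per macro step (default 0.0025 h): domain update, morphogen sub-steps, gene
update from signals bilinearly interpolated at centroids (the hoxb1a source
field is re-interpolated onto the grid every fourth step — it evolves on the
slow gene timescale), then mechanics. Gene regulation and selective sorting
can be windowed in time; convergent extension, intracellular advection and
multiplicative noise are switchable. Runs are bitwise reproducible from
(config, seed).

## Choices a user should know about

* **Problem sizes.** Default runs use the 64 x 16 grid (about 20-25 s per
  3-h simulation); the ensemble-heavy tests use 48 x 12 (7-10 s) and the
  random-parameter sweep additionally uses a 0.004-h macro step. Segment
  lengths agree across these resolutions to within the seed-to-seed spread.
* **Noise amplitudes.** `mu_h = mu_k = 0.1`, `mu_v = mu_i = 0.02`. Because
  hoxb1a and krox20 self-sustain once ignited, much larger amplitudes let
  stray cells in r2/r6 ratchet into wrong identities and the dislocated-cell
  count explodes; the defaults keep boundary-zone switching (the biologically
  motivated role of noise) without that pathology.
* **Classification tie-break** (both levels above threshold) goes to the
  larger level with ties to krox20; co-expression is transient and low, so the
  rule is essentially never exercised at steady state.
* **Degenerate inputs.** Boundary search with no cells returns the interval
  midpoint flagged degenerate; a pattern without hoxb1a cells is reported
  failed with undefined boundaries; unordered boundaries yield missing segment
  lengths with a warning.

## What the simulations do and do not show

The synthetic-data generator (the model itself plus the measured-dimension
fixture) emulates: the measured narrowing of the neural plate and slow A-P
elongation, morphogen surge-and-decay under convergence, noisy gene
expression with toggle-switch commitment, identity switching near r4/r5,
selective sorting, and the boundary-quantification pipeline. It does not
emulate cell division or D-V thickening, three-dimensional architecture,
explicit Ephrin/Eph molecules (selectivity enters only through the krox20
similarity weight), anterior FGF sources, or measurement noise of the imaging
pipeline. Passing tests therefore demonstrate internal consistency of the
model and agreement with the printed segment statistics, not validation
against raw embryo images.

Known limitations: sorting in the sorting-only model reduces roughness only
modestly over three simulated hours at the default force scale (the schedule
ordering is nevertheless robust); the r3/r4 sharpness index retains a few
micrometers of residual roughness from late krox20/hoxb1a competition; and
the one-morphogen variant's r4 bifurcation point, while placed at initial
hoxb1a 0.2 by calibration, is sharp, so lengths immediately above threshold
are smaller than the printed 21-44 um range (the two-fold expansion contract
is what the package asserts).

## Worked example

```{r}
library(rhombosim)

cfg <- simulation_config(seed = 1)
run <- run_full_model(cfg)
tail(run$metrics[, c("time_hpf", "len_r3", "len_r4", "len_r5",
                     "SI_r3r4", "DC", "failed")], 3)

ens <- run_ensemble(cfg, n = 6, seeds = 1:6)
round(ens$mean, 1)
```

An ensemble at the default resolution gives mean lengths close to
(r3, r4, r5) = (42, 38, 34) um — inside the measured 42+-5, 34+-5 and 37+-4 um
bands — with at most one dislocated cell per run.
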