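---
title: "Methods: coordination-state analysis and binding thermodynamics of lanthanide-peptide complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordination-state analysis and binding thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncoord)
```

## The scientific problem

The trivalent lanthanides La^3+^ through Lu^3+^ are chemically almost
interchangeable: all are +3 cations whose ionic radii span less than
0.26 Å across the whole series. A 17-residue lanthanide-binding peptide
(an engineered calmodulin-derived EF-hand loop, here called LBT3)
nevertheless binds them with affinities differing by more than
60-fold, and non-monotonically in atomic number. The package implements
the computational analyses by which that specificity can be dissected:

* **coordination-state calling** on donor--ion distance series from
  molecular trajectories (the six donor sites are the D3/D7/E11/E14
  side-chain carboxylate oxygens, the N5 side-chain carbonyl oxygen
  N5-Oδ1, and the W9 backbone carbonyl oxygen);
* **chelation-mode classification** (mono- vs bidentate carboxylates)
  and **first-shell water counting**, combined into the five complex
  states (i)--(v) distinguished by whether N5-Oδ1 is coordinated and
  how many waters touch the ion directly;
* **solvation statistics** -- radial distribution functions g(r) and
  running coordination numbers around the ion or a probe proton;
* **free-energy profiles** over the N5-Oδ1⋯Ln^3+^ distance with
  associated/dissociated basin depths;
* **one-site ITC analysis** and the lanthanide-series decomposition of
  ΔG into ΔH and −TΔS, with branch-point detection and the
  three-regime classification of the series.

Because no published trajectories accompany the experimental data, the
package ships a synthetic-data generator producing labelled
trajectories and thermograms with exactly the statistical structure the
analyses assume. Every classifier can therefore be scored against a
known ground truth.

## The synthetic trajectory generator

The generator is an explicit emission model, not a molecular-dynamics
surrogate. Three layers:

**1. A continuous-time Markov chain over the complex states.** States
(i), (ii), (iii), (iv), (v) interconvert only along the edges
i⇄ii⇄iii⇄iv (the path seen for large ions, where a water
infiltrates the intact complex and then displaces N5-Oδ1) and
i⇄v⇄iii (the small-ion path, where N5-Oδ1 leaves first and a
water follows). The chain is simulated exactly (Gillespie event-time
sampling) and then discretised at the frame times, so transitions
shorter than one frame interval are invisible -- just as in saved MD
output. The N5 binding state and the first-shell water count follow
deterministically from the state: i, ii are N5-bound; the water count
is 0, 1, 1, 2, 0 for i--v.

No residence-time statistics are published for these states, so the
default rates are a generator choice, flagged as such: 0.05--0.20 per
ns per directed edge, giving mean dwell times of 4--6 ns (hundreds of
frames at the default 10 ps spacing). Two deliberate consequences:
dwells are long enough that the frame-sampled path is a faithful copy
of the event path, and the probability of two events inside one frame
interval -- the only mechanism that can fabricate an apparent
off-path transition -- is of order 10^-5 per frame.

**2. A geometric emission model.** The ion sits at the centre of a
cubic periodic box (default edge 4.3 nm, holding 2589 waters -- the
simulated solvation conditions). Each donor site has a fixed direction
on the coordination sphere with small angular jitter per frame. Bound
donor--oxygen distances are drawn from a truncated normal with mean
(ionic radius + 1.40 Å)/10 nm -- the oxygen contact distance, which
ties the bound-state geometry to the lanthanide contraction -- and
σ = 0.01 nm, hard-clipped to the 0.21--0.30 nm window used as the
coordination restraint range in the underlying structure calculations.
The dissociated N5-Oδ1 sits at 0.50 ± 0.04 nm. Carboxylate oxygen
pairs keep an exact 0.22 nm O--O separation: bidentate places both
oxygens on the coordination sphere, monodentate points the second
oxygen radially outward. Mono⇄bi switching is a two-state Markov
chain per carboxylate (defaults: D3 and D7 switch, E11 and E14 stay
bidentate).

First-shell waters sit within 0.30 nm of the ion. In state (iii) the
single bound water rides the N5 axis at a radius chosen so it stays
within hydrogen-bond reach (≤ 0.35 nm) of the dissociated N5-Oδ1 --
the structural motif in which the infiltrating water bridges the ion
and the displaced donor. One designated probe water tracks the D3
chelation mode (near the G8 amide proton, 0.25 nm, under bidentate
chelation; far, 0.45 nm, under monodentate, where the freed D3-Oγ2
traps the water instead). All remaining waters are uniform in the box
outside a 0.35 nm exclusion radius around every solute atom.

Coordinates are i.i.d. per frame given the state. A temporally
correlated (Ornstein--Uhlenbeck) emission would be more MD-like but is
unnecessary: every downstream analysis here is a per-frame function or
a histogram, so only the stationary distribution matters. This is the
main sense in which passing tests on synthetic data speak to the
analysis code and not to real MD output: real trajectories add
autocorrelation (slower convergence of occupancies and RDFs) and
force-field physics, neither of which the classifiers themselves
consume.

**What the generator does not emulate:** no energetics or force field,
no peptide backbone beyond the donor atoms and the two probe amide
protons (N5-HN, G8-HN), no counterions, no water hydrogens, no
broken-complex states (the five non-N5 sites never dissociate under
the defaults, mirroring the observation that they chelate continuously).

## Coordination calling and the five-state classifier

Two distance cutoffs define donor binding: coordinated below
r_on = 0.30 nm, dissociated above r_off = 0.40 nm. Inside the
0.30--0.40 nm gap the assignment keeps the previous frame's label.
This hysteresis rule exists because a single cutoff placed anywhere in
the gap chatters on thermal noise; the dual threshold with memory is
the standard debouncing construction. A first frame that falls inside
the gap takes the label of the nearer threshold, with an exact
midpoint tie resolved to unbound (the conservative call). Re-applying
the classifier to distances consistent with its own output is a no-op,
and labels are invariant to how distance values move strictly inside
the retention band -- both properties are tested.

The complex-state classifier is a pure per-frame function of (N5
state, water count, five-site integrity): any broken non-N5 site gives
`broken`; otherwise bound/0 → i, bound/1 → ii, unbound/1 → iii,
unbound/2 → iv, unbound/0 → v, and anything else (e.g. bound with two
waters) → `other`. The catch-all labels are additions to the five
experimentally described states, which do not cover the full combinatorial
space, and a total classifier is required for honest transition
bookkeeping. Site integrity for the carboxylates is judged at site
level (either oxygen within r_chel), matching the per-residue language
in which chelation is described; W9's backbone oxygen counts as one of
the five integrity sites like the carboxylates.

Transition statistics count adjacent-frame label changes and flag --
but do not reject -- transitions outside the allowed edge set, since
frame sampling can hide intermediates.

The first-shell water cutoff r_water = 0.30 nm is not stated in the
experimental source; it is the package default because it matches the
donor-coordination window, and `first_minimum()` on the water--ion RDF
of a generated trajectory (first shell at 0.26 nm, bulk beyond
0.35 nm) returns a boundary near 0.30--0.32 nm, confirming internal
consistency. It is configurable wherever it is used.

## Solvation statistics

`rdf()` histograms minimum-image distances from a single reference
atom to a target set, normalising each shell by 4πr²Δr and the mean
target density N/⟨V⟩. The ideal-shell form (rather than the exact
bin--sphere intersection volume) biases g by under 0.5% at the default
Δr = 0.002 nm and is documented rather than corrected. The running
coordination number n(r) is the cumulative mean count, algebraically
identical to 4πρΣg(r_k)r_k²Δr over bins. First-minimum detection
smooths g with a 3-bin moving average before the discrete search --
enough to step over single-bin noise without shifting a genuine
minimum at the default bin width.

Bin width and range have no published values to match; the defaults
(Δr = 0.002 nm, r_max = 1.0 nm) are chosen for smoothness at the
100 ns-scale sampling the analyses target and are plain arguments.

## Free-energy profiles

`pmf_from_samples()` Boltzmann-inverts a weighted distance histogram:
F(r) = −RT[ln ĥ(r) − 2 ln r·(jacobian)] + C, with C fixed by min F = 0
and R = 1.987204×10⁻³ kcal/(mol K). Empty bins are NA, never zero.
The 2 ln r term removes the radial volume entropy; whether the
published landscapes include it is not stated, so both conventions are
supported and recorded in the result object, with the correction on by
default because the coordinate is a radial distance. The weight
argument exists so samples produced under an external bias b(r) can be
reweighted with w ∝ exp(+b/RT); the adaptive-bias method used to
produce the published landscapes is itself out of scope -- this module
consumes samples, whatever produced them.

Basin depths are window minima (associated 0.20--0.30 nm, dissociated
0.40--0.70 nm by default, the same convention as the coordination
thresholds), and ΔF = F_dissoc − F_assoc is positive when association
is favoured. The published depth differences (7.1 and 4.6 kcal/mol for
the Lu and La complexes) require 200 ns of adaptive-bias all-atom MD
with backbone restraints and are deliberately not reproduction targets;
the tests instead verify the estimator on analytically constructed
densities (harmonic curvature within 5% at 10⁶ samples, a constructed
2.5 kcal/mol double-well gap within 0.05, exact Jacobian cancellation
on shell-uniform samples, umbrella reweighting consistency, and
linearity in T).

## ITC model and fitting

The one-site forward model is the Wiseman isotherm with the
half-displacement volume bookkeeping used by the instrument software:
cumulative injected volume dV, cell concentrations
M = M₀(1−dV/2V₀)/(1+dV/2V₀) and X = X₀(dV/V₀)/(1+dV/2V₀), bound
fraction from the physical root of
Θ² − Θ(1 + X/NM + 1/NKM) + X/NM = 0, cumulative heat Q = NΘM·ΔH·V₀ and
per-injection heat q_i = Q_i − Q_{i−1} + (v_i/V₀)(Q_i+Q_{i−1})/2.
A no-displacement mode exists for testing conservation laws. The
default protocol is the experimental one: 283.15 K, 15 µM peptide in
the cell, 300 µM Ln^3+^ in the syringe, 20 injections of 2 µL + 19×10 µL.
The cell volume (1.4 mL) is the instrument default, not a printed
value; it scales heats but cancels in parameter recovery as long as
generation and fitting share it.

Fitting is Levenberg--Marquardt least squares (via `minpack.lm`) of
(N, K, ΔH) -- or (K, ΔH) with N fixed -- with a multistart grid over
log₁₀K ∈ {3..8} to avoid local minima, and the first (2 µL
pre-)injection excluded from the residuals by default while its volume
still enters the concentration bookkeeping. The c value N·K·M₀ is
reported; below c = 1 the isotherm loses its sigmoidal shape, the free
(N, K, ΔH) problem becomes ill-conditioned, and the fitter warns and
recommends the fixed-N = 1.0 fallback -- the same convention the
instrument software prescribes for low-K samples. ΔG = −RT ln K and
−TΔS = ΔG − ΔH follow exactly.

## Series decomposition

The per-ion table carries ΔG, ΔH, −TΔS (kcal/mol), optional K_D, and
the packaged Shannon eight-coordinate ionic radii; only the ordering
and the <0.26 Å spread of the radii are load-bearing, not the
individual values. Validation enforces |ΔG − ΔH − (−TΔS)| < 0.02
kcal/mol per row (printed-rounding tolerance).

ΔΔ quantities are plain component-wise differences, antisymmetric by
construction, with ΔΔG = ΔΔH + (−TΔΔS) exact. Branch detection scans
successive differences for sign flips, treating |d| ≤ 0.05 kcal/mol as
"no change" continuing the prior direction -- the tolerance under
which a −0.01 kcal/mol step across the late series counts as flat, as
it is interpreted experimentally. Regime classification maps the
detected branch structure onto the three classes of the series
(regime I from La through the first branch, regime II through Yb with
an IIa/IIb split at Tb, regime III = Lu); the inclusive "≤" boundary
convention makes Sm and Tb members of two classes, which is
represented as explicit dual membership rather than forced into a
partition.

The synthetic series generator interpolates ΔH and −TΔS piecewise
linearly in atomic number between anchor ions (La, Sm, Tb, Yb, Lu)
fixed by the reported values (ΔH_La = 3.83, ΔG_La = −6.9 kcal/mol, and
the ΔΔ increments between the anchors), so the down--up--down trend
with branches at Sm and Yb holds by construction and K_D follows from
ΔG at 283.15 K. The full per-ion experimental table is not publicly
tabulated, so the package ships only these anchors plus the generator.

## Problem sizes and numerical choices

The test suite and the acceptance script use problem sizes chosen so
each statistical tolerance is comfortably supported by the sampling
noise of the estimator under test: 10⁴-frame labelled trajectories
with ~30 waters for state-recovery scoring (bulk water count does not
affect recovery; it only pads the box), 100 frames × 1000 points for
the ideal-gas RDF check in a 0.8 nm box with 0.05 nm bins (so every
bin beyond 0.2 nm holds thousands of counts and the 5% flatness band
sits at ≥3.5 standard errors), and 10⁶ samples for the free-energy
recoveries. Accuracy scoring excludes the frames adjacent to each true
transition, where the frame-discretised ground truth and the
hysteresis memory legitimately disagree by one frame.

Numerical conventions worth knowing: all internal lengths are nm (PDB
I/O converts from Å); boxes are orthorhombic with minimum-image
distances everywhere; residue numbering is 1-based as in the peptide
nomenclature (D3, N5, D7, G8, W9, E11, E14); empty PMF bins are NA;
occupancy fractions sum to 1 within 10⁻¹²; and every generator is
reproducible bitwise from its integer seed.

## Known limitations

* The generator's i.i.d.-given-state emission understates the
  autocorrelation of real MD, so convergence rates measured here are
  optimistic; classifier correctness is unaffected.
* Chelation classification is purely distance-based; no angular
  (ion--O--C) criterion, so a grazing oxygen at 0.29 nm counts as
  coordinated regardless of geometry.
* The RDF is referenced at a single atom, as appropriate for one ion
  or one probe proton per box -- there is no site--site averaging.
* The one-site ITC model has no baseline integration (inputs are
  already-integrated per-injection heats) and no multi-site or
  sequential-binding extensions.
* The regime classifier encodes the lanthanide series semantics (Tb
  split, Yb/Lu boundary); it is not a general change-point method.
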