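# lncoord

Coordination dynamics and binding thermodynamics of lanthanide-peptide
complexes.

The trivalent lanthanides La³⁺…Lu³⁺ differ in ionic radius by less than
0.26 Å across the whole series, yet a short calmodulin-derived
lanthanide-binding peptide (LBT3) binds them with affinities spanning
more than 60-fold, non-monotonically in atomic number. The
discriminating mechanism is structural: for the larger ions a water
molecule can coordinate the ion directly inside the complex, displacing
the weakest donor (the N5 side-chain carbonyl oxygen, N5-Oδ1), while
the smaller ions are fully enclosed by the peptide's six donor sites.

`lncoord` implements the analysis layer of that dissection, for people
working with molecular trajectories and titration calorimetry of
metal-peptide systems:

* **Coordination calling** — per-frame donor–ion distances with
  hysteresis (dual-threshold) bound/unbound assignment: coordinated
  below *r*ₒₙ = 0.3 nm, dissociated above *r*ₒff = 0.4 nm, memory in
  between.
* **Chelation modes** — mono- vs bidentate carboxylate classification
  for D3/D7/E11/E14.
* **Complex states (i)–(v)** — the joint classification by N5-Oδ1
  binding and the number of directly coordinated waters
  (i: 6 sites + 0 w; ii: 6 + 1; iii: 5 + 1; iv: 5 + 2; v: 5 + 0), with
  occupancy and transition bookkeeping restricted to the allowed paths
  i⇄ii⇄iii⇄iv and i⇄v⇄iii.
* **Solvation** — radial distribution functions g(r), running
  coordination numbers n(r), first-shell boundary detection.
* **Free-energy profiles** — F(r) = −RT ln ĥ(r) (+ optional radial
  Jacobian correction) from weighted distance samples, with
  associated/dissociated basin depths.
* **ITC** — the one-site Wiseman isotherm with displaced-volume
  bookkeeping, blank subtraction, Levenberg–Marquardt fitting of
  (N, K, ΔH) with the fixed-N = 1 fallback for non-sigmoidal (c < 1)
  thermograms, and ΔG = −RT ln K, −TΔS = ΔG − ΔH.
* **Series decomposition** — ΔΔ quantities between ions
  (ΔΔG = ΔΔH + (−TΔΔS)), branch-point detection in the ΔH/−TΔS trends,
  and the three-regime classification of the series (La–Sm, Sm–Yb split
  at Tb, Lu).
* **Synthetic data** — a labelled-trajectory generator (Markov-switching
  complex states, ionic-radius-tied coordination geometry, first-shell
  waters, periodic bulk solvent) and a thermogram generator, so every
  classifier is testable against known ground truth.

Trajectory I/O covers multi-model PDB and XYZ (+ box sidecar), with an
atom-selection mini-grammar (`resid 5 and name OD1`). All internal
lengths are nm.

## Worked example

Generate a labelled La³⁺ trajectory, recover its complex states, and
run the thermodynamic track:

```r
library(lncoord)

spec <- traj_spec(n_frames = 5000, water_count = 30, seed = 42)
gen  <- generate_complex_trajectory(spec)

ds <- distance_series(gen$traj, gen$top, "resname LA", "resid 5 and name OD1")
n5 <- hysteresis_states(ds)
wc <- water_coordination_count(gen$traj, gen$top, "resname LA")
cs <- classify_complex_state(n5, wc$counts)
transition_stats(cs)
#> Transitions: 14 ( 0 off-path )
#> Occupancy: i 0.576, ii 0.207, iii 0.104, v 0.113

mean(as.character(cs) == gen$truth$complex_state)
#> [1] 1
```

Every frame is classified correctly: the complex spends most of its
time fully coordinated (state i), visits the water-infiltrated states
ii and iii, and all 14 observed transitions lie on the allowed paths.

```r
exp <- generate_itc_thermogram(1, K = 1e6, dH = 3.83, noise_sd = 0.1, seed = 1)
fit_one_site(exp)
#> One-site ITC fit: N = 1.004, K = 9.888e+05 1/M (c = 14.9)
#>   dG = -7.767, dH = 3.837, -TdS = -11.605 kcal/mol at 283.15 K
```

A 20-injection thermogram at the experimental protocol (15 µM peptide,
300 µM Ln³⁺, 10 °C) with 0.1 µcal noise returns the generating
parameters to within ~1%; the positive ΔH and large negative −TΔS show
the entropy-driven character of the binding (water release outweighs
the endothermic dehydration).

```r
tab <- generate_ln_series_table()
br  <- detect_branch_points(tab$dH, tab$ion)
br
#> [1] "Sm" "Yb"
classify_regimes(tab, br)
#> I   : La Ce Pr Nd Pm Sm
#> IIa : Sm Eu Gd Tb
#> IIb : Tb Dy Ho Er Tm Yb
#> III : Lu
#> dual membership: Sm, Tb

dd <- delta_delta(tab, "La", "Sm")
sprintf("ddG_Sm-La = %.2f = %.2f + %.2f kcal/mol", dd$ddG, dd$ddH, dd$mTddS)
#> [1] "ddG_Sm-La = -1.83 = -2.20 + 0.37 kcal/mol"
```

The enthalpy trend branches at Sm and Yb, the series splits into the
three binding regimes (with Sm and Tb as flagged boundary members),
and the Sm–La affinity gain of −1.83 kcal/mol decomposes into a
−2.2 kcal/mol enthalpic gain against a 0.37 kcal/mol entropic cost.

A thin command-line wrapper over the same functions ships at
`inst/cli/lncoord` (subcommands `simulate-traj`, `simulate-itc`,
`convert`, `coordinate`, `rdf`, `pmf`, `itc-fit`, `series`,
`pipeline`).

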