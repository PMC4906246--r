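---
title: "Methods: modelling voltage sensing by the GPCR pocket sodium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling voltage sensing by the GPCR pocket sodium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltsense)
```

## The model

Class A GPCRs carry a conserved, water-filled pocket reaching from the
orthosteric ligand site down to Asp^2.50^, where a Na^+^ ion binds.
Because the pocket spans a large fraction of the transmembrane voltage
drop, the position of this ion responds to membrane voltage, and its
displacement registers as a gating charge of the size measured
electrophysiologically on muscarinic and adrenergic receptors
(~0.5 e). `voltsense` models this system as a single reaction
coordinate: the ion's position z along the membrane normal, measured
from the Asp^2.50^ C-alpha plane.

Three ingredients define a receptor variant:

* an equilibrium free-energy profile G(z) (the PMF),
* an electrical-distance profile delta(z) in [0, 1], the fraction of
  the transmembrane voltage drop traversed at z,
* the thermodynamic state (310 K, kT = 2.577 kJ/mol).

A membrane voltage V_m tilts the landscape linearly:

G_V(z) = G(z) − q F (V_m/1000) delta(z),    F = 96.485 kJ/mol/V,

so a +1 carrier at 100 mV gains ~10 kJ/mol over a full crossing —
the scale argument that physiological voltages can relocate the ion.
Sign conventions: V_m = phi(in) − phi(out); depolarized is positive;
outward (increasing z) cation movement under depolarization releases
energy and yields a positive gating charge q_g = q·(delta(b) −
delta(a)).

## Reference profiles: the stated world

`make_reference_pmf()` and `make_delta_profile()` build analytic
ground truths for three variants (`dor_wt`, `dor_n131v`, `m2r`) from
knot tables interpolated with a shape-preserving monotone cubic. The
knots pin every published landscape feature: for the wild-type
delta-opioid receptor the global minimum at the crystallographic site
(z = 0), a deeper intracellular minimum near z = −1.6 Å behind a
5.3 kJ/mol barrier, a 9.0 kJ/mol outward confining barrier, a
13.0 kJ/mol total barrier, and transient-site minima near z ≈ 7 and
10 Å about 11 kJ/mol up; for the Asn131^3.35^Val mutant a broad
(~4 Å) basin preferring z = −2.2 Å, the same 13.0 kJ/mol but smoother
main barrier, and a ~10 kJ/mol transient offset; for M2R a single
sharp 26 kJ/mol barrier ~4.5 Å above Asp69^2.50^, a minor well at
z ≈ 3 Å, and a ~15 kJ/mol transient offset. Plateau electrical
distances are 0.42, 0.63 and 0.53, with 0.30 at the orthosteric-pocket
base for the wild type and M2R.

Values the source work does not print are package constants chosen
once: wall heights (20 kJ/mol), bulk plateaus (14–18 kJ/mol), the
depth of the −1.6 Å minimum (1.5 kJ/mol), the minor-well depths, and a
small δ(−2) = −0.03 dip that makes hyperpolarization pull the ion
deeper into the pocket. The 5.3 kJ/mol inter-minima barrier is
measured from the global (z = 0) minimum.

Why a custom interpolant: R's `splinefun(method = "monoH.FC")`
overshoots extremum knots by up to ~0.4 kJ/mol because its
Fritsch–Carlson filter does not zero the derivative where the secant
slope changes sign. The package's interpolant does, so knot barriers
are exact and the curve has no extrema the tables do not imply.

## The sampler

`langevin_trajectory()` integrates overdamped Brownian dynamics,

z ← z + D dt F_eff(z)/kT + sqrt(2 D dt) η,

with reflecting walls at the profile edges, harmonic umbrella biases
handled analytically, and optional voltage tilt folded into the force
table. Defaults D = 0.05 Å²/ps and dt = 0.01 ps keep the biased update
stable up to κ ≈ 1000 kJ/mol/Å².

By default every Euler move is used as a MALA proposal and accepted
with the Metropolis–Hastings ratio (`metropolis = TRUE`). This is a
deliberate design choice: the plain Euler chain carries an O(dt)
stationary-density error (~5% variance inflation at κ = 400,
dt = 0.01) which is negligible for dynamics but is amplified
enormously by umbrella unbiasing, because adjacent stiff windows
(spacing 0.5 Å, sd = sqrt(kT/κ) ≈ 0.08 Å) overlap only through their
~3-sigma tails. With the correction, window ensembles are exactly
Boltzmann at the prescribed step size; acceptance rates are ~97%.
First-passage simulations (`langevin_first_passage()`) default to
plain Euler since there the observable is the dynamics itself.

## Umbrella sampling and WHAM

`make_umbrella_windows()` emulates the umbrella protocol (ladders
finer than 0.5 Å; the published runs used >150 ns per window — the
synthetic protocol controls per-window sample counts instead, since
"time per bin" has no direct analogue here). `wham()` solves the
standard self-consistency equations on bins of 0.25 Å (< 0.5 Å as
prescribed), anchored to min G = 0, with empty bins flagged rather
than interpolated.

Two numerical choices matter in the stiff-spring regime the synthetic
world prescribes (κ·Δ²/kT ≈ 5):

1. **Bin-averaged bias weights.** Evaluating exp(−w/kT) at the bin
   center is wrong by many kT across one bin; the package uses the
   analytic normal-CDF average over the bin, then refines it with the
   current PMF estimate on a within-bin sub-grid (3 passes). Without
   this, recovered profiles are wrong by tens of kJ/mol; with it,
   accuracy is near binless.
2. **Anderson-accelerated iteration.** Tail-only overlap makes the
   plain fixed-point map converge with a ratio ≈ 1; Anderson depth-5
   extrapolation reaches the 1e-8 kJ/mol tolerance in a few thousand
   iterations, with convergence always certified on the plain
   fixed-point residual.

`bootstrap_pmf()` implements the Bayesian bootstrap (continuous
Dirichlet(1,…,1) weights per window, 200 runs by default), each
replicate warm-started from the full-data solution and re-anchored at
the same reference bin. Autocorrelation is not corrected — the
source protocol is silent on it — so the SD is a weight-resampling
SD, interpreted accordingly. `barrier_analysis()` locates extrema on
a lightly smoothed copy (3 bins) with persistence pruning (1 kJ/mol),
but always reports energies from the raw curve, so sharp barrier tops
are not flattened; minima are labeled by the nearest reference site
(deep −1.6, allosteric 0, transient 7 Å).

## Membrane voltage from charge densities

`potential_from_density()` double-integrates the slab Poisson
equation by trapezoid quadrature (phi(z) = −(1/ε0)∫(z−z′)ρ dz′, ρ in
e/nm³), with an optional linear-term subtraction enforcing
phi(L) = phi(0) for periodic boxes — the standard slab-potential
convention. `transmembrane_voltage()` takes explicit plateau ranges
(the compartments are part of the experiment definition; automatic
plateau detection is deliberately not a default) and warns when a
range is not flat. `windowed_average()` reproduces the overlapping
2-ns-window / 1-ns running-mean scheme used for V_m time series.

## Gating charges and electrical distance

The double-bilayer (CompEL) generator `make_qv_ensemble()` is a
capacitor model: at bulk imbalance Δq with the probe ion restrained a
fraction delta across the field, V_m = (Δq − q·delta)/C_m, with
C_m = 4 e/V so that one ion of imbalance sustains 250 mV (the
published 1–4 ions ↔ ~250–1,000 mV calibration). Reported means
carry SE = vm_noise_sd/sqrt(n_replicates); the default 10 mV / 50
replicates reproduces the ±0.02–0.03 e error scale of the printed
gating charges.

`gating_charge()` implements the pairing estimator: the mean voltage
offset between two restrained positions across the common imbalance
ladder, divided by the pooled fitted Q–V slope. "Maximum and minimum
slopes" are read as the extreme consecutive-point secants; the error
is the half-spread of the estimate under those two slopes. The mean
over imbalances is used (the source is implicit on this), and the
per-Δq spread is available from the series. `carrier_equivalence()`
expresses the indifference of q_g to the carrier's identity: a proton
crossing the M2R pocket registers 0.53 e ≈ 0.5 e, same as Na^+^.

## Tilted landscapes and kinetics

`tilt_pmf()` anchors every tilted curve at the base profile's global
minimum (the allosteric basin), so V_m = 0 reproduces the equilibrium
PMF exactly for every variant — the published figures instead chose
offsets arbitrarily per curve. `equalization_voltage()` solves the
linear tilt identity at fixed state positions; note the minima
themselves wander under tilt, so a brute-force scan of tilted minima
gives slightly different numbers (~9% for M2R) — the fixed-state
definition is used because it is the closed form the tilt identity
defines. `kinetic_traps()` counts minima with confining depth above a
threshold (default 2 kJ/mol: below ~kT would count noise, above ~5
would hide the printed ruggedness). `mean_first_passage_time()` uses
the standard double-integral quadrature; the CLI's voltage ladder
default is 250–1,000 mV in 250 mV steps (the figure increments do not
state a step; 250 mV assumed).

## Trajectory analysis

`assign_states()` labels frames as deep / allosteric / transient /
bulk with cutpoints −1, 3, 12.5 Å (from the site positions: allosteric
z = 0, transient z ≈ 7–10, exit beyond), then debounces: excursions
shorter than `min_dwell` (default 100 frames) merge into the
surrounding state, suppressing barrier-top recrossings. The dwell
criterion is a package decision — the source gives none.
`detect_transitions()` annotates events with the smoothed voltage
("approximate V_m at the time of the transitions"), never the
instantaneous value. `transition_statistics()` aggregates replicate
first-passage outcomes per voltage.

## What the synthetic world does and does not establish

The generator emulates: Langevin sampling of the printed PMFs,
stiff-spring umbrella windows, capacitor-model Q–V ensembles with
replicate noise, and voltage-tilted escape dynamics. It does not
emulate: 3D pathway degeneracy (the published transient-site binding
proceeds by many pathways; the 1D coordinate is valid only inside the
pocket), protein conformational gating charge (~0.13 e, out of
scope), hydration changes, multi-ion occupancy at hyperpolarized
voltages, or force-field physics. A green parameter-recovery test
therefore establishes that the pipeline is a faithful estimator on a
world whose ground truth encodes the printed values — not that it
reproduces the MD observables themselves.

## Scales, tolerances, degenerate inputs

* Acceptance experiments: 28 (WT) / 31 (M2R) windows, κ = 400 / 600
  kJ/mol/Å², 4×10⁶ integration steps per window recorded every 4th.
  The protocol floor of 2×10⁵ steps is honored as a floor: at exactly
  2×10⁵ the tail-overlap stitching noise leaves ±2 kJ/mol seed
  spread, while the larger runs sit within ~±0.7 of truth — still
  compared at the published ±2.5 kJ/mol.
* Module tests run reduced scales (10⁵–2×10⁵ samples, 30–40 bootstrap
  replicates) to keep the suite fast; full 200-run bootstrap is
  supported.
* WHAM errors on non-overlapping ladders name the dead interval;
  non-convergence reports the residual. Zero-step windows, empty
  imbalance ladders, degenerate equalization states (same position or
  equal delta) and ragged/non-uniform time series all fail loudly
  with the offending quantity named.

## Worked example

```{r example}
pmf <- make_reference_pmf("dor_wt")
delta <- make_delta_profile("dor_wt")

# the printed features, straight from the analytic curve
round(unlist(pmf_site_report(pmf, smooth = FALSE)), 1)

# noise-free gating charge between pocket floor and bulk
qv <- make_qv_ensemble(compel_spec(delta, vm_noise_sd = 0), c(0, 15))
gating_charge(qv[[1]], qv[[2]])

# voltage at which allosteric and transient sites level out
round(equalization_voltage(pmf, delta, 0, 7))
```

## Known limitations

* The 1D coordinate is meaningful only within the internal pocket;
  beyond the pocket exit the landscape is a schematic plateau.
* Bootstrap SDs ignore autocorrelation and therefore understate
  uncertainty for strongly correlated samplers.
* The binned WHAM with adaptive weights approaches but does not equal
  a binless estimator; residual discretization error at bin 0.25 Å
  and κ = 400 kJ/mol/Å² is a few tenths of kJ/mol.
* The capacitor Q–V model is exactly linear; nonlinear capacitance
  and protein charge rearrangements beyond the probe ion are out of
  scope.
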