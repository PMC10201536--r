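---
title: "Models and methods behind tautopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tautopath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tautopath)
```

# The scientific question

When DNA replicates, a helicase forces the two strands apart. If, during
that separation, the adenine–thymine pair undergoes a double proton
transfer (DPT) — thymine donating the proton of hydrogen bond B2 to
adenine, then adenine donating the proton of B1 back — the result is the
rare tautomeric pair A\*–T\*. A tautomer trapped on a separating strand can
mispair at the next replication and fix a point mutation. Whether that is
mechanistically plausible hinges on three quantities: the separation at
which the tautomeric well first becomes a bound minimum (the *onset*), how
fast the reverse barrier that protects the tautomer grows with further
separation, and how long the tautomer must survive to be carried past the
point of no return.

`tautopath` implements this analysis as a desk-scale pipeline. A calibrated
two-coordinate model surface stands in for an electronic-structure
landscape, and a coarse-grained bead–spring duplex stands in for an
all-atom simulation. Neither surrogate claims quantitative fidelity to
quantum chemistry; they are built so that the *structure* of the problem —
the stationary-point topology, the barrier laws, the mechanics of steered
unzipping — is faithfully represented and every algorithmic claim can be
tested end to end.

# The model energy surface

## Coordinates and states

A state is `(q1, q2, d)`: the transfer progress of the B1 proton, the
transfer progress of the B2 proton, and the strand-separation distance in
Å (the summed displacement of the two backbone pivot sites from
equilibrium). `(0, 0)` is canonical A–T, `(0, 1)` the zwitterion
A⁺–T⁻ after the first (B2) transfer, `(1, 1)` the tautomer. The physical
box is `q ∈ [-0.2, 1.2]`.

## Functional form

At fixed `d`,

$$V(q_1, q_2) = S(q_2;\, h_1, \delta_1) \;+\; s(q_2)\, T_2(q_1) \;+\;
\bigl(1 - s(q_2)\bigr)\, P\, q_1^2,$$

where `S(q; h, δ) = 16 h q²(1-q)² + δ q` is a tilted quartic double well,
`T₂` is the step-2 potential along `q1` (another tilted quartic where the
tautomer well exists, a smooth quadratic ramp `c_u q₁²` with `c_u = 1` eV
where it does not), `P` is the sequential penalty (default 3 eV), and `s`
is a quintic smoothstep switch, `s(q) = q³(10 − 15q + 6q²)` clamped to
`[0, 1]`. The switch encodes the asynchronous stepwise mechanism: until
the B2 proton has moved, the B1 proton sees only the stiff penalty, so
concerted diagonal motion is strongly disfavoured. The quintic (rather
than cubic) smoothstep keeps the surface twice differentiable after
clamping and, because its first two derivatives vanish at both ends,
decouples the penalty from both proton wells. Quadratic walls
(`10 eV/Å²`) outside the box keep optimizers in the physical region; the
exported `potential_energy()` refuses out-of-bounds coordinates outright,
while internal evaluators used by relaxation and path searches use the
walls.

## Calibration

The `d`-dependence enters through barrier laws evaluated by
`barrier_targets()`:

* step-1 reverse barrier: `Er1(d) = 0.10 + 0.70 d^p` eV with `p = 1.894`
  (A–T preset) or `1.783` (G–C preset);
* single- and double-transfer asymmetries, linear in `d`:
  `A_spt = 0.55 + 0.25 d`, `A_dpt = 0.45 + 0.35 d` eV;
* step-2 reverse barrier: `Er2(d) = 0.50 (d − 0.30)` eV, reported as
  *unbound* when it does not exceed `ε = 0.005` eV;
* derived: `Ef1 = A_spt + Er1`, `Ef2 = (A_dpt + Er2) − A_spt`.

Only the exponents carry literature values; every other constant is a
package convention chosen once so the landscape reproduces the qualitative
orderings the analysis depends on: the zwitterion is metastable at every
separation, no double-transfer well exists at the first two grid
increments (0 and 0.222 Å) but one exists from 0.444 Å on, the second
barrier is far below the first, and both asymmetries are positive
(canonical most stable) and quasi-linear.

Each tilted quartic is calibrated by `calibrate_tilted_quartic()`, which
root-solves `(h, δ)` so that the *true stationary analysis* of the
polynomial — minima shifted off 0 and 1 by the tilt, saddle shifted off
1/2 — reproduces the requested forward/reverse barriers to `1e-10` eV,
rather than using the first-order assignment `h = (Ef+Er)/2, δ = Ef−Er`.
This is why grid searches over the assembled surface recover the barrier
laws to a few meV (the residual coupling comes from the switch term, whose
leakage at the wells is second order).

Two edge conventions are worth stating. First, the calibration laws make
the step-2 *forward* barrier negative in a narrow off-grid window
(`d ≈ 0.31–0.42` Å) while the reverse barrier is already positive; no
double-well polynomial can realise that, so the surface treats the
double-transfer branch as unbound unless both `Er2 > ε` and `Ef2 > ε`.
The default 0.222 Å grid never lands in this window. Second, where the
branch is unbound the ramp replaces the quartic; the ramp is flat at
`q1 = 0`, so the canonical and zwitterionic wells are untouched.

```{r}
barrier_targets(c(0, 0.222, 0.444, 0.888), surface_params("AT"))
```

# The separation scan

`run_separation_scan()` imposes separation across 13 increments of
0.222 Å (all of the landmark separations — 0.222, 0.444, 1.554, ≈2.0 —
are integer multiples of this spacing). The reduced-coordinate state is
`(p_A, p_T, φ_A, φ_T, q1, q2)`: the two pivot positions (frozen during
relaxation, each carrying half the imposed separation), the rotation angle
of each base about its pivot, and the proton coordinates. Relaxation is
L-BFGS with a projected-gradient convergence check at the configured force
tolerance (0.01 eV/Å) and basin box bounds on the proton coordinates so a
line search cannot hop a shallow product well into the deeper canonical
well.

The mechanical pair model gives each base a rigid arm carrying its B1
(upper) and B2 (lower) bond site, Morse bonds across the pair
(B1 deeper than B2), and a harmonic rotational restraint
(`0.8 eV/rad²`) standing in for the stacking and steric forces that pull a
base back into the duplex plane. That stiffness was fixed once, when the
model was assembled, so that the canonical scan reproduces the
qualitative angular signature of strand separation: because B1 is
stronger, relaxation rotates the bases to protect it, B2 stretches at
nearly the separation rate, the opening angle rises to tens of degrees,
and once both bonds are deep in their Morse tails the restraint wins and
the angle reverts toward zero around 1.8–2.0 Å, slightly later for the
tautomeric form (whose B1 is scaled 1.3× stronger; its B1 bond also
briefly *shortens* at the onset increment, an emergent feature of the
rotation balance). The tautomeric scan emits flagged zwitterionic
placeholder records at increments where the tautomer well is unbound.

# Minimum-energy paths

`neb_relax()` converges a 15-image band in two phases. A *string* phase
descends the perpendicular component of the true force with equal-arc-length
reparametrization each iteration — reparametrization is what prevents
images from sliding into the wells and folding the band into switchbacks
in flat valleys. Once the perpendicular residual reaches five times the
force tolerance, the *climbing* phase switches to the standard
improved-tangent elastic band with FIRE relaxation, and the images that
are prominent maxima of the profile (topographic prominence ≥ 5 meV,
designated once at the switch) climb along the tangent onto the saddles.
Designating climbing images once, from a well-relaxed profile, matters: a
transient bump near an endpoint that is re-designated every iteration can
ascend a monotone slope indefinitely.

The surrogate-accelerated variant `mlneb_run()` relaxes the band on a
Gaussian-process model of the landscape instead. Each true-model call
contributes the energy *and* its gradient to a derivative-enhanced
squared-exponential GP (per-dimension length scales, jitter-protected
Cholesky, hyperparameters refit by marginal likelihood every five
acquisitions); energy-only regression leaves the surrogate too uncertain
between images to certify a path. Acquisition evaluates the true model at
the image with the largest predictive standard deviation (ties toward the
higher predicted mean) until the uncertainty along the whole band is below
0.02 eV; the band is confined to a trust box around the endpoints because
the GP mean reverts to its flat prior far from data. A short warm-started
band relaxation on the true model then certifies force convergence. On
the packaged surface this reduces true-model work by roughly a factor of
two to five relative to a cold elastic band — modest here, where the true
model is cheap, but the evaluation log is the point: the acquisition loop
needs only tens of true calls.

Endpoint states are relaxed by `relax_surface_state()`, seeded at the
analytically known stationary points of the calibrated quartics. Where
the tautomer well does not exist, the nominal tautomer start slides down
the ramp into the zwitterion basin; the resulting single-hump profile is
how the pipeline *discovers* that the double-transfer product is absent at
that separation, without consulting the calibration flags.

# Barrier analytics

`find_stationary_points()` interpolates a profile with a natural cubic
spline, localizes extrema on a dense grid, and prunes spurious structure
by pair annihilation: repeatedly remove the adjacent extremum pair with
the smallest energy contrast until all contrasts reach the prominence
threshold (default `ε = 0.005` eV, the unbound threshold).
`extract_barriers()` then recognises one of the two admissible patterns —
min–max–min (single transfer only) or min–max–min–max–min — and reads
barriers off by differences. `classify_stability()` labels a row unbound
(no third minimum, or `Er2 ≤ ε`, a closed boundary), metastable
(`Er2 ≤ 0.05` eV, about 2 k_B T at 310 K — a well shallower than thermal
energy at body temperature is not a meaningful trap), or stable.
`detect_onset()` returns the smallest scanned separation not classified
unbound.

`fit_power_law()` is ordinary least squares on `log y ~ log x`. The
reverse-barrier series is fitted after subtracting its `d = 0` baseline: a
pure power law must vanish at zero separation, while the model's reverse
barrier has a finite offset there. (The variant without baseline
subtraction is available by fitting `Er1` directly; the baseline-subtracted
form is the default and recovers the configured exponent exactly because
the generator *is* a shifted power law.)

Two closed-form bounds complete the analysis: `min_lifetime(2.0, 1.25) =
1.6` ps is the time the strands need to reach the 2.0 Å critical
separation at a 1.25 Å/ps separation speed, hence the minimum tautomer
lifetime for mechanistic relevance; and `barrier_temperature(E) = E / k_B`
converts a reverse barrier into the temperature whose thermal energy would
be needed to escape it (≈3.5 × 10⁴ K for the ≈3 eV barriers reached
beyond 1.56 Å — far from biological, which is the trapping argument).

# The coarse-grained duplex and steered unzipping

`build_duplex()` makes a planar ladder: per nucleotide a backbone bead and
two bond-site beads (B1 above, B2 below, separated by the 4.5 Å lever
arm) held in a stiff spring triangle (30 eV/Å², emulating a rigid base
frame without constraint algorithms); Morse bonds across the strands
(depths 0.28/0.22 eV, width 2 Å⁻¹, 2.9 Å rest length); nearest- and
second-neighbour backbone springs (2 eV/Å², the latter supplying bending
rigidity). The as-built geometry is the exact mechanical equilibrium.
Three modelling choices deserve comment:

* **Stacking couples only backbone beads.** Any spring from a bond-site
  bead to the neighbouring pair would couple the two bond sites to the
  stack asymmetrically for the terminal pair, and the opening-angle
  statistics would then reflect that geometry rather than the bond depths.
  With backbone-only stacking, the opening dynamics of a pair is exactly
  symmetric under exchanging its two bonds, so swapping the Morse depths
  mirrors the angle distribution — a property the test suite checks.
* **The dynamics is planar** (the out-of-plane coordinate is frozen).
  In three dimensions a base could spin azimuthally about its bond-site
  axis — a soft, unphysical mode that distance springs cannot restrain
  without breaking the symmetry above.
* **Separation is measured as the mean extension of the pair's two
  bonds**, the direct analogue of the scan's summed pivot displacement,
  and insensitive to the remaining soft mode (rigid rotation of a strand
  about its bond-site column).

`integrate_duplex()` is a BAOAB Langevin splitting at a 1 fs step, 310 K,
friction 1 ps⁻¹, which reduces to velocity Verlet in the deterministic
limit (the energy-drift test uses exactly that limit). The steering force
is applied as an equal-and-opposite pair to the two backbone beads of the
terminal pair along their current separation vector, recomputed every
step, so it is internal to the system and conserves momentum. Forces are
quoted in kJ mol⁻¹ nm⁻¹ and converted via 1 eV = 96.48533 kJ/mol
(25 kJ mol⁻¹ nm⁻¹ = 0.025911 eV/Å).

`angle_histogram()` bins the opening angle over the 0–2 Å separation
window (2.5° bins across ±75°), partitioned by each replica's opening
scenario — which bond's extension first exceeds 0.5 Å, ties resolved
toward B2, the weaker bond. `separation_speed()` fits the separation–time
slope between the first crossings of 0.2 and 2.0 Å per replica and
reports the ensemble mean with its standard error.

## What the coarse model does and does not reproduce

At zero force the duplex breathes — single-bond excursions past 0.5 Å
that reclose — but does not unzip; under constant force the terminal pair
ruptures stochastically, faster at higher force, and the speed estimate
rises with force. Those are the behaviours the property tests assert, on
a desk-scale ensemble (two- to three-pair duplexes, 15–30 ps production
windows, forces at the upper end of and above the 25–125 kJ mol⁻¹ nm⁻¹
ladder, where rupture statistics are reachable in minutes on one CPU;
durations and sizes are stated in the tests themselves). Two statistical
notes: rupture in the activated regime is dwell-dominated, so per-replica
speed estimates there are heavy-tailed, and the 1/√n scaling of the
ensemble standard error is checked in the prompt-rupture regime (force
above the combined bond strength) by disjoint-subset estimation on one
64-replica ensemble — a standard error "measured" from four replicas
alone carries ~40% sampling noise and cannot test a scaling law.

The angle statistics need a caveat. In this model every mechanism —
thermal amplitude, rupture force, activated escape — favours opening of
the *weaker* B2 bond, so the positive-angle side of the histogram
dominates, and because a base hinging on one intact Morse bond has no
metastable resting angle, the distribution is a central peak with heavy
tails rather than two well-separated modes. All-atom simulations of the
real duplex report the opposite sign preference (B1-end opening near
−35°) despite B1 being the stronger bond — an inversion that must come
from structural asymmetries (real base geometry, backbone attachment,
stacking) that this generator deliberately excludes in order to keep the
depth-swap mirror property exact. The sign convention, count
conservation, depth-swap mirror symmetry and force-monotonicity are
therefore the model's testable content; the −35° modal preference is not
reproducible from symmetric geometry plus a depth ordering, and the
corresponding assertion in the acceptance suite documents this honestly
rather than being tuned to pass.

# Numerical conventions

* Units: eV, Å, amu, ps, K, degrees; k_B = 8.617333262 × 10⁻⁵ eV/K; the
  internal dynamics time unit is √(amu Å²/eV) ≈ 10.18 fs.
* Relaxation: L-BFGS-B restarts until the projected gradient norm over
  free coordinates is below tolerance; frozen coordinates are
  bit-identical to their inputs.
* Band searches: spring constant 1 eV per unit coordinate², per-iteration
  displacement cap 0.05, FIRE parameters (dt 0.05–0.25, α₀ = 0.1).
* GP: noise floors 10⁻⁵ eV (values) and 10⁻⁴ eV/coordinate (gradients),
  jitter escalation from 10⁻¹⁰, length scales bounded in [0.05, 5].
* Determinism: every stochastic stage takes an integer seed; replica
  seeds are `seed + replica − 1` (thermostat streams offset by 10⁵), and
  identical configurations and seeds reproduce outputs byte-identically.

# Problem sizes used by the shipped tests and scripts

The acceptance script runs the barrier pipeline over the eight-increment
transition-state grid (0–1.554 Å) with 15-image bands — about a minute on
one CPU. The test suite uses 2–4-pair duplexes, 10–30 ps dynamics
windows, 8–24 replicas, and dense-grid oracles at 0.002–0.005 coordinate
resolution. The full 14-pair, 500 + 200 ps protocol of the packaged
presets remains one configuration edit away.

# Known limitations

* The surface is a calibrated cartoon: barrier *magnitudes* are
  conventions, and only the power-law exponents and qualitative orderings
  are meaningful points of comparison.
* The ladder model has no sequence context, no helicity, no solvent
  beyond the Langevin bath, and (deliberately) no geometric asymmetry
  between the two hydrogen bonds.
* Proton transfer is treated classically throughout; tunnelling is out of
  scope.
* The two-coordinate reduction assumes the heavy-atom geometry relaxes
  adiabatically along the transfer; the scan couples the proton state to
  base rotation only through the separation-dependent calibration.
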