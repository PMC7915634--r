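---
title: "Methods: CCFS retract-curve analysis and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CCFS retract-curve analysis and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfs)
```

## The measurement and the quantity of interest

In cell-cell force spectroscopy (CCFS) a living cell glued to a tipless AFM
cantilever is pressed onto a target cell with a constant approach speed
`v_a` until a setpoint force `F0` is reached, held in contact for a dwell
time `tau` (with the feedback keeping either the force or the piezo height
constant), and then retracted at constant speed `v_r` over a ramp long
enough (80 um here) that the cells fully separate. The retract force trace
shows an adhesion well punctuated by discrete upward force steps — rupture
events — as individual bonds or bond clusters between the cells break, and
ends on a flat near-zero baseline.

The primary readout is the detachment work

    W = -∫ F(z) dz   from Z = 0 to Z = Z_det,   [fJ]

the area between the baseline-subtracted retract force and the axis, from
the point where the trace first crosses the baseline (the Z origin) to the
final rupture (`Z_det`, `F_det`), after which the cells are detached. Units
are fixed package-wide — z in um, F in nN, so W is in fJ — and adhesive
forces are negative, making W positive for adhesive curves.

## The retract-segment algorithm

`analyze_curve()` runs, per curve:

1. **Baseline** (`estimate_baseline`): median force over the furthest 20%
   of samples by z (`tail_fraction`, config-exposed), with a MAD-scaled
   noise estimate. A fixed tail fraction makes "far from the sample"
   reproducible; median/MAD resist stray late ruptures. Windows under 16
   samples are refused.
2. **Z origin** (`find_origin`): the first crossing of the baseline level
   scanning from the contact (minimum separation) end, linearly
   interpolated between the bracketing samples. Scanning in retraction
   order means baseline-hugging noise in the far tail cannot spoof the
   origin. All downstream distances are relative to this point.
3. **Derivative** (`smooth_derivative`): Savitzky-Golay first derivative
   (window 21 samples, order 3 by default; both config-exposed). SG
   derivatives are exact for polynomials up to the filter order, so smooth
   regions contribute ~0 and a force step of height `h` produces a
   derivative peak of roughly `2.8 h / (window · dz)`.
4. **Rupture events** (`detect_discontinuities`): local maxima of the
   signed derivative (ruptures step *up* under the sign convention; an
   absolute-value variant is config-switchable) whose local prominence
   exceeds `prominence_factor · noise_sd / (window · dz)` with
   `prominence_factor = 5` by default. Candidates within one window are
   merged (highest peak wins, leftmost on plateau ties). Each surviving
   candidate is then required to carry a significant force step: the jump
   estimated from half-window flank medians must be positive and exceed
   `prominence_factor` times the standard error of that median difference.
   This second gate matters on long curves: the derivative threshold alone
   sits at only ~2.6 standard deviations of the post-filter derivative
   noise (independently of sampling and noise level), which would admit a
   few spurious peaks per multi-thousand-sample curve. The flank-median
   gate removes those while leaving genuine steps — down to the smallest
   rupture forces the simulator produces — untouched.
5. **Detachment point** (`find_detachment_point`): the last event's z and
   its pre-rupture force relative to baseline.
6. **Work** (`compute_detachment_work`): trapezoidal integral of the
   baseline-subtracted force from Z = 0 to Z_det, with sub-sample linear
   interpolation at both limits. No floor at zero is applied; a negative W
   indicates a curve violating the adhesion assumptions and is visible as
   such.
7. **Summary metrics**: maximum adhesion force (largest baseline-relative
   downward force in the detachment window, reported as a positive
   magnitude) and the event list.

Curves failing any stage (no baseline window, no baseline crossing, no
detected event) are returned *flagged* with the reason, appear in the
results CSV with NA metrics, and are excluded from condition aggregates —
non-detaching curves are protocol failures, since the 80 um ramp is chosen
to guarantee complete detachment. The analysis runs on tip-sample
separation by default; uncorrected curves are bend-corrected first
(`z_tss = z_piezo − F/k`), and raw piezo-distance analysis is available
behind `analysis_params(distance = "piezo")` since it is not documented
which coordinate the original processing used.

## The four work models

`fit_model()` fits condition means (aggregation via
`aggregate_by_condition()`) by Levenberg-Marquardt least squares with
deterministic, documented initialisation (linear-model heuristics per
model) and bounded parameters where a sign is implied:

* **delay**: `W = A + B·tau` — bond number, hence work, proportional to
  time in contact, plus an indentation-phase offset.
* **setpoint**: `W = A + B·F0^(2/3)` — Hertz contact: `F0 ∝ delta^(3/2)`
  inverts to `delta0 ∝ F0^(2/3)`, and `A = pi R delta0` makes the contact
  area, hence the bond number, scale with the 2/3 power of the setpoint.
  The coefficient B is treated as fJ per (force in nN)^(2/3); the
  published unit for this coefficient is ambiguous, so it is fixed here by
  the choice of force unit.
* **approach**: `W = A·tau·B/(B + v_a)` — the effective contact time
  shrinks inversely with approach speed (the hold position is the same at
  every speed) and saturates at the full dwell as `v_a → 0`; B is the
  half-saturation speed. The exact published legend equation for this
  panel is not available in the source text, so this saturating
  inverse-speed form, implementing the verbal description (inverse-speed
  contact time plus a constant contribution), is adopted and isolated
  behind the model registry so alternates can be registered without
  touching the fitter.
* **retract**: `W = A·g·v_r + B·log(1 + v_r/v_ref)` — viscous drag linear
  in pulling speed plus a kinetic (force-assisted bond dissociation) term
  logarithmic in speed. The geometry factor `g = 6·pi·R` (R = 10 um) and
  `v_ref = 1 um/s` are fixed constants so that, as in the published fit,
  only two parameters are free. The same caveat as for the approach model
  applies: the adopted form follows the verbal description.

Fits are to condition means, unweighted by default (matching fits to
displayed averages); `weighting = "inverse_variance"` weights by n/sd² and
drops degenerate groups. No hypothesis tests are performed anywhere: the
delay-mode comparison is descriptive (means with bootstrap percentile CIs),
matching the scope of the original analysis. A free-exponent power-law fit
(`fit_power_law()`) is provided to *check* the 2/3 exponent rather than
assume it.

## What the simulator emulates

`simulation_config()` + `simulate_contact_phase()` + `draw_bond_count()` +
`synthesize_retract_curve()` implement the generative model the analysis
assumes:

* **Contact trajectory**: approach at `v_a` from first contact to the Hertz
  indentation `delta0 = (F0/C)^(2/3)`, `C = (4/3)·E_eff·sqrt(R)` (standard
  sphere-contact prefactor; defaults R = 10 um, E_eff = 1 nN/um² ≈ 1 kPa, a
  soft-cell scale); dwell of `tau`; in-contact retraction. The contact area
  is `S = pi·R·delta` at the instantaneous indentation. In constant-force
  mode S stays at `pi·R·delta0` for the whole dwell; in constant-height
  mode the dwell force relaxes exponentially (time constant 5 s) to 40% of
  the setpoint — a phenomenological stand-in for cell remodelling — and S
  relaxes as `(F/F0)^(2/3)`. This ordering reproduces the observed
  constant-force > constant-height work difference.
* **Bond formation**: `N ~ Poisson(k_on · ∫S(t) dt)`. The rate
  `k_on = 0.218 bonds/(um²·s)` is calibrated so that the simulator's
  expected delay-time response at the baseline condition has the published
  slope of 1.72 fJ/s. (The published delay and setpoint fits are mutually
  inconsistent at the shared baseline condition — they imply ~77 fJ and
  ~5.6 fJ respectively at `tau` = 45 s, `F0` = 1 nN, reflecting
  between-experiment variability — so the generator is calibrated to the
  delay response; of the setpoint response it reproduces the 2/3 exponent,
  not the amplitude.)
* **Retract trace**: each bond loads linearly from the origin and breaks at
  a rupture force drawn from a normal distribution (mean 0.3 nN, sd
  0.1 nN, truncated below at 0.05 nN — single-bond scale chosen for
  realism; no per-event statistics are published) at an extension drawn
  from a shifted exponential (mean 8 um, sd 6 um), producing a discrete
  upward step; a repulsive contact shoulder decays from the end-of-dwell
  force over the indentation depth; a viscous drag force
  `0.005 nN·s/um · v_r` decays over 2 um from contact; Gaussian noise
  (sd 0.01 nN) is added last. An optional Bell-kinetics flag scales the
  mean rupture force with `log(v_r)`. Ground truth records every rupture
  and the work of the noiseless trace, integrated on a 10x oversampled
  grid from its own baseline crossing to the last rupture.
* **Determinism**: per-curve seeds are derived from a master seed by
  (condition index, curve index), so identical seeds give byte-identical
  sweep folders and adding conditions never reshuffles existing curves.
* **Analytic expectation**: `expected_detachment_work()` evaluates E[W] =
  k_on·∫S dt·(E[f]·E[x]/2) + drag work in closed form (quadrature for the
  constant-height dwell integral), and is the generator truth the
  end-to-end recovery tests compare against. Because the constant-height
  dwell relaxes, E[W] is linear in `tau` only beyond a few relaxation
  times; the "true slope" of a delay sweep is therefore defined as the
  ordinary-least-squares slope of E[W] over the same dwell-time grid the
  sweep uses, which is mode-agnostic and exactly what the pipeline's fit
  estimates.

### What the simulator does *not* emulate

Real CCFS curves contain membrane-tether plateaus, power-law viscoelastic
relaxation, drift and multi-scale noise, and adhesion chemistry that varies
across cells and days; the simulator has none of these. It also has, by
construction, a *weak* approach-speed and retract-speed response: bond
formation is dwell-dominated (the approach contributes `delta0/v_a` ≈
tens of ms against a 45 s dwell) and the default drag work (~0.1 fJ at
10 um/s) is small against the bond term, so fits of the approach and
retract models to simulated sweeps are poorly identified — flat responses
with large parameter uncertainties — whereas the published experimental
sweeps show strong trends. Passing end-to-end tests therefore demonstrate
that the pipeline recovers what the generative model puts in (delay slope,
setpoint exponent, per-curve work, event counts and positions), not that
real cells behave like the model. Rupture positions are drawn
independently, so two bonds can break within one filter window and merge
into a single detected event; event-count agreement is asserted on
staircase fixtures and low-bond-count curves with a minimum rupture
spacing (`min_rupture_spacing`), while work recovery — which is insensitive
to merging — is asserted on unconstrained curves.

## Numerical choices and problem sizes

Trapezoidal integration throughout (work, contact-area integral), with
sub-sample interpolation at integration limits. SG defaults 21/3; detection
prominence factor 5; plateau tie-break leftmost; derivative edge regions
(half a window at each end) are excluded from peak search. Sampling default
100 samples/um over the 80 um ramp (8001 samples/curve), down-sampleable.
Fits: Levenberg-Marquardt, ftol = ptol = 1e-14, max 200 iterations.

The test and acceptance workloads use the sweep designs of the emulated
protocol — dwell times {1, 15, 30, 45, 60, 120} s at 50 curves/condition,
setpoints {1, 10, 30} nN at 33/condition, speeds {1, 2.5, 10, 25, 50} um/s —
plus 500-case staircase sweeps (1-10 steps) for detector completeness and
1000 random piecewise-linear polylines against a closed-form area oracle;
unit tests use 50 samples/um to keep individual cases fast.

## Known limitations

Approach-segment contact mechanics (Young's modulus extraction), tether
(worm-like-chain) fitting, JKR/DMT adhesive contact corrections and any
mechanistic model of mechanosensing are out of scope. The ccfs-txt dialect
is this package's own documented format, not the vendor export layout; a
thin adapter is needed before analysing instrument exports. The two
speed-response model forms implement verbal descriptions and may not
coincide with the unpublished legend equations, so their fitted constants
are not comparable to the published ones even on the original data.
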