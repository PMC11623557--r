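---
title: "Frequency-modulated emulation of action potentials and excitable tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-modulated emulation of action potentials and excitable tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmcell)
```

## The model

`fmcell` emulates an action potential (AP) with a single sine generator of
constant amplitude whose frequency is modulated in time — the
voltage-controlled-oscillator view of a cell. A uniformly sampled trace
$v(t)$ (mV, ms grid) is first normalized,

$$y(t) = \frac{v(t) - \mathrm{offset}}{C}, \qquad
C = \tfrac{1}{2}(\max v - \min v), \quad
\mathrm{offset} = \tfrac{1}{2}(\max v + \min v),$$

so that $y \in [-1, 1]$. Writing the carrier as
$y(t) = \sin(\omega t + \varphi + \varphi_t(t))$ with constant carrier
frequency $\omega$ (rad/s, $t$ in seconds) and constant phase $\varphi$,
the varying phase is recovered sample-by-sample by arcsine inversion,

$$\varphi_t(t) = \sin^{-1}(y(t)) - \omega t - \varphi,$$

and converted to a *frequency-modulating factor*
$\Delta_w(t) = \varphi_t(t)/t$, so the AP is reproduced by

$$v(t) = C \sin\big((\omega + \Delta_w(t))\,t + \varphi\big) + \mathrm{offset}.$$

This last expression is evaluated *literally* — the instantaneous deviation
multiplies $t$ directly; it is not the integral of an instantaneous
frequency. The inversion, the quotient and the reconstruction are mutually
consistent under this convention, which makes the chain
`normalize_trace()` → `extract_phase()` → `phase_to_deltaw()` →
`fm_reconstruct()` an *exact* re-parameterization: for any finite trace the
round trip reproduces the input to ~1e-15 relative accuracy (the test suite
asserts RMSE below 1e-8 mV).

### Numerical choices in the transform

* **Arcsine branch.** $\sin^{-1}$ is multivalued; we take the principal
  value per sample and choose, greedily, the branch
  ($\theta$, $\pi - \theta$, each mod $2\pi$) closest to the
  constant-angular-velocity prediction $2\theta_{i-1} - \theta_{i-2}$.
  Choosing nearest the *previous* sample instead would systematically
  reflect the path at every crest, where the reflected branch is always the
  closer one; extrapolating the velocity carries the path through extrema.
  Continuity is the only constraint that makes the inversion well defined.
* **Constant phase $\varphi$.** Defaults to $\sin^{-1}(y(0))$, anchoring
  $\varphi_t(0) = 0$. Any other choice (e.g. $\varphi = 0$) leaves the
  round trip exact but makes $\Delta_w = \varphi_t / t$ diverge like $1/t$
  at the grid origin whenever $y(0) \ne \sin\varphi$, which ruins the
  piecewise-linear compression that is the point of the model. The
  parameter is exposed (`phi0`) for experimentation.
* **Carrier frequency $\omega$.** Defaults to one carrier period per trace
  duration, $2\pi/T$ — the single-sine, mono-component premise. Exposed.
* **The $t = 0$ sample** of $\Delta_w$ uses its right neighbor (the
  one-sided limit of the quotient).
* **Units.** Files and traces use ms/mV; all trigonometry uses seconds and
  rad/s. `ms_to_s()` is the single conversion chokepoint.

### Identifiability, not accuracy, is the limitation

Where the normalized trace sits *at* $\pm 1$ and moves slowly (a plateau
grazing the carrier extremum, or a long flat rest at the minimum), the two
arcsine branches almost coincide and the phase path is not identifiable:
extraction still reproduces the voltage exactly, but it need not return the
same $\Delta_w$ that generated the voltage. Reconstruction error is also
amplified linearly in $t$ (a late-time error $\delta$ in $\Delta_w$
contributes a phase error $t\,\delta$). Two practical consequences:

* compressed-profile reconstruction is most accurate for windows not much
  longer than the AP itself;
* blockade parameterization works best on pacemaker-like traces whose
  diastolic depolarization keeps the signal moving — which is also the
  physiological setting of the blockade axis. The synthetic generators
  default to such shapes for that use.

## Piecewise-linear compression: `pwl_fit()`

The dense $\Delta_w$ array is compressed into $n$ continuous linear
segments with free breakpoints $T_1 < \dots < T_n$ and slopes
$A_1 \dots A_n$; continuity fixes the intercepts through the recurrence
$B_{i+1} = (A_i - A_{i+1}) T_i + B_i$. The model is linear in the slopes
for fixed breakpoints, so `pwl_fit()` profiles the slopes out by linear
least squares and searches only the breakpoint positions:

* breakpoints are parameterized by log-gaps through a softmax, which
  enforces strict ordering without constraints;
* the SSE gradient with respect to a breakpoint follows from the envelope
  theorem, $\partial \mathrm{SSE} / \partial T_j =
  -2 (A_j - A_{j+1}) \sum_{x_i > T_j} r_i$, so each quasi-Newton step
  costs one least-squares solve;
* multi-start: equally spaced, curvature-weighted (quantiles of
  $|\Delta^2 y|$ mass), slope-weighted, greedy knot-insertion, an optional
  warm start (`init`, used to seed an $n{+}1$-segment fit with an
  $n$-segment solution), and seeded random perturbations up to `restarts`
  (default 8, `seed` default 0). Ties within $10^{-12}$ in SSE go to the
  lexicographically smaller breakpoint vector, so results are
  deterministic;
* signals longer than `opt_points` (default 4000) are thinned for the
  breakpoint search only; slopes and all reported metrics are recomputed on
  the full grid.

The first segment passes through the origin by default, preserving the
lookup-table form $A_1 t$ of the compressed profile; since $\Delta_w(0)$
need not vanish, `free_intercept = TRUE` is available and is used wherever
a modulating profile is fitted (the blockade machinery always uses it).
Segment counts are user-chosen (15–31 covers realistic APs; 23 is used for
the sine studies); there is no automatic model selection.

Goodness of fit uses SSE, RMSE $= \sqrt{\mathrm{SSE}/K}$ and $R^2$.
For sine targets the fitted waveform's total harmonic distortion is
computed by Fourier analysis on an integer-period window,
$\mathrm{THD} = \sqrt{\sum_{k \ge 2} V_k^2} / V_1$ with harmonics up to
Nyquist — the square-root (RMS-ratio) convention, which reproduces the
expected magnitude regime (a symmetric triangle wave gives
$\sqrt{\pi^4/96 - 1} \approx 0.121$).

With the one-period, 12000-sample window and 23 segments, the optimal fits
of the tabulated sines give RMSE $\approx 0.066$ mV and THD
$\approx 0.0022$ *independent of frequency* — both scale-free in $\omega$
because the number of segments per period is fixed. Published per-sine
values that grow with frequency imply a frequency-dependent window; absent
a stated window, the one-period convention is used throughout.

## Blockade parameterization

A family of traces indexed by a blockade fraction $b \in [0,1]$ (e.g.
funny-current block in a sinoatrial cell) is modeled in three steps
(`fit_family()`, `fit_fittype()`, `predict_ap()`):

1. every trace is normalized with a *shared* carrier (pooled voltage
   range), and its $\Delta_w$ extracted on the common grid, with the
   reference level's phase path anchoring the branch decisions of every
   other level (`ref_phase` in `extract_phase()`). Without this anchor,
   levels on either side of a grazing carrier crest can resolve the arcsine
   ambiguity onto different branches, which fractures the coefficient
   trajectories; anchoring is valid because a blockade family's phase lead
   over its reference stays well below $\pi$;
2. breakpoints are optimized once on the reference level ($b = 0$) and
   frozen; each level then re-estimates only slopes (one least-squares
   solve), so each slope is a single-valued trajectory $A_i(b)$ — the only
   construction under which per-coefficient trajectories are well defined;
3. each trajectory (plus the first-segment intercept, the carrier
   frequency and phase) is regressed on $b$ with a PL3/PL4/PL5 fit-type: 3,
   4 or 5 *independent* linear pieces with free interior knots. With ~11
   levels the knot placement is solved exactly by exhaustive search over
   contiguous partitions (each piece keeps at least two levels) with
   per-piece ordinary least squares; the reported knot is the intersection
   of adjacent fitted lines when it falls within one level of the
   separating gap, else the gap midpoint. Exhaustive search makes the
   nested-model property (PL5 SSE $\le$ PL4 $\le$ PL3) automatic.

`predict_ap()` evaluates every law at an arbitrary $b$, assembles the
piecewise-linear profile on the frozen breakpoints and plays it through the
carrier.

## The state controller and tissue coupling

A reconstructed cell becomes excitable through a two-state controller
(`fm_cell()`, `step_cell()`, `run_cell()`): at rest it emits `v_rest`;
when its sensed input reaches `v_th` it plays its stored waveform table for
exactly `k` samples, ignoring all input meanwhile (absolute refractoriness
by construction), then rests again. `v_th` defaults to `v_rest` plus 10% of
the waveform amplitude; the threshold, rest level and the at-rest
modulating value are configuration, not hard-coded.

Tissues (`tissue_config()`, `simulate_tissue()`) couple such cells through
the discrete Laplacian with unit mesh — $D(v_{j+1} - 2v_j + v_{j-1})$ on a
chain, the five-point stencil on a grid — under no-flux boundaries (a
missing neighbor contributes the cell's own value, so outward wavefronts
terminate at edges without reflection artifacts). The diffusion term
perturbs a cell's *sensed* voltage and serves to trigger its controller;
during playback the emitted voltage is the stored waveform, not waveform
plus diffusion. This trigger-only semantics is what makes the adjacent
peak-time lag a pure cell property — identical across tissue sizes — and
keeps the played AP shape invariant, the headline tissue behavior. Cells
are numbered row-major (cell 1 top-left, $N^2$ bottom-right). Playback
tables are resampled to the tissue step at configuration time.

Wavefront timing (`wavefront_metrics()`) probes peak times (first sample
attaining the maximum) at cell 1, the central cell and cell $N^2$, their
absolute differences, and the stimulated-to-neighbor lag `T_adj`, which is
verified to agree across all orthogonal neighbors (within half a step)
before being reported. Probes that never fire are reported absent (`NA`).
`find_dmin()` bisects the two-cell propagation predicate to the minimum
diffusion constant supporting cell-to-cell propagation. Lesions
(`apply_dysfunction()`) clamp marked cells 5 mV below rest (configurable);
they never fire but their clamped voltage enters neighbors' Laplacians, so
wavefronts must route around them and distal peak times can only increase.

## Reference models and synthetic data

* **FitzHugh–Nagumo** (two variables) and **Fenton–Karma** (three
  variables) supply ground-truth traces, integrated by fixed-step RK4
  (`deSolve`) at 0.01 ms for determinism. The source study states no
  parameter values, so the package ships documented defaults: the classic
  FHN constants ($a = 0.7$, $b = 0.8$, $\varepsilon = 0.08$) with the time
  scale set so one pulse spans roughly 40 ms, and the published
  three-variable parameter set giving a ~300 ms plateau AP. The FHN
  stimulus is a raised-cosine pulse (smooth, so the integrator keeps its
  convergence order); every constant is overridable. Detailed ionic models
  are deliberately out of scope — their traces enter as two-column text
  files via `read_ap_trace()`.
* **`make_synthetic_ap_family()`** emulates a blockade study: smooth
  AP-like pulses (sigmoidal upstroke, decaying plateau, sigmoidal
  repolarization) on a common grid whose APD follows a stated law in $b$,
  with optional pacemaker-style diastolic depolarization and per-sample
  Gaussian noise, deterministic per seed. It reproduces the *family
  structure* the parameterization assumes (smooth, monotone morphing),
  not any particular ionic model's waveform details; passing tests
  therefore certify the machinery, not fidelity to a specific published
  cell.
* **`make_coefficient_family()`** builds ground truth directly in
  coefficient space: slope trajectories that follow known continuous PL3
  laws (knots 0.3/0.7 by default) plus Gaussian coefficient noise
  (0.5 rad/s default). It exists because trace-space truth is not always
  recoverable — the identifiability caveat above — while coefficient-space
  truth makes slope/knot recovery a sharp oracle.

## Problem sizes and tolerances used by the shipped checks

The test suite exercises: 12000-sample sines with 23 segments; a
~4000-sample FHN trace with 31 segments (delta-w and AP $R^2 \ge 0.999$);
exhaustive-search parity on signals of up to 50 samples with up to 3
segments; an 11-level blockade family on an 801-sample grid with 20
segments (PL5 leave-one-level-out AP $R^2 > 0.99$); tissues of 7×7 to
31×31 cells at 0.1 ms steps with the FHN playback waveform, plus 17×17
lesion runs. Continuity at breakpoints is asserted to 1e-10 relative, the
FM round trip to 1e-8 mV, and controller playback to exact sample
equality. These sizes were chosen to probe each regime the model claims
while keeping a full run of the suite in the minutes range.

## Known limitations

* The literal $(\omega + \Delta_w(t))t$ form ties reconstruction accuracy
  to window length (late-time amplification); multi-component (Fourier
  sum) synthesis and integrated-phase synthesis are non-goals.
* Playback cells have no restitution: the waveform does not adapt to the
  stimulation rate, and re-stimulation during playback is ignored. S1–S2
  pacing protocols are therefore out of scope.
* Tissue coupling is isotropic, homogeneous, 1-D or square 2-D only;
  spiral-wave and re-entry protocols are not provided.
* The fit-type knot search assumes at least two levels per piece; with 11
  levels PL5 is the richest law that can be fitted.
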