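---
title: "Models and methods behind presynq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind presynq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presynq)
```

presynq analyses paired pre/postsynaptic voltage-clamp recordings of the
kind made at the calyx of Held: presynaptic calcium currents and
postsynaptic EPSCs evoked by step depolarizations, plus electron-microscopy
coordinate tables of synaptic vesicles around active zones.  This vignette
explains the models, the parameter choices, and the limits of what the
parameter-recovery tests demonstrate.

## Calcium-channel model

Peak current-voltage relations are fitted with a Hodgkin-Huxley formalism
with four independent activation gates on a Goldman-Hodgkin-Katz (GHK)
open-channel driving force:

$$I(V) \;=\; \Gamma \; V\,
\frac{1-e^{-(V-E_{rev})/25\,\mathrm{mV}}}{1-e^{-V/25\,\mathrm{mV}}}\;
\bigl[1+e^{-(V-V_m)/k_m}\bigr]^{-4}$$

with reversal potential $E_{rev}$, per-gate half-activation $V_m$, slope
$k_m$, and scale $\Gamma$.  Two details are deliberate:

* **The leading $V$ factor.**  The GHK current rectifies through
  $V\,(1-e^{-(V-E_{rev})/25})/(1-e^{-V/25})$; without the $V$ the
  expression has a pole at $V=0$.  `eval_iv_model()` evaluates the $V=0$
  point by its analytic limit, $25\,(1-e^{E_{rev}/25})$, so the curve is
  continuous over the whole working range.
* **The gate sign.**  The gate is the standard Boltzmann
  $[1+e^{-(V-V_m)/k_m}]^{-4}$, the only orientation that produces
  sigmoidal activation together with the conventional parameter signs
  ($V_m \approx -25$ mV, $k_m \approx 7\text{--}8$ mV).

The thermal constant is fixed at 25 mV and never fitted.  `fit_iv()` uses
Levenberg-Marquardt with deterministic multi-start (half-activation of the
normalized gating envelope seeds $V_m$; the extrapolated zero crossing
beyond the current minimum seeds $E_{rev}$; five fixed jitter offsets; the
best residual sum of squares wins).  On noiseless model-generated series
the fit recovers parameters to better than 0.1%; the unbiasedness of the
estimator under additive noise is property-tested over 200 replicates.

Tail currents index activation directly and are fitted with a Boltzmann
function $I_{tail}(V)=I_{base}+I_{min}/(1+e^{-(V-V_{1/2})/k})$ on
magnitudes with $I_{min}>0$ constrained, signs restored on report
(`fit_tail_boltzmann()`).

## Trace metrics

All metrics share the same conventions (`peak_amplitude()`,
`rise_time_10_90()`, `synaptic_delay()`, `integrate_charge()`):

* **Baseline** — mean over the 2 ms immediately preceding the first
  voltage excursion (the pre-pulse, if present).  The source recordings
  define no baseline rule; this is standard practice.
* **Onset** — first time the baseline-subtracted magnitude exceeds 5% of
  the eventual peak after stimulus onset, refined by linear
  interpolation.  5%-of-peak is robust to realistic noise floors.
* **Threshold crossings** (10/90% rise, 50% for synaptic delay) — linear
  interpolation between samples on the rising phase; agreement with a
  dense-resampling brute-force scan is property-tested to within one
  sample interval.
* **Charge** — trapezoidal integral from onset to the last time at least
  10% of the peak remains; if the current never decays that far the
  integral is truncated at the trace end and flagged.
* **Signs** — inward currents are stored negative; reported amplitudes
  and charges are positive magnitudes.

Offline series-resistance compensation (`compensate_rs_offline()`) is the
first-order single-compartment correction: rescaling by the driving-force
ratio $(V_h-E_{rev})/(V_h-E_{rev}-IR_s)$ plus the capacitive term
$C_m\,d(IR_s)/dt$.  The contract tested is the round trip: an EPSC
distorted by a forward $R_s$ model (5 M$\Omega$) and then compensated
recovers the undistorted peak within 3%.  Higher-order corrections in
published offline routines are not reproduced; only the "output as if
$R_s=0$" contract is asserted.

`lowpass_filter()` is a zero-phase 4-pole Bessel low-pass (hard-coded
analog prototype poles, bilinear transform with frequency pre-warping,
forward-backward application with edge-replicate padding), emulating the
6 kHz bandwidth of the recording chain.

## Release model and EPSC rendering

The generator uses a two-pool depletion model.  During release (from step
onset plus a latency until step end):

$$\xi(t)=\frac{N_f(t)}{\tau_f}+\frac{N_s(t)}{\tau_s},\qquad
\dot N_f=-\frac{N_f}{\tau_f},\qquad
\dot N_s=-\frac{N_s}{\tau_s}+r$$

with constant refilling $r = 10$ SV/ms into the slow pool (refilling into
the slow pool is a convention; the downstream correction is
pool-agnostic).  The solution is evaluated in closed form — no ODE solver
— and the stored rate samples are interval averages of the analytic
cumulative, so cumulative summation on the grid reproduces the closed
form exactly at sample boundaries.

EPSCs are rendered by convolving $\xi$ with a quantal kernel: a
bi-exponential mEPSC of unit peak scaled to $q$ ($\tau_{rise}=0.2$ ms,
$\tau_{decay}=1$ ms) plus a residual-current pathway for delayed
glutamate clearance (each vesicle adds one unit to a residual state with
$\tau_{clear}=40$ ms that contributes $0.05\,q$ pA per unit).  The
residual scales with $q$ because it is carried by the same receptors;
this keeps the kernel linear in the quantal size.  Rendering uses the
exact sum-of-exponentials state recursion, so the output is strictly
causal and linear.

## Preset calibration

`make_preset()` encodes group-level targets.  Channel parameters
($V_m, k_m, V_{1/2}, k$, maximal current) are the group means; $\Gamma$
is solved so the true I(V) extremum magnitude equals the group's maximal
current.  Pool parameters are calibrated rather than copied: with a
two-pool model the measured 3 ms cumulative release necessarily contains
slow-pool and refill contributions, so the initial pool sizes
$(N_{f0}, N_{s0})$ are obtained from a 2-by-2 linear system such that
the *observables* hit the group values exactly — the 3 ms cumulative
equals the fast-pool (RRP) target and the refill-corrected 30 ms
cumulative equals the total-pool target.  The remaining generator
constants were chosen once, for calyx-like behaviour, and are not
fitting targets: activation $\tau_{act}=0.3$ ms; control kinetics
$\tau_f=0.6$ ms, $\tau_s=25$ ms, latency 1 ms; mutant kinetics
$\tau_f=1.5$ ms, $\tau_s=30$ ms, latency 1.5 ms; presynaptic noise SD
5 pA and postsynaptic 20 pA (added before the 6 kHz filter).  The
quantal size $q$ is calibrated once so the noiseless control 3 ms EPSC
peak equals the control group's mean amplitude, and is shared by all
groups (quantal size is a postsynaptic property).

## Deconvolution

`deconvolve()` inverts the linear causal model EPSC $= K\xi$ where $K$ is
the lower-triangular convolution operator of the joint kernel (mEPSC +
residual pathway).  Embedding the residual in the kernel is equivalent to
the classical formulation that first estimates and subtracts the residual
current and then deconvolves the remainder.

Numerical design: point-sampling the kernel on the grid makes the
discrete system non-minimum-phase (its leading sample carries only the
residual weight) and forward substitution then amplifies round-off
astronomically, even though the *continuous* kernel is minimum phase
(transfer-function zeros at about $-0.06$ and $-125\ \mathrm{ms}^{-1}$).
The package therefore discretizes the kernel by interval averaging
(zero-order hold), shared exactly between renderer and solver; forward
substitution is then stable and exact to $10^{-9}$.  Because the kernel
is a sum of three exponentials, the triangular solve collapses to an
O(n) state recursion; the literal dense solve is retained
(`dense = TRUE`) and tested for agreement.

Options: a greedy per-sample non-negativity clamp (off by default — under
noise, rectification would bias the integral upward), and a ridge
smoother on second differences applied to the recovered rate
(`smoothing_lambda`, default 0).  The joint ridge
$(K^\top K+\lambda D^\top D)$ would be dense and cubic in trace length at
50 kHz; the post-solve smoother preserves the noiseless contracts.

Pools: the fast pool (operational RRP) is the cumulative release 3 ms
after the onset of the release-triggering 0 mV step, uncorrected; the
total releasable pool is the 30 ms cumulative minus $10\ \mathrm{SV/ms}
\times 30\ \mathrm{ms}$.  The refill correction is applied only to the
30 ms measurement.  The 3 ms/30 ms ratio reported by
`build_pool_report()` is the *amplitude* ratio of the peak EPSCs (the
table it mirrors is labelled an EPSC ratio); pool-integral ratios can be
formed from the same report.

Kernel mismatch sensitivity is approximately reciprocal: a +10% error in
$q$ produces pools low by about 1/1.1 (tested).

## EM morphometry

Active zones are straight segments per section profile; vesicle-membrane
distance is the **edge distance**: centre-to-segment (capsule) distance
minus the vesicle radius, floored at zero.  Edge distance makes the
"< 5 nm = docked" criterion physically meaningful for ~40 nm vesicles;
whether published distance-map workflows were centre- or edge-referenced
is not decidable from their descriptions, so this is recorded as a
convention, and the generator uses the same one (recovery tests are
convention-consistent).  Distances are binned in half-open 5 nm bins
$[0,5),\dots,[195,200)$; the first bin is the docked count.  A second,
rasterized path (1 nm/px Euclidean distance transform of the stamped
segment, sampled at vesicle centres) mirrors image-based workflows and
must agree with the exact geometry within $\sqrt 2$ px — this is the
cross-check, not the primary path.

EM presets: AZ length Normal (truncated above 50 nm) with the group mean
and an SD consistent with the group SEM at its n; docked count Poisson
with the group mean and Uniform(0, 5 nm) edge distances; background
vesicles at 2.5·10⁻⁴ vesicles per nm of AZ per nm of depth in the
5–200 nm band (chosen once to give a realistic ~13 vesicles per AZ
profile); vesicle radius 20 nm.

## Statistics

`check_assumptions()` (Shapiro-Wilk per group, Bartlett across groups),
`anova_dunnett()` (one-way ANOVA, then Dunnett's many-to-one comparisons
with single-step family-wise adjustment via multcomp/mvtnorm), and
`ttest_unpaired()` (classical equal-variance t, the form implied by a
preceding Bartlett check).  Operating characteristics are
simulation-tested: family-wise type-I error of the Dunnett family is at
or below 0.05 within Monte-Carlo error over 2000 null replicates (4
groups, n = 10), Shapiro-Wilk p-values are uniform under the null, and
both Bartlett and the t-test reject at the nominal rate.

## What the recovery tests do and do not show

The generator shares its forward model with the analysis (matched mEPSC
kernel, same residual model, rate-based release).  Recovery therefore
validates *inversion correctness, calibration, and plumbing* — not the
fidelity of the kernel to any particular synapse.  Features of real data
deliberately not emulated: stochastic vesicle-by-vesicle (binomial)
release; calcium-dependence of release rates on the simulated calcium
current; receptor saturation/desensitization (experimentally blocked in
the source preparation); mEPSC template estimation from noise recordings;
AZ curvature and 3-D reconstruction.  One visible consequence: a pure
depletion model has a monotonically decreasing release rate, so both the
3 ms and 30 ms EPSCs peak early and the mutant 3 ms/30 ms amplitude
ratios fall only slightly below 1, not to the ~0.5 seen with genuinely
slowed coupling; the control-group ratio (≈ 1.0) is the quantity used
for recovery.

## Problem sizes and determinism

Default traces are sampled at 50 kHz (dt = 0.02 ms): ~750 samples for the
3 ms protocol, ~2100 for the 30 ms protocol.  Monte-Carlo property tests
use 200 replicates for fit unbiasedness, 50 seeded replicates for the
noisy round trip, 2000 for the Dunnett family-wise error, and 120 AZ
fields per EM group (matching the group n).  Every stochastic stage
takes an explicit integer seed; `run_paper_suite()` derives all stage
seeds from the manifest seed, and re-running a manifest reproduces the
report byte-for-byte.
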