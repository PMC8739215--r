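---
title: "Seizure transition dynamics in a thalamocortical neural mass model with excitatory interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure transition dynamics in a thalamocortical neural mass model with excitatory interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmass)
```

## The model

`tcmass` implements a six-population neural mass model of the
thalamocortical loop.  The cortical module contains pyramidal neurons
(PY), spiny stellate cells — glutamatergic *excitatory interneurons*
(EI) — and fast and slow GABAergic interneurons (I1, I2, standing for
GABA~A~- and GABA~B~-type inhibition).  The thalamic module contains the
excitatory relay nucleus (TC) and the inhibitory reticular nucleus (RE).
Each population is described by one mean potential governed by

$$\dot x_i \;=\; \tau_i\Big(h_i - x_i + \textstyle\sum_j \pm\, c_{j\_i}
f(x_j)\Big) \;[+\,N],$$

where $f(x) = 1/(1+\varepsilon^{-x})$ is the logistic firing-rate transfer
function ($\varepsilon = 2.5\times10^5$), $h_i$ a constant input offset,
$\tau_i$ a time scale in 1/s, and the signs follow the receptor type of
each projection (glutamatergic $+$, GABAergic $-$).  The pyramidal
equation receives the cortical input
$N_{py} = B_{N_{py}} + a_{py}\sin(2\pi f_{py} t)$ and the relay nucleus
the sensory input $N_{tc} = B_{N_{tc}} + a_{tc}\sin(2\pi f_{tc} t)$; both
are added outside the $\tau$ multiplier, exactly as the model is defined.
The observable is the cortical mean $(PY+I1+I2+EI)/4$, the model's
EEG-like output.

The couplings are named `c_SOURCE_TARGET`.  The three couplings into EI
are the scientific focus of the toolkit: `c_py_ei` (glutamatergic
excitation from PY), `c_i1_ei` (GABAergic inhibition from I1) and
`c_tc_ei` (thalamic drive).  Their baseline values are 0.8, 0.3 and 4.5;
all remaining defaults are the published reference parameterization and
are returned by `model_parameters()`.

An *ablation variant* (`ei_enabled = FALSE`) freezes EI at zero, drops
every projection from EI, and averages the output over the three
remaining cortical populations.  The circuit definition does not
prescribe an ablation; this is the minimal construction that removes the
population without touching anything else, and it is what the
EI-contrast analysis below uses.

## Simulation protocol

Trajectories are integrated with the classic fixed-step fourth-order
Runge–Kutta scheme at `dt = 0.0039` s over 60 s windows, the protocol
under which all reference results were obtained.  The integrator is
implemented in C++ and is strictly deterministic — identical inputs give
bit-identical output, which the test suite asserts.  A divergence guard
aborts when any potential exceeds $10^6$ model units; sweep engines
record such grid points as missing instead of failing.  The default
initial state is the origin: the model definition does not state an
initial condition, and a fixed, parameter-independent default keeps every
analysis reproducible.  Sweep engines override it with attractor
inheritance (below).

Steady-state analysis uses the trailing 2 s of the output (512 samples),
from which three kinds of features are extracted:

* the **dominant frequency** (DF), the maximum-power bin of the
  mean-removed FFT periodogram over positive frequencies (0.5 Hz
  resolution at the 2 s window, no taper);
* the **ranked local extrema**: the largest and smallest local maxima
  (`Pmax1`, `Pmax2`) and minima (`Pmin1`, `Pmin2`), with extrema defined
  by strict sign changes of the first difference, and extremum *levels*
  counted after single-linkage clustering with tolerance $10^{-3}$;
* the **peak-to-peak amplitude** and window mean.

A window whose peak-to-peak amplitude is below $10^{-3}$ model units is
treated as non-oscillatory (DF set to 0, extrema marked absent).  The
reference analysis implies such a rule — fixed-point regimes are reported
at DF = 0 — without stating the threshold; $10^{-3}$ sits two orders of
magnitude below the smallest genuine limit cycles of interest and two
above the trailing numerical transients of 60 s runs.

```{r}
r <- simulate_model(model_parameters(c_i1_ei = 0.4))
compute_features(r)
```

## Classifying activity regimes

The model produces seven qualitatively distinct activities: normal
background firing, preictal spikes, slow rhythmic activity, typical and
atypical absence seizures, clonic and tonic seizures.  `classify_state()`
maps a feature set to one of these labels through precedence-ordered
rules (see its help page for the exact table).

The published characterization of the seven signal classes was measured
on simulated waveforms that still carried transient envelope modulation,
so it distinguishes e.g. clonic from preictal partly through the spread
of the local maxima.  Under this package's fully converged attractors
that spread collapses to numerical noise ($\sim10^{-4}$): a clonic or
tonic cycle has a *single* maximum level.  The rules therefore
operationalize the same regime definitions with the discriminations that
survive exact convergence:

* **tonic** — fast spiking, DF ≥ 14 Hz, single minimum level;
* **normal** vs **slow rhythmic** — both fixed points; separated by the
  resting output level (slow rhythmic is the depressed stable focus,
  mean output in $(-0.8, -0.1)$, per the published level range);
* **preictal** — *low-amplitude* spiking (peak-to-peak < 0.15, maxima
  spread < 0.12) below 3.5 Hz; this covers both the small cycle born at
  the supercritical Hopf point and the characteristic two-amplitude
  pattern after the first period doubling;
* **typical absence** — spike-and-wave discharges: two separated minimum
  levels (spread > 0.004) at 2–4 Hz;
* **atypical absence** — the same structure outside 2–4 Hz;
* **clonic** — large simple slow-wave cycling at 2–7 Hz (the wider
  frequency bound follows the published state-map legend), tested after
  the absence rules so spike-and-wave structure takes precedence.

The classifier is total: anything else is `unclassified`.  The
randomized-feature tests assert totality, and end-to-end tests assert
that simulations inside each regime of the bifurcation diagrams receive
the regime's label.

## Equilibria and Hopf bifurcations

`find_equilibria()` locates fixed points of the constant-input model by
damped Newton iteration from a deterministic grid of $3^6+1$ starts over
$[-4,2]^6$, deduplicated at $10^{-6}$; each solution is reported with the
eigenvalues of the analytic Jacobian (assembled from
$f'(x) = \ln\varepsilon\, f(1-f)$) and a stability class.  The default
configuration has three equilibria; the *cortically active* one (the
branch with PY highest) is the branch along which all transition
dynamics unfold.

`locate_hopf()` follows that branch across a parameter interval by
warm-started Newton continuation and bisects the zero crossing of the
real part of the leading complex-conjugate eigenvalue pair to $10^{-4}$.
Two numerical choices matter:

* **Fold re-acquisition.**  Near `c_i1_ei` ≈ 0.3455 the tracked branch
  passes through a narrow pair of folds before the Hopf point at
  ≈ 0.3491.  A plain warm start loses the branch there; the continuation
  retries from deterministically perturbed starts and accepts the
  nearest solution, which lands on the reconnecting segment.  Without
  this the first Hopf point of the inhibition sweep is unreachable.
* **Hopf type** is read empirically from simulation (cycle amplitude
  growth past the crossing), not from a first Lyapunov coefficient; the
  reference analysis interprets its diagrams the same way, and the
  normal-form computation would add nothing the tests could check
  independently.

```{r, eval = FALSE}
locate_hopf(model_parameters(), "c_i1_ei", 0.2, 0.45)   # ~0.3491
```

## Bifurcation sweeps, period doubling and bistability

`sweep_1d()` simulates 60 s per grid point.  With *attractor
inheritance* (default) each run starts from the previous end state, so
the sweep follows one attractor through coexistence regions; running the
same grid in both directions and comparing the reached attractors
(`detect_bistable_windows()`) exposes hysteresis, whose edges approximate
the fold-limit-cycle and subcritical-Hopf boundaries.  Two attractors
count as different when their clustered extremum-level sets differ by
more than 0.02 model units — the coexisting spike-wave branches differ by
≥ 0.04 while numerical jitter stays below $10^{-3}$.  A cold-start mode
(`inherit = FALSE`) restarts every point from a fixed state instead.

Period-doubling events are read off the waveform, as in the reference
diagrams: a doubling of the number of distinct maximum levels (1→2 or
2→4) between adjacent oscillatory grid points places an event at the
interval midpoint.  No Floquet analysis is performed (out of scope, as is
continuation of unstable cycle branches).

The default grid resolution is 0.002 in the cortical couplings and 0.02
for `c_tc_re`, fine enough to resolve every printed event location at its
2–3 significant digits.

`map_2d()` classifies the attractor reached from the origin on a grid of
$(c_{py\_ei}, c_{i1\_ei})$ cells at fixed `c_tc_ei` (default 40×40 over
$[0.1,0.9]\times[0.2,0.9]$; the reference maps' grid density is
unstated).  On the baseline map all seven regimes appear, arranged in
the published diagonal banding.

## Frequency response

`frequency_sweep()` drives one input channel with a sinusoid of
amplitude 0.02 (the reference stimulation amplitude; only the silenced
channel's amplitude is stated in the original protocol, so the driven
amplitude is recorded here as an assumption) across a frequency grid,
with optional inheritance across frequencies and a 0.01 Hz refinement
pass around the amplitude peak (the reference protocol uses 0.01 Hz
everywhere; refinement keeps the runtime at desk scale without losing
peak resolution).

One measurement subtlety is promoted to an explicit option.  The
steady-state swing of a response to a drive slower than 0.5 Hz is not
visible in a fixed 2 s window: the window covers less than one drive
period and its measured amplitude *phase-beats* with frequency.  The
default `window_mode = "drive_period"` therefore widens the analysis
window to at least one full drive period; `window_mode = "fixed"`
reproduces the literal last-2-s reading.  Under the physical measurement
the interictal cortical response is a monotone low-pass curve; the
historically reported low-frequency "resonance" near 0.2 Hz only arises
from the fixed-window beating, and reproducing that number requires
`window_mode = "fixed"` (the acceptance protocol does exactly that, and
still lands at ≈ 0.35 Hz rather than 0.2 — the beating pattern depends
on integrator phase details that are not recoverable from the published
description).

`detect_resonance()` reports prominent local maxima of the lightly
smoothed amplitude curve (including boundary maxima, so a pure low-pass
yields its low-frequency edge).  `detect_jumps()` flags adjacent-point
amplitude differences exceeding 5× the median adjacent difference — the
amplitude-jump signature of non-linear resonance.  The near-onset state
(`c_py_ei = 0.748`) shows such a jump in the cortical channel, and the
linearity tests confirm the published qualitative contrast: the
interictal state responds proportionally to drive amplitude, the
near-onset state does not.  The *location* of the cortical jump is
knife-edge sensitive: it moves across 0.8–1.8 Hz as `c_py_ei` varies by
0.008 around the Hopf point and with drive amplitude between 0.02 and
0.05.  This package's model, whose first Hopf point of the
glutamatergic sweep sits at 0.7475 (published: "∼0.74"), jumps at
≈ 1.29 Hz at the printed configuration; the published ≈ 1.7 Hz would
correspond to a base state a few 10⁻⁴ closer to the bifurcation.  The
sensory-channel jump near 4 Hz is robust and reproduced.

A frequency band is flagged *chaotic* when the trailing window is
aperiodic at the drive period (autocorrelation at one drive-period lag
below 0.9).  This is a proxy; Lyapunov exponents are out of scope.

`state_switch_protocol()` runs the published state-transition
experiment: `c_py_ei` follows a piecewise-constant schedule
(0.76 → 0.748 → 0.76 by default) under a fixed 1 Hz drive, with state and
drive-phase continuity across epochs.  The reversible amplitude
excursion of the middle epoch is reproduced; its label at the printed
parameter is preictal rather than full absence, consistent with the Hopf
offset discussed above.

## What the tests do and do not show

The synthetic fixtures (`generate_fixtures()`) — sinusoids, alternating
two-amplitude spike trains, trough-alternating spike-wave proxies, damped
oscillations at a depressed level — exercise the feature extractor and
classifier against constructions with known ground truth.  They emulate
waveform *shapes* of the model's regimes, not EEG: no measurement noise,
no nonstationarity, no artifacts.  Passing them validates the analysis
pipeline's arithmetic, not clinical applicability; classification of real
recordings is explicitly out of scope.

Reported problem sizes are the package's working defaults: 60 s
simulations, sweep grids of 60–350 points, 40×40 maps, frequency grids
of 100–200 points with local refinement.  All are chosen to resolve the
published 2–3-digit event locations; the full test suite runs in a few
minutes on one CPU.

## Known limitations

* Unstable limit-cycle branches are not continued; bistable windows are
  localized by forward/backward hysteresis instead, so window edges carry
  the sweep's grid resolution (±0.002 by default), not continuation
  accuracy.
* The 2 s feature window limits DF resolution to 0.5 Hz; regime
  boundaries quoted at finer resolution (e.g. the 3.5 Hz preictal bound)
  inherit that quantization.
* The atypical-absence area trend across decreasing `c_tc_ei`
  (4.5 → 4 → 3.5) is not reproduced: in this implementation the tonic
  region absorbs the whole mid-frequency band (cells with DF in
  [4, 14) Hz drop from 146 to 70 across the three maps) and the
  atypical-absence count *decreases* (75 → 57 → 39), while the other six
  regime-area trends, including the growth of the tonic region, match
  the published maps.  The acceptance test states the published trend
  and records the failure rather than weakening it.
* Stochastic inputs, conductance-based dynamics and adaptive-step
  integration are non-goals.
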