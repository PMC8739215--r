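# tcmass

Simulation and bifurcation analysis of a thalamocortical neural mass
model with an excitatory-interneuron (spiny stellate) population, built
to study how cortical excitatory interneurons shape the transition from
normal brain activity to epileptic seizures.

## The model

Six neural populations — pyramidal (PY), excitatory interneurons (EI),
fast and slow inhibitory interneurons (I1, I2), thalamic relay (TC) and
thalamic reticular (RE) — evolve as coupled mean potentials

```
dPY/dt = tau1 (h_py − PY + c_py_py f(PY) − c_i1_py f(I1) + c_tc_py f(TC)
                − c_i2_py f(I2) + c_ei_py f(EI)) + N_py
...
dRE/dt = tau6 (h_re − RE + c_py_re f(PY) − c_re_re f(RE) + c_tc_re f(TC))
```

with logistic transfer `f(x) = 1/(1 + eps^−x)` (`eps = 250000`),
sinusoidal cortical/sensory drives
`N = B + a sin(2 pi f t)`, and EEG-like output `(PY + I1 + I2 + EI)/4`.
Depending on the couplings into EI — glutamatergic `c_py_ei`, GABAergic
`c_i1_ei`, thalamic `c_tc_ei` — the output reproduces seven activity
regimes: normal background, preictal spikes, slow rhythmic activity,
typical/atypical absence, clonic and tonic seizures.

The toolkit provides:

* a deterministic fixed-step RK4 simulator (C++ core, 60 s / 0.0039 s
  protocol) with drives, divergence guard and CSV export;
* feature extraction from the trailing window: dominant frequency,
  ranked local extrema, amplitude;
* a total rule-based classifier for the seven regimes;
* equilibrium search (multi-start damped Newton), analytic Jacobian,
  and Hopf localization by eigenvalue bisection with fold-tolerant
  branch continuation;
* 1D bifurcation sweeps with attractor inheritance, period-doubling
  detection and forward/backward hysteresis (bistability) windows;
* 2D state maps over the `(c_py_ei, c_i1_ei)` plane;
* frequency-response analysis with resonance, amplitude-jump and
  aperiodicity detection, plus the state-switch stimulation protocol.

## Worked example

Raising the GABAergic inhibition of the excitatory interneurons
destabilizes the resting state and walks the cortex through the full
seizure repertoire:

```r
library(tcmass)

p <- model_parameters()               # baseline: c_py_ei 0.8, c_i1_ei 0.3
locate_hopf(p, "c_i1_ei", 0.2, 0.45)
#> [1] 0.3491211        # seizure onset: supercritical Hopf point

bd <- sweep_1d(p, "c_i1_ei", seq(0.2, 0.9, by = 0.002))
subset(bd$events, type == "period_doubling")[1, ]
#>              type location direction
#> 4 period_doubling    0.355   forward   # preictal two-amplitude spikes

r <- simulate_model(model_parameters(c_i1_ei = 0.55))
as.character(classify_state(compute_features(r)))
#> [1] "typical_absence"   # ~3.5 Hz spike-and-wave discharge
```

The Hopf point at `c_i1_ei ≈ 0.349` marks the interictal-to-ictal
transition; the period doubling at `≈ 0.355` creates the two-amplitude
preictal spike pattern; inside the bistable window (lower edge
`≈ 0.459`, found by `detect_bistable_windows()` on a forward/backward
sweep pair) large- and small-amplitude spike-wave discharges coexist.
With the EI population ablated (`model_parameters(ei_enabled = FALSE)`),
no preictal interval follows oscillation onset — seizures start
abruptly, which is the model's core claim about spiny stellate cells.

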