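# gaintrack

Neural mass modelling and unscented Kalman tracking of inhibitory synaptic
gain from wide-bandwidth electrophysiology.

## The problem

DC-coupled recording technologies (e.g. graphene transistor arrays) retain
the ultraslow potential shifts and infraslow oscillations (0.01–0.1 Hz)
that conventional AC-coupled clinical amplifiers discard above ~0.3 Hz.
During seizures, those infraslow components can carry the signature of the
underlying synaptic change. `gaintrack` is for computational
neuroscientists and methods developers who want to quantify — in a fully
simulated, ground-truth-available setting — how much the infraslow band
matters when synaptic physiology is inferred from a recording with a
model-based state estimator.

## The model and the estimator

The core is the three-population Jansen–Rit neural mass model. Each
population converts mean membrane potential to firing rate through a
sigmoid σ(v) = e₀ / (1 + exp(−ρ(v − v_th))) and firing rate back to
potential through a second-order synaptic kernel h(t) = a·r·t·exp(−r·t)
with gain *a* (mV) and inverse time constant *r* (s⁻¹). The observed
output is the pyramidal membrane potential V = x_ex − x_i.

Seizure transitions are generated by promoting the inhibitory gain A_i to
a slow state,

    dA_i/dt = ε(−α A_i + β σ(V) + n(t)),   ε = 0.1, α = 0.06, β = 5,

so gain excursions reshape both the oscillatory regime (seizure-like
discharges at low inhibition) and the DC baseline of V — shift and seizure
share one mechanism.

A continuous–discrete unscented Kalman filter tracks the 7-dimensional
augmented state (six model states + A_i) from a single observed trace:
sigma points propagated through the deterministic drift between samples,
exact linear measurement update (H = [0 0 1 0 −1 0 0]) at each sample.
The filter is certified against a closed-form Kalman filter on a linear
fixture to 1e−8.

## Worked example

Alpha rhythm from the canonical parameter set:

```r
library(gaintrack)
sim <- integrate_nmm(nmm_preset("alpha", c = 135),
                     simulation_config(duration = 30, seed = 1),
                     burn_in = 5)
spectral_peak(power_spectrum(sim$trace, window_s = 4), 1, 50)
#> [1] 11
```

11 Hz: the model's alpha peak at connectivity C = 135. The four-condition
experiment — two synthetic seizure recordings (without / with a DC shift),
each tracked wideband and after a 0.3 Hz high-pass:

```r
report <- run_experiment(experiment_config(seed = 1))
print(report)
#> <experiment_report>
#>   seed 1, endogenous DC-shift mechanism, 300 s recordings
#>   no-shift:  wideband vs high-pass track r = 1.000
#>   DC shift:  wideband vs high-pass track r = -0.912
#>   shift-window slopes (mV/s): wideband +0.051, high-pass -0.011
#>   truth recovery noshift_wideband r = -0.986  rmse = 1.13 mV
#>   truth recovery noshift_highpass r = -0.982  rmse = 11.75 mV
#>   truth recovery shift_wideband   r = +0.949  rmse = 1.52 mV
#>   truth recovery shift_highpass   r = -0.982  rmse = 11.75 mV
#>   verdict: tracks DIVERGE when a DC shift is present
```

Reading the numbers: when the recording carries no DC shift, the wideband
and high-pass gain tracks are interchangeable (r = 1.000). When the
recording carries a DC shift, the two tracks anti-correlate (r = −0.912):
the wideband track follows the true gain trajectory (r = +0.949 against
ground truth, rising during the post-ictal recovery at +0.051 mV/s), while
the high-pass track moves confidently in the *opposite* direction
(r = −0.982, falling). Discarding the infraslow band does not add noise —
it produces a well-behaved estimate that is wrong about the direction of
the synaptic change.

`plot(report)` draws the recordings and the three gain trajectories
(wideband track, high-pass track, ground truth) per scenario. A thin
command-line front end with `simulate`, `condition`, `track`,
`experiment`, and `report` verbs is installed at
`inst/scripts/gaintrack-cli`.

## Scope

Single cortical column, single observed channel, single tracked parameter
(joint multi-parameter tracking from one channel is ill-posed and
deliberately out of scope). The synthetic generator emulates the
statistical structure of DC-coupled seizure recordings — baseline
oscillation, paroxysmal discharges, infraslow shift, post-ictal
suppression, sensor noise — not electrode physics or artifacts. See the
methods vignette (`vignettes/gaintrack-methods.Rmd`) for the model,
numerical conventions, and design decisions in full.
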