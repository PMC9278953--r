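---
title: "Modeling Kv3 activation-voltage shifts in fast-spiking PV interneurons and a reduced cortical circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Kv3 activation-voltage shifts in fast-spiking PV interneurons and a reduced cortical circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kv3net)
```

## The scientific question

Parvalbumin-expressing (PV) fast-spiking interneurons deliver the fast
perisomatic inhibition that keeps cortical circuits stable and paces
gamma-band oscillations.  Their signature firing style — sub-millisecond
action potentials at hundreds of Hz without adaptation — depends on Kv3
family potassium channels, which activate at depolarized potentials with
sub-millisecond kinetics.  A hyperpolarizing shift of the Kv3 activation
voltage (as observed in young amyloid-model mice) lets the channel open
in the subthreshold range, where it acts as a leak that specifically
suppresses firing near rheobase while leaving the high-frequency end of
the input–output curve intact.  `kv3net` implements this hypothesis as a
tested simulation pipeline: channel gating, a calibrated PV cell model,
voltage-clamp and current-clamp protocols, an in-silico dynamic clamp, a
220-cell recurrent circuit with an LFP proxy, and the curve-fitting
stages used to analyze both synthetic and simulated data.

## Channel mechanisms

The Kv3 conductance has one activation gate (m) and one slow inactivation
gate (h):

$$ m_\infty(v) = 1 - \frac{1}{1 + e^{(v + 5 + s)/12}}, \qquad
   h_\infty(v) = \frac{1}{1 + e^{(v + 30 + s)/10}}, $$

$$ \tau_m(v) = 0.5 + 4\,e^{-\tfrac12\left((v + s + 25)/25\right)^2}
   \cdot \text{scale} \;\text{ms}, \qquad \tau_h = 1000 \text{ ms (default)}. $$

Here $s$ is the internal voltage-shift term.  The public interface works
in terms of `delta_shift`, the change of the half-activation voltage
(negative = hyperpolarizing), with $s = -\texttt{delta\_shift}$, so that
`delta_shift = -10` moves the half-activation from $-5$ mV to $-15$ mV —
the convention in which experimental shifts are reported.  Two details of
$\tau_m$ were genuinely open and are package decisions: the Gaussian
width (25 mV, chosen to give a smooth bell peaking at 4.5 ms at
$-25$ mV) and the placement of the kinetic scale factor, which by default
multiplies the Gaussian term only (`parse = "gaussian"`); the alternative
(`"whole"`) is selectable and both coincide at `scale = 1`.

The sodium channel is the classic squid-axon Hodgkin–Huxley mechanism
($m^3h$) with two knobs: a rigid voltage shift of both curves and a
multiplicative kinetic scale.  The PV default `na_kin_scale = 0.10`
accelerates the rates tenfold, standing in for the very fast Na kinetics
of fast-spiking interneurons; with slower Na kinetics the spike
downstroke acquires a sodium-dependent component and the AP width becomes
sensitive to Na density, contrary to the dissociation the model is meant
to exhibit (width set by Kv3, threshold/dV/dt set by Nav).

The supplemented Kv7 (M-type) conductance activates at $-27$ mV (slope
4 mV).  Its time constant is very slow below spike threshold (~8 s) and
two orders of magnitude faster above ~+8 mV, and it is deliberately not
translated by the activation-voltage shift.  Under these kinetics the
M-current behaves as a spike-activity integrator: it accumulates during
the suprathreshold portion of each action potential — where control and
shifted steady-state curves are both saturated — and barely tracks the
subthreshold trajectory.  This is the regime in which the two reported
Kv7 observations coexist: adding 2 mS/cm² lowers the entire F–I curve,
while hyperpolarizing the Kv7 activation voltage by 10 mV leaves firing
frequencies essentially unchanged.  A conventional fast, subthreshold
M-current cannot satisfy both in this cell model, because near rheobase
the shifted channel's standing subthreshold conductance suppresses
marginal spiking; we flag this as a deliberate modeling choice rather
than a fitted property of any particular KCNQ subunit.

## Cell models and the integrator

The PV neuron is a single compartment, modeled as a 20 µm × 20 µm
cylinder (lateral area ≈ 1257 µm², ≈ 12.6 pF at 1 µF/cm²; a flat-square
reading of the geometry is selectable).  Channel densities were
calibrated, not transcribed: gNa = 0.3 S/cm², gKv3 = 0.04 S/cm², leak
0.8 mS/cm² (input resistance ≈ 100 MΩ), E_L = −68 mV (rest ≈ −71 mV),
E_Na = +50 mV, E_K = −90 mV.  The calibration targets were a stable
resting potential, non-adapting firing above 200 Hz, AP half-width near
0.3 ms, and the Kv3-shift phenotype: a −10 mV shift abolishes
near-threshold firing, and its mild effect on the maximal rate is
restored to within 10% by co-scaling the activation kinetics
(`kv3_kin_scale ≈ 0.3`).

The pyramidal cell is a single-compartment conductance burster: fast Na
with instantaneous activation and inactivation slaved to the
delayed-rectifier gate ($h = 1 - n$), a delayed-rectifier K current, a
leak, and a persistent Na current whose slow inactivation
(`tauh_bar = 1500` ms) paces burst onset and termination.  Depolarizing
bias moves it from silence through rhythmic bursting into tonic firing;
its constants (C = 21 pF, gNa = 28 nS, gK = 11.2 nS, gNaP = 2.8 nS,
gl = 5 nS, E_L = −62 mV) were calibrated so that the network targets
below are met — the network claims depend on the rate/burst regime, not
on the identity of the burster.

Both integrators use a fixed step (default dt = 0.025 ms) with exact
exponential gate updates and an exponential (linearly implicit) voltage
update in which conductances are frozen over the step.  The voltage
update is exact for a passive membrane — the passive RC test in the
suite holds to < 0.1% — and remains stable at spike-peak sodium
conductances, where the membrane time constant (~10 µs) is far below dt
and a fully explicit update diverges.  Halving dt changes subthreshold
trajectories by well under 0.5 mV RMS and spike counts by at most one
per 300 ms pulse.

## Protocols

* **F–I curves**: 300 ms square pulses normalized to capacitance
  (pA/pF), default grid 1–21 pA/pF in 2 pA/pF steps.  "Near-threshold"
  is operationalized as the lowest two amplitudes that elicit at least
  one spike in the control condition; "maximal" is the highest tested
  amplitude.
* **AP metrics**: threshold at the spike foot, found by searching
  backward from the peak for the last upward crossing of a 20 V/s dV/dt
  criterion (robust to the capacitive charging ramp at high current
  densities); amplitude = peak − threshold; half-width at
  threshold + amplitude/2; AHP relative to threshold.
* **Voltage clamp**: holding −110 mV, steps −90…+50 mV in 20 mV
  increments for 300 ms.  Under clamp the gating ODEs have exact
  exponential solutions, which are evaluated in closed form; peaks feed
  the chord-conductance/Boltzmann analysis.
* **Synaptic bombardment**: 1000 excitatory (E_rev 0 mV) and 500
  inhibitory (E_rev −90 mV) alpha synapses, 10 nS each, at uniform
  random onset times over 1 s.  The alpha time constants are not pinned
  by the protocol; the excitatory value is 0.5 ms (fast AMPA onto PV),
  and the inhibitory value was calibrated to 5.8 ms (GABA_A-range decay)
  so that the control-condition rate matches the 30.64 Hz calibration
  target.  Under these conditions the firing rate declines monotonically
  as the Kv3 activation voltage is hyperpolarized.
* **Dynamic clamp (in silico)**: an extra current
  $g_{tot}\,m\,h\,(v - E_{rev})$ with Kv3 gating evaluated on the live
  membrane potential.  20 nS of unshifted conductance leaves the F–I
  curve within 10%; the same 20 nS with a −10 mV shift collapses firing
  at the lowest near-threshold step while sparing the top of the curve.
* **gEPSP trains**: regular excitatory conductance events (alpha, 5 ms)
  with per-event Gaussian amplitude jitter (CV 0.08 around a calibrated
  1.16 nS mean), each condition held at −70 mV by a bias current found
  by secant search.  The jitter stands in for biological input
  variability: a 20 nS clamp moves this model's gEPSP threshold by only
  a few percent, so identical deterministic events would yield
  degenerate all-or-none probabilities.  The EPSP-amplitude protocol
  likewise holds every condition at −70 mV so that amplitude differences
  reflect the subthreshold Kv3 conductance rather than resting-potential
  offsets.

## The reduced circuit

200 pyramidal cells and 20 PV cells are connected with the literature
connection probabilities: PC→PC 10%, PC→PV 80%, PV→PC 36%, PV→PV
chemical 78%, PV–PV gap junctions 61% (unordered pairs).  Chemical
synapses are spike-triggered exponential conductances (τ_E = 2 ms,
τ_I = 5 ms, delay 0.5 ms) with one weight draw per edge (±10% uniform
jitter); gap junctions are ohmic (0.5 nS).  Each cell receives a
constant bias current drawn uniformly per run (PC: 0.045–0.078 nA;
PV: 0.095–0.135 nA), which randomizes individual activity levels.

The calibration followed a stepwise recipe: PV–PV chemical weights were
set for moderate interneuron-network synchronization, gap junctions were
added at a conductance that synchronized the PV population further, and
the PV→PC and PC→PV unitary weights were constrained so that somatic
PSPs measured on a quiescent postsynaptic cell held at −70 mV stay below
1 mV.  Within those constraints the weights and bias ranges were tuned
to the control targets (PC ≈ 7 Hz sparse firing under a dense PV
inhibitory tone ≈ 63–67 Hz); the −10 mV condition is then a genuine
prediction, not a fit (PC ≈ 29–30 Hz, PV rate decreasing).

Two reversal-potential conventions deserve note.  The bombardment
protocol keeps the stated 0/−90 mV reversals.  The network's inhibitory
reversal is −80 mV: with −90 mV the unitary IPSP needed to hold the
control PC rate exceeds 1 mV, and with −75 mV the circuit becomes
bistable (any shift tips it into full synchrony).  −80 mV satisfies the
sub-mV constraint and yields a graded, monotone gamma-versus-shift
relation.  Similarly, the strength of PC recurrence controls the
frequency of the synchronized state: with strong recurrence the
oscillation tracks the PC firing rate (~30 Hz) and drifts below the
30 Hz band edge at strong shifts; the default `w_pc_pc = 0.4` nS keeps
the rhythm PV-paced near 40 Hz, inside the gamma band across the whole
shift grid.

## LFP proxy and spectral analysis

The LFP proxy is the negated sum of the ionic transmembrane currents of
all 220 cells, converted to mV through a nominal 1 MΩ impedance and
decimated to 1 kHz by block averaging.  It is band-passed 5–50 Hz with a
zero-phase 2nd-order Butterworth filter; the spectrum is a Welch
averaged periodogram (500 ms Hann windows, 50% overlap, one-sided
density normalization, validated against a sinusoid via Parseval);
gamma power is the mean spectral density over 30–50 Hz.  Because the
proxy's impedance factor is nominal, absolute gamma densities carry an
arbitrary scale: comparisons across conditions (ratios, orderings,
trend fits) are meaningful, absolute mV²/Hz values only up to that
factor.  The gamma-versus-shift sweep (0…−10 mV, several seeds per
point) is summarized by a least-squares fit $\gamma = a e^{b|shift|} + c$,
with $R^2 = 1 - RSS/TSS$ about the mean — stated explicitly because
nonlinear $R^2$ conventions differ.

## Fitting stages

Chord conductance $g = I_{peak}/(V - E_{rev})$ feeds a Boltzmann fit
$g_{max}/(1 + e^{-(v - V_{1/2})/k})$ via Levenberg–Marquardt with
data-driven starts ($V_{1/2}$ from the half-maximum crossing of the
monotonized data, slope from the 25–75% span, $g_{max}$ from the
plateau); normalized conductance divides by the fitted $g_{max}$, not
the largest observed point.  Activation kinetics come from a
mono-exponential fit to the rising phase.  All fitters are deterministic
given their inputs, and every fit test in the suite asserts recovery of
parameters from the synthetic-data generator's serialized ground truth,
never against hard-coded numbers.

## What the synthetic data do and do not emulate

`generate_patch_family()` produces voltage-clamp K⁺ current families
with Boltzmann activation, mono-exponential activation kinetics, slow
inactivation, and additive Gaussian current noise, at WT-like
(V½ −6.6 mV) and AD-like (V½ −15.5 mV) settings, with the generating
parameters attached.  It deliberately omits capacitive transients,
series-resistance errors, and pharmacological-subtraction artifacts, so
passing round-trip tests demonstrates the correctness of the analysis
chain on clean currents, not robustness to every recording artifact.
Homogeneous Poisson spike trains serve the synchrony metrics the same
way.

## Problem sizes and determinism

The standard runs are sized for interactive use: single-cell protocols
integrate 0.3–1 s at dt = 0.025 ms in milliseconds of wall time; one
1 s, 220-cell network run takes about a second.  The reproduction suite
uses 5 network realizations per condition and a 5-point shift grid with
3–5 seeds per point; the acceptance script uses 15 realizations for the
rate targets and 5 × 5 for the sweep.  Every stochastic element (event
times, connectivity, weights, biases, initial voltages, amplitude
jitter) is drawn from a user-supplied seed, and reruns are bit-identical.

## Known limitations

Single compartments cannot express axonal spike initiation or dendritic
integration; temperature dependence and stochastic channel gating are
out of scope.  The Kv7 kinetics are a functional choice (spike-activity
integrator), not a fit to KCNQ data.  The absolute LFP scale is
arbitrary, so absolute gamma densities should not be compared to
extracellular recordings; and the exact constants of the original
deposited cell models were not transcribed — the calibration targets
substitute for them, which is why the control-condition statistics are
calibration-constrained while the shifted-condition results are
predictions.
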