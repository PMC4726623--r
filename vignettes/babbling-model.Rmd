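---
title: "A reward-modulated spiking-network model of babbling acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reward-modulated spiking-network model of babbling acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`babblesim` models how syllabic (canonical) babbling can emerge from
domain-general cortical learning. No syllable frame, oscillator, or central
pattern generator is built in: a generic recurrent spiking network, a
salience-contingent reward, and dopamine-gated Hebbian potentiation are
enough for consonant–vowel alternation to become progressively more
frequent. This vignette describes the model, its parameters, the numerical
choices, what the synthetic fixtures do and do not establish, and the design
decisions that were genuinely open.

## Model

### Network dynamics

Each neuron follows the two-variable Izhikevich equations

$$v' = 0.04 v^2 + 5v + 140 - u + I, \qquad u' = a(bv - u),$$

with a spike recorded and the reset $v \leftarrow c$, $u \leftarrow u +
d_{\text{reset}}$ applied when $v \ge 30$ mV at step entry. Integration uses
two half-ms sub-steps for $v$ per 1-ms step (the standard stabilization for
this model). Excitatory reservoir neurons and all motor neurons are regular
spiking ($a=0.02$, $b=0.2$, $c=-65$, $d_{\text{reset}}=8$); inhibitory
neurons are fast spiking ($a=0.1$, $b=0.2$, $c=-65$, $d_{\text{reset}}=2$).
Parameters are homogeneous by default; `build_network(heterogeneous =
TRUE)` applies the classic per-neuron jitter instead, since the literature
this architecture descends from randomizes $c$ and $d_{\text{reset}}$
slightly and the original description leaves the choice open.

The reservoir holds 1000 neurons, 200 of them inhibitory. Every neuron has
exactly 100 outgoing connections (inhibitory neurons only onto excitatory
ones); excitatory weights are drawn from $U(0,1)$, inhibitory from
$U(-1,0)$, and both stay fixed for the whole run. 200 excitatory neurons
are designated outputs and project all-to-all to the 200 motor neurons
(100 agonist, 100 antagonist) through the plastic weight matrix. All-to-all
output connectivity is an inference from the weight-matrix figures of the
source literature, which show a dense output-by-motor grid. Spikes recorded
at ms $t$ deliver current at ms $t+1$; there are no longer conduction
delays. Every reservoir and motor neuron receives i.i.d. uniform noise on
$[-6.5, 6.5]$ pA each ms — the model's only input, so all structure in the
output is endogenous.

State persists across trials: a run is one continuous simulation whose
global ms counter also phases the 10-ms plasticity boundaries.

### Motor interface and vocal tract surrogate

Per-ms spike counts are summed over each motor pool and smoothed with a
100-ms moving average over fully contained windows, so a 1000-ms trial
yields a 900-sample series; the smoothed value is mean pooled count per ms
(not per neuron), which makes amplitude grow with pool size, as the
parameter sweep expects. Net muscle activity is $m \cdot (\text{agonist} -
\text{antagonist})$; the same series drives both the jaw-raising masseter
and the lip-closing orbicularis oris, a single closure degree of freedom.

The full aerodynamic articulatory synthesizer used in the source work
(coupled mass–spring tube walls, adult female geometry) is not
re-implemented. The built-in surrogate preserves the two properties the
learning dynamics need: a hard airflow cutoff at closure, and larger
acoustic change per unit aperture change near closure. Aperture is
$\mathrm{clamp}(0.5 - \text{muscle}(t),\, 0,\, 1)$; the rest aperture 0.5
leaves the mouth half open so that learned increases in mean activation
move toward closure/opening alternation. A 220-Hz pulse train (a generic
adult-female fundamental; the external synthesizer derives f0 from
laryngeal physics) is shaped by a lungs-driven envelope — a 10-ms onset
ramp times a slow $\tau = 0.6$ s exhalation decay standing in for the
emptying lungs, gated by the lung-volume schedule — then filtered by a
single time-varying resonance $F_1(t) = 300 + 900\,a(t)$ Hz (bandwidth
80 Hz) and multiplied by $a(t)^\gamma$ with $\gamma = 1$. Output is 0.9 s
at 22050 Hz. For work with the external synthesizer,
`export_praat_script()` emits a byte-stable script with the fixed settings
(adult female speaker; lung volume 0.1 at 0 and 20 ms, 0 at 50 and 900 ms;
Interarytenoid 0.5; Hyoglossus 0.4) and the per-ms muscle targets.

### Salience and reward

The salience estimate is a cochleagram (32 log-spaced bands, 100–8000 Hz,
256-sample Hann windows at 1-ms steps, log-compressed band energies)
followed by per-band temporal edge detection: the mean log-energy over the
coming 20 ms minus the mean over the preceding 20 ms, summed over bands.
Positive values mark onsets, negative offsets. The score is

$$S(v) = \sum_{t=151}^{900} |s(v,t)|,$$

excluding the first 150 ms, which carry the file-onset transient. The
source model's final stage — cortical filters trained on speech — is
intentionally absent, so absolute scores are not comparable to published
values; what carries over is the ordering property that more
closure/opening alternation yields higher salience, which the test suite
verifies on constructed fixtures.

The transient trace carries a fixed output scale (2.69e-4) chosen once so
that vocalizations of the untrained reference configuration (200 motor
neurons, $m = 2$) score about 5 salience units. That places the model's
starting distribution at the operating point where the adaptive threshold
engages, reproducing the study's starting conditions in the surrogate's
units. Reward is the strict inequality $S > \theta$; $\theta$ starts at
4.5 and increases by 0.1 — with the 10-trial reward history reset —
whenever at least 3 of the last 10 trials were rewarded. Because the
history starts at zeros, the criterion can fire within the first 10
trials; that is the literal reading of the rule and is implemented as such.

### Plasticity

The output-to-motor synapses learn by dopamine-modulated, LTP-only STDP
with eligibility traces. Per ms, in order: dopamine decays ($d \leftarrow
0.995\,d$); every motor spike adds the current presynaptic traces to its
incoming eligibilities ($e_{rm} \leftarrow e_{rm} + c_r$); every output
spike sets its trace to 0.1, then all traces decay by 0.95; on 10-ms
boundaries $s_{rm} \leftarrow \min(s_{rm} + e_{rm} d,\, 4)$, all weights
are divided by their mean, and $e \leftarrow 0.99\,e$. Rewards add 1 to
dopamine. Three ordering details matter and are fixed as follows:

* **Same-ms pre/post pairs do not potentiate.** Traces are read before the
  current ms's presynaptic spikes are registered, so credit begins at
  $t+1$ — consistent with the 1-ms spike propagation delay, which makes
  causal pre-then-post pairs the ones that carry signal.
* **Mean, not sum, normalization.** The source pseudocode divides by the
  grand sum while the prose divides by the mean; dividing by the sum
  (40 000 synapses) would collapse all weights toward zero and contradict
  the published weight scales, so the mean is the default and
  `plasticity_params(normalize = "sum")` remains available for
  sensitivity analysis.
* **Distal reward.** A trial's reward bumps dopamine at the first ms of
  the next trial (decay first, then bump, per the pseudocode's line
  order), since the sound can only be evaluated after the trial completes.
  Eligibility decays by 0.99 per 10 ms, so the dopamine transient
  (half-life ≈ 139 ms) mostly credits synapse activity from the rewarded
  trial's end and the following trial's start.

Weight nonnegativity is structural (potentiation only adds, the cap and
normalization preserve sign), and after the first normalization the mean
is exactly 1 at every boundary; both are asserted at every update in the
invariant tests.

### Yoked controls and syllable counting

A yoked control run has its own weights, noise, and dynamics but receives
rewards at the trial indices of a reference run. Any learning effect
present in reinforced runs but absent in yoked runs is therefore
attributable to reward *contingency* rather than to reward occurrence.

As a learning-independent metric, syllable nuclei are counted from
intensity peaks: framewise RMS (64-ms windows, 10-ms steps) in dB relative
to the maximum, peaks above a −25 dB silence threshold, separated by dips
of at least 2 dB, with pauses of at least 0.3 s splitting the sound into
independently analyzed chunks, and an autocorrelation voicing check
(pitch in 75–600 Hz, peak ≥ 0.45) at each surviving peak. The reference
tool's exact intensity algorithm is not published, so framewise RMS with
max-relative thresholds was adopted; the three stated defaults keep their
semantics, and absolute counts on real speech may differ slightly. The
voicing threshold 0.45 was set so that steady pulse trains pass and
equal-envelope white noise fails, which the fixtures verify. Whether the
−25 dB threshold should be relative to the maximum or to a high percentile
is left switchable; relative-to-maximum is the default.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `n_motor` | 200 | neurons | motor pool (half agonist); output pool matched |
| `m` | 2 | — | muscle scaling; sweep explores 2–8 |
| noise amplitude | 6.5 | pA | spontaneous drive to every neuron |
| `window_ms` | 100 | ms | motor smoothing window |
| `rest_aperture` | 0.5 | — | mouth opening at zero net activation |
| θ init / increment | 4.5 / 0.1 | salience units | adaptive reward threshold |
| reward criterion | 3 of 10 | trials | threshold-raise rule |
| dopamine decay / bump | 0.995 per ms / 1 | — | reward gating |
| trace bump / decay | 0.1 / 0.95 per ms | — | presynaptic memory |
| eligibility decay | 0.99 per 10 ms | — | credit window |
| weight cap | 4 | — | single-synapse limit |
| nuclei thresholds | −25 dB, 2 dB, 0.3 s | — | syllable detector defaults |

The full design runs 7200 one-second trials (two simulated hours) per
simulation, five simulations per parameter combination, over the 13
combinations of `sweep_grid()`. The package keeps those defaults;
the bundled experiments use scaled runs (600–1200 trials, five seeds),
which are large enough for the directional learning effects while keeping
a full verification run on one CPU in the tens of minutes. The vignette
and tests state per-run problem sizes next to each result.

## What the synthetic data shows — and what it does not

The fixtures module generates every input the tests need: spike rasters
with known pooled statistics, muscle series with closed-form mean/SD,
waveforms with a known number of voiced bursts, muscle series with a known
number of closure episodes, and salience sequences paired with a literal
transcription of the threshold rule. Because each fixture carries its
ground truth, no test recomputes expectations with the code under test.

Passing these tests establishes the algorithmic contracts: the exact
window arithmetic of the smoother, the exclusion boundary of the salience
sum, the state-machine semantics of the threshold, the order of operations
in the plasticity update (verified against an independent brute-force
eligibility oracle to 1e-12), and the detector's response to constructed
audio. It does **not** establish that absolute salience values, syllable
counts, or learned-weight magnitudes match what the full articulatory
synthesizer and the trained salience model would produce on real or
synthesized speech — those depend on components explicitly out of scope.
The scaled learning experiment therefore asserts directions and paired
contrasts (reinforced vs yoked), not published magnitudes.

In the scaled experiment (5 seeds × 1200 trials plus paired yoked
controls) the reinforced runs raise last-minute salience over first-minute
salience (one-sided paired test, α = 0.05) while the yoked runs show no
significant increase; the reinforced agonist/antagonist weight ratio
exceeds the yoked one (≈1.07 vs ≈1.01 at this scale); muscle mean rises
robustly. Two honest caveats, visible in the test data: yoked runs drift
upward in salience too (non-significantly), because reward-triggered
potentiation spreads the weight distribution regardless of contingency and
the surrogate's salience is sensitive to the resulting motor variability;
and the muscle-SD trend, while positive on average across the five seeds,
is small at 1200 trials — it is the slowest-moving of the learned
features, consistent with the weight ratio (its upstream cause) being
itself ≈1.07 rather than the asymptotic ≈1.35 reached after six times as
many trials. Syllable counts per vocalization move in the expected
direction relative to yoked controls at this scale (reinforced +0.01 vs
yoked −0.06 nuclei from first to final minute, means across five seeds)
but are not asserted numerically: the surrogate's absolute counts sit
near 2 from the start because its continuous amplitude modulation, unlike
the aerodynamic synthesizer's, already produces intensity dips that the
detector reads as nucleus boundaries.

## Numerical choices and degenerate inputs

* Reproducibility: a run is fully determined by `(seed, config)`. The
  topology/reservoir weights, the initial plastic weights, and the noise
  stream use fixed offsets of the master seed, so the topology is
  identical regardless of run length. The compiled trial kernel draws its
  noise from R's RNG, so R-level seeding governs everything.
* The compiled kernel is an exact transcription of the R-level
  `step_network()`/`per_ms_update()` semantics; the suite checks
  element-wise agreement of the R path against a per-neuron scalar oracle
  (tolerance 1e-9 over 1000 ms) and the eligibility bookkeeping against a
  brute-force pairwise oracle (1e-12 over randomized patterns).
* Division by the weight mean is guarded: a zero mean raises an integrity
  error (unreachable from valid $U(0,1)$ initialization, since
  potentiation only adds and the cap preserves positivity).
* Non-finite membrane state raises a runtime integrity error rather than
  propagating NaNs.
* Silence in: the cochleagram floors at the additive energy constant, the
  intensity contour at −90 dB; both yield zero salience/zero nuclei
  rather than errors. Empty waveforms error explicitly.
* Muscle-series SD is the population SD (divisor $n$) of the 900 values.
* The intensity peak-merge rule keeps the louder of two peaks whose
  separating dip is shallower than 2 dB.

## Known limitations

* One motor degree of freedom; no tongue, velum, larynx, or independent
  lip/jaw control. The lungs/laryngeal settings are fixed exports, not
  learned.
* The surrogate's absolute acoustics (and hence salience units, nucleus
  counts, and learned-weight magnitudes) are not comparable to the
  external synthesizer's; only orderings and contrasts are.
* No perceptual system: salience is computed by an external function of
  the waveform, not by neurons in the model.
* Rewards are binary; graded rewards are deliberately out of scope.
* Learning is confined to the output-to-motor synapses; the reservoir is
  fixed by construction, and the suite hashes it to prove it.
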