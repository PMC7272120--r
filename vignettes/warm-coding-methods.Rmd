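---
title: "Methods: psychophysics, afferent simulation and the dual-channel warm code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychophysics, afferent simulation and the dual-channel warm code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocode)
```

## Scope and units

`thermocode` analyses a head-fixed go/no-go warm-detection task on the
mouse forepaw and the thermosensitive C-fiber recordings that accompany
it, and implements a population-coding model in which skin warming is
read out from two concurrent afferent signals: excitation of
warm-excited polymodal C-fibers, and suppression of the ongoing firing
of cool-driven C-fibers. Because the original animal data are not
publicly deposited, the package ships first-class synthetic generators
for both the behaviour and the afferent spike trains; every analysis
function is exercised end-to-end on these.

Units are fixed package-wide: seconds, °C, Hz, mm², fibers/mm². All
timestamps are relative to session start. Traces are *command*
temperatures; the thermal lag between the Peltier command and skin
temperature is not modelled, because no transfer function is available
— analyses that depend on absolute timing near stimulus onset (first
spike latency, thermal thresholds) therefore carry a small systematic
earliness relative to what a thermocouple would report.

## Stimuli

The behavioural stimulus is a ramp–hold–ramp step:
`step_waveform_params(baseline, target, 0.5, 3, 0.5)` — 0.5 s ramp to
target, 3 s hold, 0.5 s return, total 4 s; the trained stimulus is
32→42 °C and threshold stimuli shrink the amplitude (6, 4, 2, 1,
0.5 °C). Afferent search stimuli are 1 °C/s linear ramps (32→48 °C heat,
32→12 °C cold). Waveforms are sampled at 1 kHz by default (the
behavioural acquisition rate); the model integrates rates at 200 Hz,
which is ample for piecewise-linear waveforms. Total waveform duration
equals the sum of the segment durations exactly, and interpolation
(`temperature_at`) is linear with no extrapolation.

## The behavioural session generator

A session (`session_schedule`) interleaves 50 stimulus and 50 catch
trials in random order, with successive onsets separated by the
stimulus duration plus a uniform 3–30 s interval, a 3.5 s response
window and a 2 s pre-stimulus lockout — the task's published design.
The synthetic observer (`observer_params`) is intentionally minimal:

* spontaneous licking is a homogeneous Poisson process (default
  0.05 Hz, giving a false-alarm rate ≈ 0.16 in a 3.5 s window);
* each stimulus trial is detected with probability
  $p(A) = \mathrm{guess} + (1-\mathrm{guess}-\mathrm{lapse})\,
  \big/\,\big(1+(\theta/A)^{\beta}\big)$, a saturating psychometric
  function of amplitude $A$ with midpoint $\theta$ (default 1 °C) and
  exponent $\beta$ (default 3);
* a detection produces one stimulus-locked lick at a log-normal latency
  (median 0.8 s, log-SD 0.3).

The defaults were chosen once to reproduce the behaviour of a trained
wild-type animal — asymptotic hit rate ≈ 0.93, session d′ ≈ 2.4, a 1 °C
perceptual threshold, mean first-lick latency ≈ 0.85 s — and are not
fitted to data. The lick baseline and latency forms are the simplest
distributions consistent with lick PSTHs; the generator does not model
satiation, impulsivity sequences, motor variability or within-session
drift, so passing parameter-recovery tests here demonstrates that the
*analysis* pipeline is correct, not that real mice behave this simply.

## Scoring and signal detection

A stimulus trial is a hit iff a lick falls in the half-open window
(onset, onset + 3.5 s]; a catch trial is a false alarm under the same,
equally long window at its virtual onset. The window is open on the
left: a lick exactly at onset cannot be a response to the stimulus.
Licks inside the 2 s lockout are counted and flagged but do not change
outcomes (the task imposes a timeout there; its scoring effect is not
documented, so we only flag). The published hit definition ties the
window to the re-cooling phase; for the default 0.5/3/0.5 s waveform
that reading coincides with a flat 3.5 s window, which is what is
implemented.

Sensitivity is $d' = z(h) - z(fa)$ with the boundary correction that
replaces rates of 1 and 0 by $1-\tfrac{1}{2N}$ and $\tfrac{1}{2N}$
(each rate corrected with its own trial count), computed with the
full-precision inverse normal CDF — no lookup approximation. The test
suite checks `dprime()` against an independently coded inverse normal
(Acklam's rational approximation with Halley refinement) to 1e-9 over
1,000 random rate/count triples.

Perceptual thresholds: the original analysis detects performance via
repeated-measures ANOVA on hit vs false-alarm rates across animals;
with single synthetic sessions we instead use the rule *smallest tested
amplitude with d′ ≥ 1.0 whose trial-level bootstrap 95 % CI (10,000
resamples) for h − fa excludes 0*. The d′ criterion is exposed in
`estimate_threshold()`. The trial-level bootstrap resamples binary
outcomes with replacement, which is implemented exactly as binomial
resampling of each rate.

## The afferent generator

Two generative archetypes cover the recorded thermal response types:

* **Warm-excited fibers** (C-MH, C-MHC, A-MH): silent below an absolute
  threshold `t_on`, rate $g\,(T - t_\mathrm{on})^+$ above it, capped at
  `r_max` (30 Hz). `t_on` is drawn uniform on [33, 44] °C — the
  recordings show one low- and one high-threshold example but no
  distribution, so a uniform span over the innocuous-to-noxious range
  is the least-committal choice, exposed in `population_spec()`. Gains
  are uniform on [1, 3] Hz/°C, placing a 10 °C step response at a few
  tens of spikes — matching the *sparse* firing reported for warm
  steps. Thresholds are absolute temperatures, so a 22→32 °C step
  recruits few fibers, weakly: the absolute-coding interpretation of
  warm-excited afferents. A `preferring` mode (rate peaks at a rolloff
  temperature and declines with equal slope) represents the small
  population of warm-preferring units inhibited by noxious heat; it is
  available in `warm_fiber()` but not sampled by default, since those
  units are rare and their incidence is not quantified.
* **Cool-driven tonic fibers** (mostly C-MC, some C-MHC): ongoing rate
  drawn uniform on [0.2, 6] Hz — the observed range at 27 °C — excited
  by cooling at `cool_gain` (1 Hz/°C) and multiplicatively suppressed
  by warming at 0.2 per °C, so a 5 °C warm step silences them, matching
  the observation that warm ramps silence spike activity. Rates
  re-reference to the session background temperature instantaneously
  (ongoing rates are reported similar at 32 °C and 22 °C baselines); no
  adaptation time constant is modelled. With zero ongoing rate the same
  form yields a phasic cool-excited fiber, used for cool-only classes
  without ongoing activity.

Spike trains are inhomogeneous Poisson processes realised by thinning,
with a 5 ms absolute refractory period — the simplest point process
consistent with the mean-rate descriptions (no interval statistics are
published). At the rates involved (< 30 Hz) the refractory correction
to the mean count is below 15 % and below 2 % for tonic fibers; tests
that compare counts to $\int r\,dt$ account for this.

A population (`population_spec`) defaults to the measured forepaw
numbers: 176 fibers/mm² × 22 mm² = 3,872 fibers, 36 % thermosensitive,
19 % of the thermosensitive subset tonically active. Class labels draw
from the recorded tallies renormalised over the six named classes
(C-MH 20, C-MHC 6, C-MC 7, C-C 2, A-MH 1, A-MC 1, of 37); the tonic
subset is assigned C-MC:C-MHC at 5:1, as observed. Conduction
velocities are uniform within the class bands (<1.2 m/s for C,
1.2–10 m/s for Aδ). A single session seed expands into per-component
child seeds (`child_seed`), so all generators are bit-reproducible.

### Genotype presets

`genotype_preset()` encodes lesions at the population level, not the
channel level:

| preset | effect |
|---|---|
| `wildtype` | identity |
| `trpm8_null`, `pbmc_block` | ongoing fraction → 0, cool-excited classes removed, cooling gain → 0 |
| `trpv1_null` | incremental gain above 44 °C → 0 (non-noxious gain intact) |
| `tko` (trpv1:trpa1:trpm3) | incremental gain above 42 °C × 0.2; cool channel intact |
| `trpm2_null` | cool-class proportions halved |

The pbmc preset represents acute pharmacological TRPM8 blockade; at the
population level it is identical to the genetic null (reversibility is
an experimental, not a population-state, property). The trpm2 halving
operationalises "significantly reduced cool-sensitive proportion"
without a published effect size.

## Ephys analyses

Classification is a total function of conduction velocity and modality
flags; 1.2 m/s and 10 m/s both classify as Aδ (the C band is stated as
strictly below 1.2). Heat-only non-mechanosensitive fibers — not
observed in the recorded sample — are labelled `C-H` for totality, and
mechano-only fibers `C-M`. Thermal thresholds read the stimulus trace
at the first spike; over repeats the estimate exceeds the generating
`t_on` by the first-arrival delay ($\sqrt{\pi/2g}$ s on a 1 °C/s ramp,
≈ 0.9 °C at the default 2 Hz/°C gain), a positive bias bounded by 1 °C
that the recovery tests assert. Ongoing activity uses a 0.1 Hz floor —
below the observed 0.2 Hz minimum, for which no detection criterion is
published — required in both halves of the baseline window so bursts do
not qualify. The percentage rate-change index is undefined (NA) at zero
baseline rate rather than clamped. PSTHs pool counts over units ×
repeats and satisfy an exact conservation identity that the suite
checks property-style.

## The dual-channel decoder

`model_dprime()` fixes one sampled population (identities per
experiment), computes each channel's expected pooled count in a 1 s
decision window after onset (trapezoidal integration of the
instantaneous rates) and in a matched constant-baseline window, and
draws per-trial pooled counts as Poisson — exactly the distribution of
the summed fiber counts given Poisson fibers, which makes hundreds of
trials over thousands of fibers cheap. The 1 s window brackets the
behavioural first-lick latencies (~0.3–0.9 s) and is exposed in
`decoder_params()`.

Evidence is excitation $e = N_A^{stim} - N_A^{base}$ and suppression
$s = N_B^{base} - N_B^{stim}$. Two combination rules are provided
because the downstream integration site and rule are explicitly
unknown:

* `sum`: $e + s$ — either channel suffices;
* `coincidence` (default): $\min(e/\hat\sigma_e,\; s/\hat\sigma_s)$,
  each channel normalised by its null-epoch SD estimated from the same
  run (floored at 1 count so an empty channel contributes zero, not
  undefined, evidence) — both channels are required.

The coincidence default operationalises the claim that excitation alone
is insufficient for warm perception; the sum rule is retained for
contrast experiments. This is an interpretive choice, not a mechanism
claim. Whether the trpm8-null detection failure reflects the
coincidence requirement or weak excitation is left open by the data;
both hypotheses are runnable as configurations.

Two sensitivity indices are reported. `predicted_dprime` thresholds the
statistic at the decoder criterion (by default the 95th percentile of
the same run's null distribution — an ideal observer pinning its
false-alarm rate near 5 %) and applies the boundary-corrected
behavioural d′ to the resulting hit/false-alarm rates; it is the number
comparable to behavioural d′ and saturates at $2 z(1 - \tfrac{1}{2N})$.
`dprime_gaussian` is the distribution-based
$(\mu_{stim}-\mu_{null})/\sigma_{pooled}$; it is continuous and
unbounded, matches the analytic Poisson-count prediction in the
constant-rate limit (checked to within 5 %), and is the right index for
monotonicity analyses where the thresholded index would tie at ceiling.
Degenerate zero-variance statistic distributions are flagged and give a
Gaussian index of 0. Note one caveat: with the min rule, a channel that
is *exactly* silent clips the statistic at zero, which biases the
Gaussian index for lesioned populations; lesion contrasts therefore use
`predicted_dprime`, which is exactly 0 there.

With default parameters the ideal observer is far more sensitive than
the animal (a 1 °C step yields pooled-count d′ well above behavioural
values): it pools optimally over ~1,400 fibers with no central noise.
The model is used for *pattern* predictions — monotonicity in amplitude
and area, null identity, lesion contrasts, warm/cool specificity — and
is deliberately not fitted to the behavioural d′ values.

## Problem sizes and numerical choices

The test suite and acceptance script run the full default population
(3,872 fibers) through the count-based model; spike-level population
simulation in the analysis scripts uses a recording-campaign-sized
sample (~400 fibers), a choice of presentation, since count-based and
spike-level paths agree by construction. Simulation sizes (20 seeds for
recovery and monotonicity runs, 200–1,000 trials per model condition,
10 × 60 s tonic recordings, 50 ramp repeats) were chosen so Monte Carlo
standard errors sit well inside the asserted bounds. Ties in rank
correlations are avoided by using the continuous Gaussian index.
Bootstrap CIs use 10,000 resamples. Seeds: every public generator takes
one seed and derives per-component child seeds by a documented
congruential rule, so adding a component never reorders another's
draws.

## Known limitations

* The observer and fiber models are generative stand-ins shaped by the
  published summary statistics, not fits to raw data; absolute numbers
  (e.g. model d′) are not comparable to the animal values, only the
  qualitative contrasts are.
* Skin-temperature lag, adaptation time constants, inter-fiber
  correlations, and central/decision noise are not modelled; all four
  would lower model sensitivity toward behavioural values.
* Mechanosensitivity enters only as a boolean classification flag;
  mechanical tuning is out of scope.
* The two residual unclassified thermosensitive units in the published
  tallies (35 of 37 named) are handled by renormalising over the named
  classes; the alternative (a seventh "other" class) would change class
  proportions by < 3 %.
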