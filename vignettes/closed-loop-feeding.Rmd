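---
title: "Closed-loop optogenetic feeding: detection, simulation and analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optogenetic feeding: detection, simulation and analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OptoFeed)
```

## The assay

In capacitance-based feeding monitors (the FlyPAD family), a fly stands on
one electrode and the food sits on another; each proboscis contact changes
the capacitance between them, sampled at 100 Hz as dimensionless integer
codes. A closed-loop optogenetic extension of this assay gates an LED on
food contact in real time, so that neurons expressing a light-gated channel
(CsChrimson) are excited exactly while the fly interacts with one of two
identical foods. Appetitive populations (sweet GRNs, PAM dopaminergic
neurons) then pull the fly toward the light-paired food; aversive
populations (bitter GRNs, PPL1) push it away. `OptoFeed` implements the
three software layers of such a system — the real-time trigger, post hoc
sip calling, and the behavioral analytics — plus a seeded agent-based
simulator that closes the loop in silico and provides ground truth for
every test in the package.

## The real-time trigger

The trigger keeps the minimum of the preceding `windowSamples` samples
(default 10, i.e. 100 ms at 100 Hz) and switches the LED on whenever

$$x_t - \min(x_{t-w}, \ldots, x_{t-1}) > \theta,$$

with threshold $\theta = 100$ capacitance units by default. Three
consequences follow directly from the rule and are part of the contract:

* a rising edge turns the LED on within one sample of contact;
* the LED turns off at the falling edge of the signal, or after one full
  window on an elevated plateau, whichever comes sooner — a sustained step
  therefore produces at most `windowSamples` on-samples (100 ms), which
  keeps the light from sticking on through slow baseline shifts;
* a constant trace never triggers, and adding a constant to every sample
  changes nothing.

Decisions the rule itself does not fix, made once and tested:

* **Strict inequality.** "Exceeds by a set threshold" is read as strictly
  greater; with integer codes a boundary convention is unavoidable, and a
  rise of exactly $\theta$ does not trigger.
* **Window excludes the current sample.** The minimum is over the
  *preceding* window only.
* **Warm-up.** Before `windowSamples` samples have accrued, the minimum is
  over however many preceding samples exist; the very first sample can
  never trigger. This gives defined behavior from sample 1 without
  modelling hardware register initialisation.
* **No debouncing, smoothing or refractory period** beyond the stated
  rule.

`runController()` computes the running minimum by folding `pmin` over the
`w` lagged copies of the trace ($O(nw)$, vectorised; with $w = 10$ this is
faster in R than an amortised-constant monotonic queue would be
interpreted). The contract is the brute-force per-sample rule, and the test
suite checks the vectorised output against an independent brute-force
recomputation on 1,000 random traces, and the streaming form
(`controllerStep()`) against the batch form bit-for-bit.

## Post hoc sip calling

The published FlyPAD classifier filters capacitance changes by shape and
duration criteria defined in prior work and not restated in the
closed-loop system's description, so `callSips()` is a transparent
stand-in, not a re-implementation: rolling-median baseline (2 s window —
robust to the contact pulses themselves), segments more than 100 units
above baseline, gaps shorter than 20 ms merged, and segments kept only if
their duration lies in [100 ms, 5 s]. Its role in the package is
comparative. Because the real-time trigger cannot know a contact's
eventual duration, it also fires on brief leg touches that the duration
filter rejects; on recordings the LED activation count is therefore an
upper bound on the called-sip count, and the two series track each other
tightly in 1-min bins (`compareAlgorithms()` reports the OLS $R^2$, slope
and the ratio of totals, after excluding bins empty in both series).
Reproducing the published $R^2 = 0.963$ and $\approx 1.4\times$ ratio
numerically is out of scope — those numbers were measured on the authors'
unreleased recordings — but the direction (ratio $> 1$, $R^2 > 0.9$) is
reproduced on simulated hours.

With exactly two retained bins the OLS fit is saturated and $R^2$ is
trivially 1; `compareAlgorithms()` refuses to report anything on fewer
than two retained bins or when the sip counts have zero variance.

## The generative model

No generative model of fly feeding is published for this assay, so the
simulator's model is the package's own, chosen to be the simplest process
that reproduces the assay's headline phenomena. A fly alternates between
idle waiting and feeding bouts (semi-Markov renewal):

1. **Idle.** Waits $\sim \mathrm{Exp}(\lambda_b \cdot s)$, with baseline
   bout rate $\lambda_b = 1.5$/min and starvation gain $s$ (dimensionless,
   default 1).
2. **Channel choice.** One bout happens on channel 1 (light-paired) with
   probability $w_1 / (w_1 + w_2)$, where
   $w_1 = \max(p_1 + u, \varepsilon)$, $w_2 = \max(p_2, \varepsilon)$,
   $p_i$ are intrinsic palatabilities (default 1) and
   $\varepsilon = 0.05$ a floor that keeps even a strongly avoided side
   reachable. Additive light drive is what lets shared chemical
   palatability dilute optogenetic attraction, and the floor is what
   makes aversion collapse toward indifference when both foods become
   unpalatable.
3. **Bout.** Sips have gamma-distributed durations (shape 4, mean 250 ms)
   truncated below at 110 ms — sips generally outlast the trigger's
   100 ms plateau window. Inter-sip intervals are exponential (mean
   0.5 s). After each sip the bout continues with probability
   $p_\mathrm{cont} = 0.8$; on the light channel every sip is illuminated
   and the continuation probability is modulated per illuminated sip,
   $p_\mathrm{eff} = \mathrm{clamp}(p_\mathrm{cont}
   e^{0.25\, v f(I)}, 0, 0.99)$, coupling valence to feeding
   microstructure and not only to choice.
4. **Experienced valence.** The weight $u$ starts at 0 and after every
   light-channel bout relaxes toward its asymptote,
   $u \leftarrow u + \alpha\,(v f(I) s_v' - u)$, with per-bout rate
   $\alpha = 0.15$ and $s_v' = s_v$ for appetitive valence ($v > 0$) and
   1 otherwise — starvation potentiates appetitive drive but not
   aversion. The relaxation produces the observed ramp-then-plateau
   preference over the first 10–15 min rather than instantaneous
   preference.
5. **Intensity.** $f(I) = I^h / (I^h + K^h)$ with $K = 1.85$ mW/cm²,
   $h = 2$: no light, no effect; roughly stable preference above the
   assay's 1.85 mW/cm² threshold intensity. The response is deliberately
   monotone — the drop in sweet-GRN interaction counts at very high
   intensity is observed but mechanistically unexplained, and is not
   modelled.
6. **Feedback loop.** With feedback gain $g > 0$, each LED offset on the
   light channel immediately re-initiates a sip with probability $g$
   (command-neuron regime, e.g. Fdg). At $g = 0.95$ flies become trapped
   in feeding chains and accumulate an extreme number of light-side
   interactions.
7. **Touches.** Brief non-sip contacts (uniform 30–80 ms) occur at
   0.6/min of bout time on the bout's channel, independent of valence
   feedback, and are never sips in the ground truth; they exist because
   the trigger fires on them while the sip caller rejects them.

Traces are synthesized from the event schedule as baseline (default 1000
units) + Gaussian random-walk drift (s.d. 0.5/sample) + white noise (s.d.
5), with per-event amplitudes drawn uniformly (sips 200–500, touches
120–250 units — all above the trigger threshold, so every real contact can
illuminate). Real amplitude distributions are unpublished; these are
package choices. The closed-loop trigger is then run on the light
channel's synthesized trace, and that lighting log is the experiment's
record — the simulator never shortcuts it from ground truth.

### Numerical and reproducibility choices

* **Rasterization.** Event times are continuous; sample mapping is
  `floor(t * rate)` with half-open intervals `[onset, onset + duration)`;
  single-sample rise and fall. Values are rounded to integer codes and
  clamped at 0.
* **Minimum event spacing.** All inter-event spacings (idle waits,
  inter-sip gaps, touch margins, the 30 ms post-LED re-initiation gap)
  are floored at 25 ms, guaranteeing at least two baseline samples
  between events at 100 Hz. Without the floor, about 5% of exponential
  gaps rasterize to under one sample, fusing adjacent events in the trace
  and breaking the one-illumination-per-contact correspondence the tests
  rely on. The distortion of the inter-sip distribution is small
  ($P(\mathrm{Exp}(0.5\,\mathrm{s}) < 25\,\mathrm{ms}) \approx 5\%$).
* **One random stream per fly,** consumed in a fixed, documented order:
  idle wait; channel choice; then per sip: duration (rejection draws for
  the truncation), feedback-gain draw (light channel, only if $g > 0$),
  continuation draw; then per bout: touch count, and per touch its onset
  and duration; finally two sub-seeds (drawn with `sample.int`) seed the
  per-channel trace synthesis, which consumes drift, then white noise,
  then per-event amplitudes in onset order. Cohort fly $i$ uses seed
  `baseSeed + i`. Identical parameters and seed reproduce an experiment
  bit-exactly.
* **End of experiment.** Events crossing the end of the experiment are
  clipped at `durationS`; a clipped final sip may be shorter than the
  truncation bound.

### What the simulator does and does not emulate

The defaults reproduce, qualitatively: valence-sign-ordered preference
with near-zero control preference; intensity gating and a stable plateau
above the half-max intensity; dilution of appetitive preference by shared
palatability and collapse of aversion as both foods approach the
palatability floor; starvation scaling of total interactions and of
appetitive (only) preference; the feeding-loop explosion of light-side
interactions; and the excess of LED activations over called sips.

Known limitations, deliberately not tuned away:

* Mild *enhancement* of bitter-activation avoidance by sucrose is
  observed in the assay; the additive-with-floor choice model predicts
  mild attenuation instead.
* At the top of the aversive palatability grid ($p = 1$ vs $p = 0.5$,
  $v = -2$) the model produces a statistical tie rather than a strict
  ordering at realistic durations: the $p = 1$ arm approaches the choice
  floor more slowly because $u$ must fall further, and the two arms'
  cumulative preferences cross within noise. The tests assert no
  significant increase along the grid plus the robust endpoint collapse.
* Appetitive cohort-mean cumulative preference settles within 0.1 of its
  final value by 15 min of an hour; aversive preference settles more
  slowly (the weight $u$ only updates on light-side bouts, which become
  rare as avoidance develops) and can still drift by ~0.1–0.12 after
  15 min. The tests assert the 0.1 band for appetitive drive and a 0.2
  band for aversive drive.
* Sip/touch amplitude distributions, multi-fly arenas, biophysical neuron
  models and associative learning (both foods are identical; there is no
  predictive cue) are out of scope.

## Analytics conventions

* Preference index $\mathrm{PI} = (n_1 - n_2)/(n_1 + n_2)$ over LED
  interactions, channel 1 being light-paired; undefined (NA, not 0) when
  both counts are zero.
* The exclusion threshold of 15 total interactions is inclusive: a fly
  with exactly 15 passes.
* SEM uses the sample standard deviation ($n - 1$); undefined for a
  single fly.
* Temporal curves pool events in 1 s periods and are **cumulative**; the
  timecourse is NA until the first event. (Whether published temporal
  curves are cumulative or windowed is not stated beyond the 1 s pooling;
  cumulative matches the monotone settling they show, and windowed curves
  are not implemented.)
* Dye-assay scoring is by light-association (+1 light-channel color, −1
  other color, 0 both), so dye-swap counterbalancing cancels by
  construction; "none" flies are excluded with a report.
* Inferential statistics (ANOVA, post hoc tests) are intentionally
  absent; the package emits tidy per-fly tables for any standard tool.

## Problem sizes in the test suite

The suite simulates cohorts of 100 flies for 10 min per condition for the
valence and palatability grids (an hour-long assay reaches the same
conclusions; 10 min keeps the full grid to a couple of minutes of compute
and the preference plateau is largely established by then), 30 flies for
the feeding-loop regime, and ten 60-min flies per valence for the
settling analysis. Grids are compared with common random numbers — the
same per-fly seeds under every condition — which is the standard paired
variance-reduction design; without it, adjacent grid means that differ by
~0.01 in PI would need cohorts an order of magnitude larger to order
reliably. Trigger properties are checked on 1,000 random traces of 2,000
samples against the brute-force oracle.

## Worked example

```{r example, eval = FALSE}
library(OptoFeed)

## one appetitive fly, 10 minutes
exp <- simulateFly(FlyParams(), OptoParams(valence = 2, intensity = 11.26),
                   NoiseParams(), durationS = 600, seed = 1)
interactionCounts(exp)

## a small control cohort shows no side bias
co <- simulateCohort(20, FlyParams(), OptoParams(valence = 0),
                     NoiseParams(), durationS = 600, baseSeed = 100)
res <- excludeLowInteractionFlies(cohortResults(co))$kept
groupSummary(preferenceIndex(res$n_light, res$n_dark))

## trigger vs sip caller on a simulated hour
mh <- fixtureExperiment("mixed_hour")
sips <- callSips(traces(mh)[[1]])
compareAlgorithms(binCounts(sipOnsets(sips), 3600),
                  binCounts(interactionOnsets(lightingLog(mh)), 3600))
```
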