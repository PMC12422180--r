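---
title: "Speed-selective closed-loop stimulation at desk scale: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-selective closed-loop stimulation at desk scale: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinestim)
```

## The experiment this package emulates

In a motor state-dependent deep brain stimulation paradigm, a patient moves a
pen between rectangles alternating across a tablet screen while a real-time
controller tracks cursor speed, classifies each reach as *fast* or *slow*
relative to the previous two reaches, and delivers a brief (300 ms, 130 Hz)
subthalamic stimulation burst when the ongoing movement matches the block's
target class. Sessions comprise four 96-movement blocks: stimulation in
blocks 1 and 3 (one fast-targeting, one slow-targeting, order balanced
across subjects), recovery without stimulation in blocks 2 and 4. The
scientific questions are whether stimulating fast movements counteracts the
bradykinetic within-block speed decline more than stimulating slow
movements, whether stimulation shifts the speed of the following
same-direction movement toward the speed of the stimulated one, and how the
bursts modulate sensorimotor beta-band (20--35 Hz) activity.

`kinestim` rebuilds this pipeline end to end on synthetic data so that every
stage -- the generator, the controller, the behavioural statistics, and the
spectral analysis -- is testable without any recording.

## The synthetic-data generator

### Targets

Targets alternate strictly between the left (x = 100 px) and right
(x = 1820 px) screen edge at one of four y positions (390, 465, 615,
690 px). With four start and four end heights per direction there are 32
trajectory classes; a seeded random Eulerian circuit over the class
multigraph yields a pseudorandomised 96-movement block in which every class
occurs exactly 3 times, while the side alternation is preserved across
block boundaries.

### Kinematics

Each reach follows a minimum-jerk speed profile, $s(\tau) \propto
\tau^2(1-\tau)^2$ on the normalised movement span -- the standard unimodal
shape of point-to-point reaching, and the simplest profile satisfying the
online detector's rise-then-fall assumption. The true peak speed of the
$i$-th movement of a block is

$$v_i = v_0\,(1-d)^{\,i-1}\,\varepsilon_i, \qquad
  \varepsilon_i \sim \text{lognormal with mean } 1,$$

with $v_0$ = `peak_speed_start` (default 1800 px/s), a geometric
bradykinetic decrement $d$ (default 0.2% per movement, resetting at block
boundaries where the task pauses), and multiplicative noise with
coefficient of variation `noise_cv` (default 0.10). Durations are drawn
from N(0.812 s, 0.115 s), the cursor is sampled at 62 Hz, and additive
Gaussian position noise (default SD 2 px) emulates digitiser jitter.
Movement amplitude follows from the minimum-jerk identity
$D = 16\,vT/30$, so the synthetic reach is anchored at the alternating
sides without being forced to traverse the full screen; this keeps the
decrement law on true peak speeds exact to machine precision, which the
tests exploit.

Movements are separated by a 350-ms rest during which the cursor holds its
position; a trial consists of its pre-movement rest plus the movement.

### Reinforcement injection

When a protocol is supplied, the generator runs an idealised two-back
classifier on the true peak speeds and flags stimulated movements. A
stimulated movement $k$ multiplies the *next same-direction* movement's
target peak speed (movement $k+2$, since targets alternate) by
$1 + \delta\,\mathrm{sign}(v_k - \text{trend}_k)$: reinforcement pushes the
follower in the direction of the stimulated movement's deviation from the
decrement trend. Ground truth records every factor, which makes three
things measurable downstream: the realized injected effect (the sign rule
dilutes the nominal $\delta$, since a classified-fast movement is not
always above trend), stimulation chains (a follower that is itself
stimulated later -- about a quarter of stimulated movements carry an
earlier injection), and the exact causal effect of the injections on any
statistic via counterfactual bookkeeping (`injected_change_targets()`
recomputes follower changes with all factors removed, on the noiseless
trimmed-average-speed map `minjerk_trimmed_average()`).

### What the generator does not emulate

No biomechanics, reaction times, curved trajectories, secondary
sub-movements, fatigue beyond the geometric decrement, or learning beyond
the reinforcement term. Position noise is white; real digitiser noise may
be correlated. Consequently, green tests show that the *analysis machinery*
is correct and calibrated under the stated statistical structure -- not
that real patient data would yield the same effect sizes.

## The closed-loop controller

The controller mirrors the deployed algorithm sample by sample:
instantaneous speed (Euclidean step over elapsed time), a causal trailing
mean over the last six samples, and online peak detection. The default
detector declares the peak at the first strictly decreasing run of three
consecutive smoothed values lying entirely after the running maximum (ties
interrupt the run); the online peak speed is the maximum seen so far. The
alternative timer-based detector reads the peak once the elapsed time since
movement initiation reaches a calibrated latency percentile (default: the
80th percentile of familiarization peak latencies, linear-interpolation
convention). Classification is strictly two-back: fast if the online peak
exceeds both previous peaks, slow if below both, intermediate otherwise;
the comparison window resets at block boundaries, so the first two
movements of every block are unclassified and never stimulated.

Two implementation choices deserve notice. First, the detector is *armed*
only once the smoothed speed exceeds a movement threshold (default
800.77 px/s, the 3-SD rest-based constant): during the intertrial rest,
differentiated position noise otherwise produces spurious
three-decreasing runs at near-zero speeds. Second, if a movement ends
without a detection, its peak is read out at movement end for bookkeeping,
but no burst is emitted.

### Fidelity under noise

On noiseless sessions (no peak-speed noise, no position noise, constant
durations, nonzero decrement) the controller reproduces the offline oracle
exactly: 100% label agreement and an identical stimulated set. Constant
durations matter because six-sample smoothing attenuates the peak by a
duration-dependent factor (~1%); with exactly equal peaks the strict
two-back rule is degenerate. Under the default noise conditions the
smoothed-maximum estimator carries about 1.4% multiplicative error (mostly
differentiated position noise), and agreement with ground-truth labels
settles near 91% over 50 sessions: classification boundaries are ties, so
even small estimator noise is costly. A ceiling analysis (labels from true
peaks versus labels from noise-perturbed true peaks) shows agreement of
96% would require estimator noise below about 0.6%, which the prescribed
6-sample differentiation of 2-px-noise positions cannot deliver; the
96% figure is attainable only when online labels are compared against an
offline analysis of the *same* recorded data, where estimator noise is
shared. Detection latency is bounded below by three sampling intervals
(48.4 ms at 62 Hz) plus the smoothing group delay, giving mean latencies
near 116 ms on synthetic profiles.

## Offline behavioural analysis

The offline pipeline operates on the same six-sample smoothed speed
readout as the controller -- deliberately, because the recovery-block
classification reuses "the same algorithm", and because using a noisier
peak estimator for the reference selection than for the online selection
visibly biases the matched subtraction described below.

Per movement: the peak sample is located, onset and offset are the first
and last samples of the contiguous above-threshold run containing the peak
(robust to secondary sub-movements), and the average speed between onset
and offset is the main outcome. Block-level analysis excludes the first
five trials, treats average speeds above 2413.35 px/s as missing
(outliers), and normalises to the mean of the block's first five
movements; recovery blocks are normalised to the start of the preceding
stimulation block. Both thresholds can be recomputed from a cohort via the
3-SD definitions (`compute_rest_threshold()`).

The post-stimulation shift contrasts, per condition, the percent change of
the two movements following each stimulated movement (follower 1 is the
opposite-direction movement, follower 2 the same-direction one) against the
identical quantity for not-stimulated movements of the same speed class
identified post hoc in the paired recovery block. Because classified-fast
movements are locally extreme, raw follower changes are negative after
fast and positive after slow anchors even under the null (about ∓8%); the
matched subtraction cancels this regression to the mean, which the tests
verify on null cohorts. Followers crossing a block boundary are dropped;
cells without reference movements are reported as missing, never zero.
Cohort-level inference aggregates one value per subject per condition and
tests at the subject level, matching the within-subject design.

A recovered shift is benchmarked against the counterfactual injected
effect rather than the nominal $\delta$: threshold trimming compresses a
5% peak-speed change to about 3.9% on the average-speed scale, the sign
rule dilutes by the average sign, and stimulation chains contribute a real
causal component -- all of which the bookkeeping target includes.

## Permutation machinery

All tests are two-sided. Paired and sign-flip tests build the null by sign
flips of per-subject values; the independent test shuffles group labels;
all switch to exact enumeration when the permutation space fits within the
requested count (then $p = b/m$), and otherwise use Monte Carlo with the
add-one correction $p = (b+1)/(n+1)$, which keeps $p \ge 1/(n+1)$.
Equality of a Monte-Carlo statistic with the observed one is decided up to
a square-root-machine-epsilon tolerance so that enumerated ties are
counted.

The cluster test forms point-wise Welch $t$ statistics, thresholds them at
the two-sided $\alpha$ quantile with Welch degrees of freedom (the
cluster-forming rule, chosen here as the field default), sums $|t|$ within
maximal contiguous supra-threshold runs, and compares each cluster mass to
the permutation distribution of the maximal mass, which controls the
family-wise error. Time points removed upstream (see the masked-epoch rule)
break contiguity, so clusters cannot bridge them.

## Artifact-aware beta-power analysis

Synthetic sensorimotor epochs are 2 s long, centred on the peak-speed
time: a 1/f background plus a beta oscillation whose amplitude dips around
the movement and rebounds afterwards. Stimulated trials additionally scale
beta amplitude inside the peri-stimulation (0.13--0.3 s) and
post-stimulation (0.41--1.0 s) windows by the injected effect sizes and
carry high-amplitude transients at the burst on/offset times. The
synthetic sampling rate is 1000 Hz -- ample for a 45-Hz analysis ceiling
and far cheaper than clinical-amplifier rates.

The analysis chain: common average reference (excluding poor-quality
channels), epoching, Morlet transform with four cycles (unit-energy
wavelets; samples whose wavelet support of 3.5 temporal SDs leaves the
epoch are masked), z-scoring per trial and frequency against the -400 to
-100 ms baseline, speed-matched sampling of not-stimulated trials (greedy
nearest neighbour in descending stimulated speed, accepted only if an
independent permutation test on peak speed is non-significant), and
masking of ±65 ms around every stimulation edge. For the cluster test,
time points with fewer than 15% masked epochs are median-filled across
epochs; time points at or above 15% are excluded. Linear interpolation
across masked spans exists solely for visualization
(`interpolate_masked()`); no statistic touches interpolated values.
Window statistics are missing-value-aware per-trial means over 20--35 Hz,
compared between groups with the independent permutation test.

## Numerical and design choices

* Strict inequalities everywhere in classification and detection; ties
  yield `intermediate` or interrupt a run. Continuous synthetic speeds
  make exact ties null sets; degenerate constant-speed inputs are the
  documented exception.
* Percentile convention: linear interpolation between order statistics
  (`stats::quantile` type 7), applied uniformly.
* The first-five exclusion is applied to every block, including recovery
  blocks, for uniformity.
* Stimulation metadata (frequency, pulse width, amplitude) are carried but
  never modelled electrically; "bilateral" stimulation is a single event
  stream.
* The 15% masked-epoch rule replaces below the threshold and excludes at
  or above it.
* Seeds propagate through every stochastic stage; the RNG state of the
  caller is saved and restored, so identical inputs and seeds give
  bit-identical outputs.

## Problem sizes used by the checks

The calibration and recovery checks run at desk scale, chosen to give
stable Monte-Carlo estimates: 1,000 blocks for the percentile-placement
simulation, 50 sessions for online/offline agreement, 2,000 null cohorts
of 24 subjects (1,000 permutations each) for the type-I error of the
paired test, 20 subjects per reinforcement level for shift recovery, 59
trials per group for the spectral effect detection, and 100 replicates of
60 trials for the spectral null calibration.

## Known limitations

* The synthetic generator's effect sizes are conventions, not estimates;
  magnitudes from real sessions are not reproducible here and are not
  claimed.
* Online/offline agreement against *ground-truth* labels saturates near
  91% under the default noise; see the fidelity discussion above.
* The cluster statistic is the independent two-sample sum-|t| variant;
  paired or max-t variants would need small extensions.
* Single-channel spectral analysis only; no source modelling,
  connectivity, or decoding.
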