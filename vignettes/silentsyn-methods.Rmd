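---
title: "Models and methods behind silentsyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind silentsyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

silentsyn implements the quantitative procedures used to characterize
AMPA-silent synapses and experience-dependent visual-cortex plasticity:
minimal-stimulation failure-rate analysis, event-based synaptic assays,
Fourier analysis of periodic-stimulus intrinsic-signal movies, fluorescence
puncta quantification, and visual-water-task psychophysics. Because raw
recordings of this kind are rarely deposited, every analysis stage is paired
with a synthetic-data generator with known ground truth; the package's tests
and the `analysis/` drivers are recovery studies against that ground truth.
This vignette explains the models, the defaults, and the choices made where
the methods literature leaves the design open.

## The silent-synapse estimator

A glutamatergic axon contacts a cortical pyramidal neuron through a handful
of synapses — about five on average in layer 4 to layer 2/3 pathways. A
fraction *s* of these may be AMPA-silent: they carry NMDA-receptor current
(visible at +40 mV) but no AMPA-receptor current (invisible at −60 mV).
Under minimal stimulation, with per-synapse release probability *p* and
*N* synapses of which *N~a~* are AMPA-active, the evoked response fails

* at −60 mV when no AMPA-active synapse releases: $F_{-60} = (1-p)^{N_a}$,
* at +40 mV when no synapse at all releases: $F_{+40} = (1-p)^{N}$.

Taking logarithms and dividing eliminates *p*:

$$\hat{s} \;=\; 1 - \frac{\ln F_{-60}}{\ln F_{+40}} \;=\; 1 - \frac{N_a}{N}.$$

`silent_fraction()` implements exactly this. Three properties matter in
practice and are enforced by tests:

* **Identity.** For exact binomial failure probabilities the estimator is
  exact for every $p \in (0,1)$ — the package checks this to $10^{-12}$
  over a grid of $p$, $N \le 10$.
* **Monotonicity.** At fixed $F_{+40}$ the estimate is strictly increasing
  in $F_{-60}$ ($\partial\hat{s}/\partial F_{-60} = -1/(F_{-60}\ln F_{+40})
  > 0$): more AMPA failures mean more silent synapses.
* **Negative estimates are data.** Sampling noise in the two empirical
  failure rates can push $\hat{s}$ below zero, most visibly when the true
  fraction is near zero. Estimates are reported and averaged unclipped;
  clipping at zero would bias cohort means upward. Cells with a failure
  rate of exactly 0 or 1 give the estimator no value; they are flagged,
  excluded from silent-fraction means, and retained for potency and
  success-rate summaries.

`analyze_cell()` derives the two failure rates from classified trials,
synaptic potency (mean success amplitude at −60 mV, failures excluded) and
success rate $1 - F_{-60}$.

### Success/failure classification

Interactive workflows score successes visually. The algorithmic surrogate
here calls a trial a success when its peak inside a potential-specific
response window exceeds `k_sd` (default 3) times the baseline RMS. The
−60 mV window (1–20 ms post-stimulus) brackets the fast AMPA component;
the +40 mV window (5–60 ms) extends over the slow NMDA component because
the +40 mV trace is a composite AMPA+NMDA response. Both windows and
`k_sd` are configurable. With quantal amplitudes several times the
baseline noise — the regime minimal stimulation is tuned for —
classification agrees with generator ground truth at better than 99%.

### Generator

`simulate_minstim()` draws, per trial, a binomial number of releasing
synapses and sums gamma-distributed quantal amplitudes (mean/CV
parameterization; the gamma was chosen for positive support, as no quantal
distribution is prescribed by the assay). The realized silent count is
`round(n * s)` and ground truth stores the realizable fraction, so recovery
is judged against an attainable target at small *n*. NMDA quanta of silent
and AMPA-active synapses are identically distributed — the estimator's
derivation implicitly assumes equal NMDA detectability. Defaults: quantal
means 12 pA (AMPA) and 10 pA (NMDA), CV 0.3, baseline noise 1 pA. Trial
counts per holding potential are a free parameter of the protocol; the
recovery studies use 200 per potential, and 50 is a realistic lower bound
for real recordings.

## Event-based assays

**mEPSC detection.** The detector thresholds a causally boxcar-smoothed
(2 ms) signal at 3 robust noise SDs (median/MAD of the smoothed trace),
requires at least 2.5 ms above threshold — isolated noise excursions are
too brief — and merges events within a 5 ms refractory interval, keeping
the larger peak. Event time is region onset; amplitude is baseline-to-peak
on the raw trace. The published assays do not document their detectors, so
this one is explicitly a surrogate with all knobs exposed. At SNR 5 it
reaches ≥95% sensitivity and precision against generator event lists. Known
bias: taking the raw-trace maximum over the detection region overestimates
amplitudes by roughly the expected maximum of the in-window noise (about
1–2 SD), which cancels in within-pipeline comparisons but should be kept in
mind when absolute quantal sizes matter.

**400-event/20-bin cumulatives.** Per cell, the first 400 values (in
recording order, for determinism) of amplitude or inter-event interval are
sorted and cut into 20 rank bins of 20 values; bins are summarized by their
means and averaged across cells. Rank bins — rather than equal-width bins —
are the natural reading of "sorted … and binned", make the bin populations
equal, and give an exact conservation law (the mean of a cell's bin means
equals its overall mean), which the tests check to $10^{-12}$. Equal-width
binning remains available as an option. A cell needs 400 values of the
*binned variable*, so IEI binning requires 401 events; short cells are
excluded and logged, never silently padded.

**Paired-pulse ratio.** The tail of response 1 under response 2 is removed
by fitting a double exponential to the post-peak segment of response 1 and
extrapolating it across the second response window. The single-trace fit
was preferred over a paired-average blank because it applies to individual
sweeps; with the default kinetics it recovers the second amplitude within
1% in the noiseless overlap case, and the ratio is invariant to uniform
gain.

**MK-801 decay.** With an open-channel NMDA-receptor blocker, a synapse
that releases is lost to subsequent sweeps, so the expected normalized peak
at sweep *k* is $(1-p)^{k-1}$. Cohort series are averaged sweep-wise
*before* normalization (a single noisy first sweep is a poor normalizer),
then fitted with $a\,e^{-bk}$ by iteratively reweighted least squares with
weights $1/\max(\hat{y}, 0.01)$ — the sweep-mean variance scales with its
mean, as in quantal counting noise — and the per-sweep survival $e^{-b}$ is
reported as the proxy for $1-p$. A flat series (nothing releases) is
flagged degenerate rather than fitted.

**Sr²⁺ quantal analysis.** Strontium substitution desynchronizes release;
each releasing synapse emits its quantum at a uniform random latency in the
post-stimulus window (default 500 ms), making single quanta resolvable in
the stimulated pathway. The analysis reuses the mEPSC binning machinery and
reproduces the generator's quantal mean; evoked and spontaneous quantal
distributions with identical parameters are statistically indistinguishable.

## Fourier maps and ocular dominance

For a continuously presented temporally periodic stimulus, each pixel's
reflectance series is modeled as $A\cos(2\pi f_{stim} t - \phi) +
\text{drift} + \text{noise}$. `fourier_extract()` regresses each series
jointly on an intercept, a linear trend and the cosine/sine pair at the
stimulus frequency. The joint fit is deliberate: projecting after separate
detrending lets the trend leak into the quadrature pair (and vice versa),
which is visible as a percent-level amplitude bias even in noiseless data;
the joint fit is exact there. Amplitude is the modulus of the quadrature
coefficients — identical to the classical $2/T$ Fourier projection over
whole cycles — and phase is their argument wrapped to $[0, 2\pi)$.
Acquisition at 30 Hz is reduced to 7.5 Hz by non-overlapping 4-frame
means (`temporal_bin()`), with any trailing remainder dropped and logged;
a sinusoid is attenuated by the known Dirichlet factor of boxcar
averaging, negligible at stimulus frequencies far below Nyquist.

Ocular dominance uses the raw response magnitudes of the two eyes:
per responsive pixel, $\text{OD} = (C-I)/(C+I) \in [-1, 1]$, and the ODI
is the mean OD score over the responsive region (positive = contralateral
dominance). Run ODIs are grouped into consecutive blocks of four runs, one
ODI per block; animals with fewer than three block ODIs are discarded, and
the animal's value is the mean of its block ODIs. What counts as
"responsive" is not standardized in the source methods; the default mask
keeps pixels whose contra *or* ipsi amplitude exceeds 30% of the
99th-percentile contra amplitude — scale-free, robust to hot pixels, and
fully overridable with an explicit mask. Pixels with $C + I = 0$ are
excluded rather than producing 0/0.

Map scatter quantifies retinotopic smoothness as the mean absolute circular
difference between a pixel's phase and the circular mean phase of its
surrounding neighborhood (5×5 by default, center excluded). The exact
published map-quality formulas are not restated in the methods this package
follows, so this statistic is a labeled surrogate with the right limits: ≈0
for a locally planar map and ≈π/2 for i.i.d. uniform phases. Circular means
(mean resultant direction) are used wherever phases are averaged, since
arithmetic means are wrong near the wrap point. Phase maps are reported in
radians; conversion to visual-field degrees requires stimulus geometry and
is out of scope.

The movie generator renders the cosine model with Gaussian noise and an
optional 1/f (pink) temporal component, off by default: the analyzer only
needs the stimulus-frequency component, and hemodynamic filtering is not
modeled. The recovery studies use 64×64 movies, 600 frames at 7.5 Hz
(10 stimulus cycles at 0.125 Hz), amplitude-to-noise 10.

## Puncta, colocalization, density

Semi-thin (0.5 µm) section immunofluorescence is emulated as disk-shaped
puncta on a jittered grid (so distinct puncta never touch) across three
channels (Munc13-1 and the PSD-93/95 paralogs), with a controlled fraction
of paralog puncta co-placed on Munc13-1 puncta. Segmentation thresholds by
intensity (Otsu by default; the interactive workflows this mirrors used
manual intensity choices, so an absolute threshold is also available),
labels connected components, and discards objects under 200 px² — at the
6 nm reference pixel size, about 7,200 nm². Manual splitting of fused
puncta is replaced by an optional watershed.

The colocalization rule — overlap greater than 5% — names no denominator in
the methods it follows. The smaller punctum's area is used here so that the
rule is symmetric between channels (a matched to b iff b matched to a);
alternative denominators are available. Each punctum matches at most one
partner, greedily by decreasing overlap fraction with ties broken by label
order. Synapses are matched Munc13-1⁺/paralog⁺ pairs, and density is their
count divided by imaged area × section thickness; 20 synapses in a
10.13 µm × 10.13 µm × 0.5 µm volume give the reference ≈0.39 µm⁻³.
Border-touching puncta are not excluded; at the simulated densities this
is immaterial, but it is a configurable point for real images.

Western-blot band intensities are normalized per blot and protein to the
mean of that blot's control samples, making the control mean 1 by
construction and the output invariant to per-blot gain; rows lacking a
control on their own blot are flagged and excluded.

## Visual water task

The two-alternative observer has accuracy
$\gamma + (1-\gamma-\lambda)\,\text{logistic}(\beta x)$ with guess rate
$\gamma = 0.5$, lapse rate $\lambda$, and $x$ the signed distance from
threshold in the task's difficulty direction (rising spatial frequency for
acuity; shrinking orientation difference, tested in 5° steps from 90°, for
discrimination). Sessions test levels in protocol order with a fixed-size
trial block per level, stopping after the first block under 70%. Thresholds
are step-quantized: the acuity threshold is the *highest* spatial frequency
with block accuracy ≥70% (inclusive), the orientation threshold the
*smallest* passing angular difference. Non-monotone level performance
(pass–fail–pass) takes the extreme passing level, with a logged note.

Block size is not prescribed by the task description; the function default
is 10 trials, and the recovery studies use 40 trials per level, chosen by a
binomial power calculation so that a chance-level block passes the 70%
criterion with probability below 1% (at 10 trials it passes ≈17% of the
time, which no staircase summary survives). The recovery observers place
the true threshold between grid levels (0.47 cycles/degree on a 0.05-step
grid; 23° on the 5° grid): with threshold exactly on a tested level the
psychometric function passes through ≈ the criterion there and the
recovered level is intrinsically ambiguous. Learning is summarized
separately as the first block reaching 90% accuracy, and the looming assay
reduces to a response fraction over at most three presentations.

## Reproducibility and problem sizes

Every generator consumes the R RNG, so `set.seed()` makes any stage
bit-reproducible; `run_pipeline()` derives per-stage seeds from one master
seed (counter-based, `derive_seed()`) so stages can be rerun independently,
and writes a provenance manifest with MD5 hashes of config and outputs.
Tables are UTF-8 CSV with units in column names; movies and multi-channel
images travel as 32-bit TIFF stacks with a JSON sidecar carrying frame
rate, stimulus frequency and the value scale (reflectance values are
signed, so stacks are min/max-normalized with the scale recorded).

The recovery studies were sized to keep every property measurable at desk
scale while leaving Monte-Carlo error well inside the tolerances quoted
above: 200–300 cells × 200 trials for estimator recovery, 100 cells × 50
sweeps for MK-801, 64×64×600 movies, 200 sessions for psychophysics. The
package is organized as an analysis workflow — numbered drivers under
`analysis/` that narrate one study each and write tables under `results/` —
over a conventional R package in `R/` where every computation lives and is
unit-tested.

## What the synthetic data do and do not show

The generators emulate the *statistical* structure of each raw-data type:
binomial multi-synapse release, Poisson event trains with gamma quanta,
periodic cortical responses with retinotopic phase gradients in Gaussian
(optionally pink) noise, disk puncta with controlled overlap, and a
Bernoulli psychometric observer. They do not model conductance-based
biophysics, dendritic filtering, hemodynamics, vessel artifacts,
anisotropic punctum shapes, or sequential-dependence in behavior. Passing
recovery tests therefore demonstrates that the estimators are correct and
well-calibrated *under their own model assumptions* — binomial release with
uniform p, equal NMDA quantal visibility, sinusoidal single-frequency
responses — not that those assumptions hold in any particular preparation.
Where real data violate them (e.g., heterogeneous release probabilities
inflating the failure-rate estimator's bias, or correlated noise in
intrinsic-signal movies), the generators provide the natural place to probe
sensitivity by construction.
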