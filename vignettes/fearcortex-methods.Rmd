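---
title: "Methods: discriminability, learning specificity, and the thalamo-cortico-amygdala model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminability, learning specificity, and the thalamo-cortico-amygdala model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearcortex)
```

# The scientific problem

In differential fear conditioning (DFC), an animal learns that one tone
(the CS+, here 15 kHz) predicts a foot-shock while a nearby tone (the
CS-, 11.4 kHz, 0.4 octaves away) is safe. Mice differ widely in how
*specific* their learned fear is: some freeze only to the CS+, others
generalize to the CS-. This package implements the analysis chain that
asks whether the state of auditory cortex *before* learning predicts that
individual difference, and a small circuit model that explains why the
prediction holds before but not after conditioning.

The package operates on trial-response tables (neuron x frequency x
repeat scalars derived from two-photon calcium imaging), motion-index
traces from retrieval sessions, and ROI scenes for longitudinal cell
tracking. A synthetic-cohort generator produces all three with a
programmed ground truth, so every statistic in the chain can be validated
against known parameters.

# Behavioral scoring

The motion index is the mean grayscale difference between consecutive
video frames (3.75 Hz). Freezing is motion strictly below the session's
**12.5th percentile** of motion-index values; the percentile uses linear
interpolation between order statistics (R's default type-7 convention --
no convention is standard in the field, so we fix one and document it).
Ties count as moving, which makes a constant trace score 0% freezing.

Per-trial freezing fractions feed the learning-specificity score

$$LS = \frac{1}{N}\sum_i fr_{CS+}(i) - \frac{1}{N}\sum_i fr_{CS-}(i),$$

a signed fraction in $[-1, 1]$ (reported in percent where convenient).
Mice that freeze to neither CS are excluded by a per-mouse two-way ANOVA
(factors: stimulus CS+/CS-, and period stimulus/baseline); a *learner*
shows a significant main effect of period or a period-by-stimulus
interaction at $p < 0.05$.

A consequence of percentile thresholding worth stating: if motion values
are continuous, exactly 12.5% of a session's samples fall below the
threshold, so the method can only score freezing accurately when (a) the
two motion states are separated by a gap and (b) session-wide freezing
occupies less time than the percentile mass. Real motion indices satisfy
(a) through their strongly bimodal histograms and a quantization floor
during movement. The synthetic generator reproduces exactly this regime:
a low-motion state below 0.25, a moving state at or above 1 with an atom
at the floor, and retrieval schedules (4 CS+ and 4 CS- trials of 30 s,
90-s intervals) whose expected freezing occupancy stays near 10%. Within
that regime the generator's round trip recovers programmed freezing
fractions to well within 5 percentage points; outside it (e.g., a session
that is mostly freezing) the threshold convention itself breaks down, for
real data as much as for synthetic.

# Single-neuron statistics

Responses are $\Delta F/F_{std}$: fluorescence minus the mean of the 1-s
pre-stimulus baseline, divided by the baseline SD, averaged over the 2 s
after tone onset. Presentations with zero baseline variance are flagged
degenerate and excluded rather than propagated as infinities.

* **Responsiveness**: one-sample t-tests per frequency against zero,
  Holm-corrected across the (typically 12) frequencies; responsive if any
  corrected $p < 0.05$.
* **Frequency response function (FRF)**: mean response per frequency;
  best frequency (BF) is the argmax, with ties broken to the lowest
  frequency for determinism.
* **Sparseness**: $a = (\sum r_i/N)^2 / (\sum r_i^2/N)$,
  $S = (1-a)/(1-1/N)$ -- 0 for a flat positive FRF, 1 for one-hot.
  Negative responses are kept as printed, so $S > 1$ is possible and is
  returned unmodified.
* **Discriminability**:
  $Z_{diff} = |\bar r_{CS+} - \bar r_{CS-}| / \sqrt{\sigma_{CS+}\,\sigma_{CS-}}$
  with sample SDs (n-1). Significance: the observed score must exceed the
  95th percentile of 250 full relabellings of the pooled trials
  (unpaired exchangeable null; strict inequality).
* Sessions without the exact CS frequencies are interpolated linearly on
  the **log2-frequency axis**, because the stimuli are log-spaced and all
  tuning distances are reported in octaves.
* Plasticity metrics: FRFs are normalized by their maximum (the
  normalization is isolated in one function so it can be swapped),
  percent change is $100(post-pre)/|pre|$ per frequency, and BF distance
  from the CS+ is $|\log_2(BF/15\,\mathrm{kHz})|$ octaves. A 12-bin BF
  resampling utility equalizes BF distributions across groups; empty bins
  are skipped with a warning.

# Population decoding and inference

CS+/CS- decoding uses a linear-kernel SVM (cost 1, the libsvm default)
with stratified 10-fold cross-validation; features are standardized with
training-fold statistics only, and fold accuracies are averaged. Because
mice contribute different neuron counts, per-mouse metrics are computed on
100 resamples (with replacement) of $n^*$ neurons, where $n^*$ is the
cohort's minimum count.

Rank correlations (Spearman, average ranks for ties) get percentile
bootstrap CIs from 1000 joint resamples of the (x, y) pairs. The
correlation flavor *inside* the bootstrap defaults to Spearman for
internal consistency with the point estimate; a Pearson mode is provided
because resampled ranks and raw values genuinely differ and both
conventions are in circulation. Differences between two correlations over
the *same* mice use paired bootstrap replicates (shared resample indices);
the difference is significant when the 95% CI of the delta distribution
excludes zero, with a two-sided $p = 2\min(P(\Delta\le 0), P(\Delta\ge 0))$.

# Longitudinal ROI tracking

Sessions are registered by a least-squares affine transform fitted to
landmark pairs (at least 3 non-collinear; affine covers the
translation/rotation/scale/shear of field-of-view realignment). Each new
ROI is matched to the nearest reference centroid; pairs are flagged for
review when two new ROIs claim one reference ROI, when mask overlap
(intersection over the smaller mask) falls below 80%, or when the
centroid distance exceeds the matched mean by more than 2 SDs (with a
0.5-px floor so floating-point noise in well-aligned scenes cannot trip
the rule). Accepted matches are injective by construction. Multi-session
merging aligns everything to session 1, grows a cumulative catalogue with
new cells, and finally drops catalogue entries whose mutual overlap
exceeds 50% (configurable; the field reports no standard number), since
those cannot be attributed to a single cell.

# The synthetic cohort generator

The generator is the package's test bed and defines the study conditions:
14 conditioned + 9 pseudo-conditioned mice, 60-120 neurons per mouse, 12
log-spaced tones (5-32 kHz, including both CS frequencies exactly), 25
repeats, 8 sessions, and 4 retrieval sessions of motion traces.

Each neuron has a Gaussian tuning curve in log2-frequency (width 0.5-1.5
octaves, amplitude 2-5 $\Delta F/F_{std}$; 20% of neurons are silent, so
the responsiveness filter has work to do). A per-mouse
**discriminability gradient** $g \in [0,1]$ fixes the fraction
$0.1 + 0.6g$ of responsive neurons that are CS-tuned: BF exactly at the
CS+ or CS- with a narrow width (0.2-0.35 octaves). This is what separates
the population's responses to the two conditioned tones. The CS-tuned
count is set deterministically from $g$ (not binomially), so the
programmed monotone link between gradient and separation is not blurred
by composition noise.

Trial variability has three components: independent Gaussian noise
(SD 1), a population-wide log-normal gain shared by all neurons within a
trial (SD 0.3), and a shared fluctuation along the population's CS+/CS-
signal direction (SD 6 across the population). The last term implements
information-limiting correlations: without it, a linear decoder over ~100
independently noisy neurons is at ceiling for every mouse and the
decoder-vs-$Z_{diff}$ comparison degenerates. With it, per-mouse SVM
accuracy spans roughly 0.55-0.95, the range real cohorts occupy.

Ground-truth learning specificity is a logistic function of the
population separation $s$ (in noise-SD units):
$LS = 0.65\,\mathrm{logit}^{-1}(4(s - 1)) + \varepsilon$,
$\varepsilon \sim N(0, 0.05)$, which places conditioned-mouse LS in
roughly 0.1-0.6 with a spread comparable to real cohorts (where the
conditioned-group SD is about 20 percentage points); pseudo-conditioned
mice get $LS = \varepsilon$, centred at zero. The centre and slope were
chosen once from the generator's own separation statistics and are
documented here rather than tuned per analysis. Session-to-session drift
is a cumulative Gaussian random walk on each neuron's BF (octaves) and
log-gain (SD 0.05/session by default) -- deliberately mechanism-agnostic,
just enough structure to support the drift analyses.

What the generator does *not* emulate: calcium-indicator dynamics,
neuropil contamination, burst statistics, non-Gaussian noise tails,
neuron dropout across sessions, or any anatomical structure. Passing
tests therefore validate the *analysis chain* under known ground truth,
not the biology of any particular dataset.

# The circuit model

Ten frequency channels feed the auditory thalamus (MGB), which feeds
auditory cortex (AC); both project to a basolateral amygdala (BLA)
readout whose activity is the freezing propensity. Tuning is Gaussian on
a circular channel axis with the exponent $-d^2/(2\sigma)$ -- **sigma
enters unsquared**, exactly as the model is specified; this differs from
the conventional $2\sigma^2$ form and is kept deliberately. The MGB uses
$\sigma^{MGB} = 0.8$, gain 1, no inhibition. The cortex uses gain
$1/1.8$, subtractive inhibition $I^{ctx} = 0.9$ (rectified), and a width
$\sigma^{ctx}$ of 3 (narrow, discriminating) or 10 (broad,
generalizing).

The printed MGB and AC equations are mutually dependent (AC feeds back to
MGB). We resolve the loop as a single feedforward-then-feedback pass --
$x_0 = T^{MGB}s$, $x^{ctx} = T^{ctx}x_0$, $x^{MGB} = x_0 + x^{ctx}$ with
channel-matched feedback, consistent with tonotopically organized
corticothalamic projections -- and provide an optional fixed-point
iteration (tolerance 1e-8, 50 iterations) for sensitivity checks; at
these parameters the two agree closely because the feedback gain is
small.

Conditioning presents the CS+ (channel 3, one-hot) paired with a shock
for 10 steps; both pathways' BLA weights follow the Delta rule
$\Delta w_i = \alpha x_i e$ with $\alpha = 0.1$, bounds $[0,1]$, initial
value 0.1. Freezing is BLA activity normalized by the activity with all
weights at 1 under the same readout condition but with the *intact*
inhibition, saturated at 1. The saturation matters only when the readout
circuit is disinhibited relative to the normalizer, and it is what makes
the disinhibition manipulation generalize: the CS+ response ceilings
while the broadened weights raise the CS- response. Model learning
specificity is freezing(CS+) minus freezing(CS-).

After conditioning, $\sigma^{ctx}$ drifts for 10,000 steps as a uniform
$\pm 0.25$ random walk clipped to $[4, 20]$. The narrow initial width 3
lies below that band; the bounds apply only from the first drift step, so
conditioning runs at the printed narrow value. A zero drift amplitude is
a strict no-op (no clipping), so drift-free controls are exact. Channel
indices are 1-based throughout, matching the "channel 3 / channel 6"
convention.

The four experiments: **control**; **reduced inhibition**
($I^{ctx} = 0.45$ in the disinhibited circuit -- conditioning and the
readout numerator -- with the normalizer intact); **AC off during
conditioning** (cortical activity and feedback zeroed during learning
only); **AC off at recall** (cortex zeroed in the readout's numerator and
normalizer). The first three reproduce their experimental counterparts:
narrow tuning beats broad, and both disinhibition and cortical silencing
during learning reduce specificity. Recall inactivation changes
specificity by ~0.03, several-fold less than the other manipulations but
not exactly zero: the cortical pathway's contribution to the readout
cannot cancel exactly, because the thalamic and cortical weight vectors
learn at different rates and clip differently. We report the computed
difference rather than forcing it to vanish.

# Numerical choices and evaluation protocol

* All randomized routines take explicit seeds and restore the caller's
  RNG state; cohorts are bit-reproducible functions of their
  configuration.
* Degenerate cases are flagged (`NA` + documented semantics), never
  silent infinities: zero baseline SD, zero response SD in $Z_{diff}$,
  all-zero FRFs in sparseness, constant resamples in the bootstrap.
* BF ties break to the lowest frequency; the 95th-percentile permutation
  criterion uses strict inequality; Holm correction is the base
  `p.adjust` implementation.
* The evaluation protocol behind the test suite uses reduced problem
  sizes chosen to exercise every code path at adequate statistical
  power: 2000 neurons for the permutation-null calibration, 100 shuffle
  seeds for decoder calibration, 20 cohort seeds of 14 conditioned mice
  (4 sessions, default neuron counts) for the prediction analyses, 20
  seeds by 3 drift rates for the drift properties, 50 seeds for the
  model manipulations, and a 200-ROI scene (5 degree rotation, 1 px
  jitter) for tracking. The `analysis/` scripts run the full 23-mouse,
  8-session cohort.

# Known limitations

The generator's ground-truth link between neural separation and behavior
is programmed, not biological: it demonstrates that the pipeline recovers
such a link when present, not that cortex causes specificity. The
circuit model is a rate-based caricature -- no spiking, no learned
inhibition, no thalamic tuning plasticity -- and its learning-specificity
axis is normalized, so only orderings and relative changes are
meaningful. Tracking emits review flags rather than adjudicating
ambiguous matches, mirroring pipelines in which a human performs the
final check.
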