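---
title: "Odour-mixture summation and population coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Odour-mixture summation and population coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obmix)
```

# The scientific problem

Olfactory scenes are mixtures. When a mouse must report whether a target
odour (here labelled EB, with MB as its closest masker) is present in a
binary mixture, the usefulness of the olfactory bulb's output depends on
how mitral/tufted (M/T) cell responses to the mixture relate to the
responses to its components. If mixtures summed linearly, the target's
population pattern would simply add to the background's; saturating or
suppressive interactions corrupt that picture in an amplitude-dependent
way. This package implements the analysis chain used to study that
question with two-photon calcium imaging across brain states: transient
processing, summation-linearity statistics, population-similarity and
decoding analyses, a simulation isolating the effect of a saturating
("normalising") sublinearity, and Go/No-Go behavioural metrics — together
with a synthetic-session generator so the whole chain is testable without
any recorded data.

# Transients and response amplitudes

Acquisition follows the standard protocol: 400 frames at 30 Hz per trial
with stimulus onset (final-valve opening) at frame 200. `computeDff()`
defines each ROI's baseline F0 as its mean fluorescence over the 2 s
preceding onset and rescales the trace to (F − F0)/F0; trials already in
delta-F/F are passed through unchanged. `responseAmplitude()` averages the
delta-F/F over a window, by default the 1-s (30-frame) response period
starting at onset.

Conventions that the data formats leave open are fixed as: frames are
0-based; time is in seconds relative to onset; windows are half-open
[start, end), so the default window covers exactly frames
onset … onset+29. Time-resolved analyses
(`slidingResponseMatrices()`) use a causal 1-s window ending at each time
point, so a value at *t* summarises (*t* − 1, *t*]. Both the 30-frame and
20-frame window lengths that appear in amplitude analyses are supported
through the `window` argument.

# Summation statistics

For a binary mixture a+b, `linearSumPairs()` computes per ROI the
trial-averaged observed mixture amplitude and the linear sum of the
trial-averaged component amplitudes. Two deviation statistics quantify
nonlinearity:

* **Fractional deviation** `(R_obs − R_lin) / |R_lin|`
  (`fractionalDeviation()`): scale-free; negative values mean sublinear
  (suppressive) summation. Because the ratio is unstable near a zero
  linear sum, ROIs with |R_lin| below a configurable floor (default
  0.05 delta-F/F) are excluded and reported as such; the data themselves
  do not dictate a floor, so it is a documented analysis parameter.
* **Deviation from linearity** `(R_obs − R_lin) / (sem_obs + sem_lin)`
  (`deviationFromLinearity()`): the difference in units of the joint
  dispersion. The denominator adds the two s.e.m.s — a literal
  implementation of the printed formula; pooling variances instead would
  shrink the denominator by up to √2 and inflate the statistic. |value| > 2
  is classified nonlinear, < −2 sublinear (`classifyLinearity()`).

`medianFractionalDeviation()` summarises per field of view by the median
over included ROIs, and across fields by the median of field medians with
25th/75th percentiles, the boxplot convention used for time courses.

The **masking index** (`maskingIndex()`) works on glomerular single-odour
responses: trial-averaged target responses are z-scored across glomeruli
within a field, glomeruli with z > 2 form the target-responsive set, and
the index is the mean per-glomerulus overlap with a ceiling of 1 per
glomerulus. The overlap itself is stated in the source material only as
"average overlap, maximum 1"; we adopt the clipped amplitude ratio
clip(R_bg/R_target, 0, 1) with negative responses clipped to zero, and
expose the equivalent min(R_bg, R_target)/R_target formulation behind a
switch to make the interpretation explicit rather than silent.

## Noise robustness of the deviation distribution

`noiseRobustness()` probes how trial-to-trial variability shapes the
fractional-deviation distribution: zero-mean Gaussian noise of increasing
SD is added to trial amplitudes before averaging, and the per-ROI
deviations are recomputed over many repeats. The expectation is that
noise broadens the distribution while leaving its median approximately
unchanged — which is why a broader distribution in awake data need not
imply different summation.

Because the fractional deviation is a ratio, this invariance is exact
only to first order when noise also lands on the component trials: the
perturbed denominator induces a small systematic median drift (of order
(sem/R_lin)², empirically ~0.01–0.03 deviation units, about a tenth of
the distribution's IQR, at noise SDs of 0.3–0.6 delta-F/F on the default
synthetic sessions) and can mildly shrink the IQR at small SDs. With
`applyTo = "mixture"` the noise perturbs only the observed-mixture
trials; the numerator is then linear in the noise, broadening is exact
and the median is unbiased. The default remains `"all"` (the literal
procedure); the variant isolates the mechanism.

# Population similarity and discriminability

`trialCorrelationMatrix()` computes Pearson correlations between the
population (across-ROI) amplitude vectors of every pair of trials, with
trials partitioned into S+ (target-containing, single or mixture) and S−.
`classCorrelationSummary()` averages within-S+, within-S− and
across-class pairs, each unordered pair counted once.

The **discriminability index** (`discriminabilityIndex()`) uses
1 − Pearson correlation as the distance: for each S+ trial it compares the
mean correlation with the other S+ trials against the mean correlation
with all S− trials, and reports the fraction of S+ trials strictly closer
to their own class. Ties count as not discriminated; 0.5 is chance. Two
granularity choices are deliberate: the comparison is per-trial (means of
correlations, not correlations of means), and the across-class pool is
all S− trials rather than odour-matched subsets.

# Decoding

The decoder (`trainLinearDecoder()`) is a linear max-margin classifier
with its intercept constrained to zero, mirroring a linear SVM fitted
without a bias term: the decision is sign(w·x), invariant to uniform
scaling of the amplitudes. It minimises an L2-regularised squared-hinge
loss with BFGS; the penalty strength (default 1) is a fixed
regularisation choice, and a test verifies that separable-data accuracies
move by < 0.1 across a decade of that parameter. Exact zero decisions
classify as positive; with balanced classes this convention is neutral.

Two designs are provided. `randomSplitAccuracy()` trains on a random 80%
of trials and tests on the held-out 20% (stratification-free; a draw that
leaves either side single-class is redrawn, capped and logged), with the
same partitions reused across time points by default so time courses
reflect coding dynamics rather than split noise. The number of splits
defaults to 50. `crossGeneralizationAccuracy()` trains on single-odour
trials only (target vs. other singles) and tests on mixtures labelled by
target presence — the probe of whether mixture patterns resemble their
components.

`accuracySignificance()` marks the earliest window whose field-level mean
accuracies exceed chance by a one-sided t-test at alpha = 0.05 per window,
with no multiple-comparison correction — matching the source analysis and
documented as such. `ranksumZ()` implements the tie-corrected normal
approximation of the Wilcoxon rank-sum statistic without continuity
correction, and `ranksumZTimecourse()` applies it per time point to two
groups of decoding results.

A calibration caveat worth knowing: with a finite trial set, label
permutations leave train and test label frequencies negatively dependent,
so shuffled-label accuracies centre slightly below 0.5 (the usual
cross-validation null bias) and imbalanced designs push pre-onset
accuracies toward the majority base rate. Calibration checks therefore
use class-balanced trial lists (`balancedTrialList()`), where the shuffle
control sits within ±0.03 of 0.5 at ~100 splits on the default sessions.

# The sublinearity simulation

To isolate what a saturating sublinearity does to discriminability,
`simulateMixtureTest()` rebuilds the in-silico experiment: per time
point, a decoder is trained on the session's single-odour responses;
simulated mixtures are constructed by summing the trial-averaged
responses of every odour pair; uncorrelated Gaussian noise is added per
ROI with SD = sigma0 + slope·|amplitude| (`NoiseModel`); and, in the
sublinear condition, the noisy sums are passed through the saturating
transform before classification. Fresh noise is drawn for every
repetition (the alternative — one draw per trial-equivalent — only
rescales the number of effective repeats). The noise uses |amplitude| in
the scaling term since delta-F/F amplitudes can be negative.

The transform (`normaliseResponse()`) is
R* = Rmax·(2/(1+exp(−s·R)) − 1): odd, strictly increasing, bounded in
(−Rmax, Rmax), slope Rmax·s/2 at the origin. The reference parameter
point is Rmax = 6, s = 0.2 (delta-F/F and 1/delta-F/F respectively).
`fitNormalisation()` recovers the parameters from observed
(linear-sum, observed) pairs by unweighted Levenberg–Marquardt least
squares pooled over ROIs; when the data never probe the bend
(max |s·R_lin| < 1) only the product Rmax·s/2 is identified and the fit is
flagged unidentifiable. `fitNoiseSlope()` estimates the amplitude scaling
of trial noise by regressing per-ROI, per-stimulus trial SDs on |mean|
(OLS), clipping negative slopes to zero; sigma0 comes from the state
(0.2 anaesthetised, 2 awake/behaving).

`accuracyRatio()` expresses the sublinear condition's accuracy as a
fraction of the linear baseline per time bin and averages over the early
(0–1.5 s] and late (1.5–3 s] phases; `compareRatioPhases()` runs the
paired phase comparisons across fields.

# The synthetic-data generator

The generator defines the study conditions for every test.

**Panel** (`makePanel()`): the target's tuning across ROIs is gamma
distributed (positive, right-skewed); each non-target odour's tuning is
built from the standardised target vector plus an orthogonalised
independent draw so its Pearson correlation with the target equals the
requested overlap exactly, then scaled by a per-odour potency factor
drawn from U(0.4, 1.2) — panels in this field span a wide range of
evoked-response strengths, and exactly exchangeable odours would put
every target mixture on the decision boundary of a singles-trained
zero-intercept decoder, an artificial degeneracy.

**States** (`statePreset()`): anaesthetised — gain 1, trial-amplitude SD
0.2 delta-F/F, mixture components summed then passed through the
saturating transform (Rmax 6, s 0.2); behaving — gain 0.4, SD 2 (the
baseline SDs also used in the noise model), linear summation; the naive
awake states sit between. Per-ROI amplitude distributions are not
reported for the recorded data, so the tuning scale is the package's own
choice: with mean 6 and SD 4 delta-F/F of synaptic drive, the
anaesthetised preset yields a median fractional deviation near −0.2
(clearly sublinear) while keeping anaesthetised observed amplitudes
larger than behaving ones. Those two constraints pull against each other:
driving the amplitudes high enough to reproduce the deepest reported
sublinearity (median ≈ −0.4) would make the dampened awake responses
(0.4 × drive, unsaturated) exceed the saturated anaesthetised ones, which
real recordings do not show. The generator therefore reproduces the
anaesthetised/behaving ordering and the sign and rough magnitude of the
summation statistics, not the exact real-data medians.

**Trials** (`simulateSession()`): each trial's mean amplitude over the
response window equals gain × f(sum of component tuning) plus
N(0, trialNoiseSd) per ROI, where f is the identity or the saturating
transform. The waveform is a difference of exponentials (rise 0.15 s,
decay 4 s, onset lag 0.1 s) scaled to unit mean over the response window
— the real transient shape is not specified anywhere, only its window
averages matter to the analyses. Traces are generated directly as
delta-F/F (baseline mean 0); a small per-frame noise floor (SD 0.05)
emulates photon/readout noise, and a per-trial shared gain jitter is
available but off by default. Trial lists either follow the recorded
session design — target, masker and their mixture once per 10-trial block
(`makeTrialList()`) — or are class-balanced for decoder calibration
(`balancedTrialList()`). All randomness flows through explicit seeds; no
function touches the caller's RNG state.

**What the generator does not emulate:** sparse/heavy-tailed single-cell
tuning, inhibitory reformatting beyond the saturating transform,
correlated (shared) trial-to-trial noise, sniff-coupled temporal
structure, and slow response growth across the trial. Passing tests
therefore validate the statistics and the machinery on data with known
structure; they do not certify that real recordings satisfy, e.g., the
late-phase susceptibility contrast. Indeed, under this generator the
sublinearity simulation does not reproduce the reported direction of the
state contrast: for the high-gain, correlated-pattern preset the
saturating transform compresses potent background components and thereby
*helps* a singles-trained decoder about as often as it hurts (late-phase
accuracy ratio ≥ 1), while the dampened, decorrelated, noisy preset shows
a mild cost (ratio ≈ 0.9). The reported degradation in anaesthetised-like
data plausibly requires codes whose discriminative information is
concentrated in strong responders — exactly the sparse tuning this
generator does not model. We record this as a known limitation rather
than tuning the generator around it.

# Behaviour

`classifyResponse()` applies the anticipatory-lick threshold of 2 licks
within the 3-s response window: rewarded trials need ≥ 2 licks (hit),
unrewarded trials ≤ 1 lick (correct rejection); an unrewarded trial with
exactly 2 licks is a false alarm, implementing the "one lick or less"
boundary literally. `learningCurve()` reports accuracy over
non-overlapping 50-trial blocks and the trials-to-criterion for 80%
accuracy, taken as the end index of the first block at criterion (the
convention is otherwise unstated); a trailing partial block is reported
separately. `lickPreferenceIndex()` computes
(Lick_rewarded − Lick_unrewarded)/(Lick_rewarded + Lick_unrewarded) from
mean anticipatory-lick counts per background odour; it is 1 when all
anticipatory licks occur on rewarded trials and undefined (NA) when
neither trial type shows licks. Per-background accuracy tables
(`backgroundAccuracy()`) aggregate per animal first when used across
animals.

`simulateBehaviour()` generates Go/No-Go trials with a per-background
probability of a correct decision; go responses emit at least
threshold-many licks with the rewarded lick rate, withheld responses stay
below threshold with the unrewarded rate.

# Reproducible runs and I/O

Sessions serialise to a directory of per-trial CSV arrays plus a CSV
manifest (`writeSession()`/`loadSession()`); doubles are written with 17
significant digits so round-trips are bit-exact. Deposited-style
two-column tables of (linear sum, observed) amplitude pairs load through
`readSummationPairs()`. `runPipeline()` ties simulation, summation,
similarity and decoding into a run directory with tidy CSVs, a JSON
summary, a log capturing exclusions, and a resolved-config snapshot;
outputs are byte-identical across reruns with the same seed.

# Problem sizes

The packaged tests and the acceptance script run sessions of 40–120
trials with 40–150 ROIs, 6–8 fields per condition, 100–200 Monte-Carlo
repeats and 10–100 decoder splits — sizes chosen to estimate each
statistic within a few percent while keeping any single check in the
seconds-to-minutes range.
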