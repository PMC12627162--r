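---
title: "Closed-loop audio-visual search and the transfer of learned gaze biases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gazebias methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gazebias)
```

## The paradigm

`gazebias` implements, as a fully simulatable desk-scale pipeline, a
closed-loop **audio-visual search (AVS)** paradigm and the eye-movement
analysis chain used to measure whether a spatial bias learned during search
transfers to unrelated free-viewing behaviour.

In the AVS task an observer moves their gaze across a screen searching for
an *invisible* circular target (radius 4.1 degrees). The only information
about the target is a continuous tone whose loudness encodes the Euclidean
distance between gaze and target centre: silence means "on target",
loudness saturates at 17.8 degrees. A trial succeeds when gaze dwells
inside the target radius for a continuous 500 ms, and times out at 10 s.
Targets occupy an invisible 6 x 3 grid (horizontal eccentricities
±3.8, ±11.4, ±19.9 degrees; vertical −7.5, 0, +7.5) and, crucially, their
locations are *biased*: 180 trials are distributed 90-60-30 over the left,
central and right pair of grid columns (mirrored for the right-bias group),
a 2:1 hemifield ratio. The question is whether observers implicitly learn
this location-probability structure and whether the learned prioritisation
carries over to blank-screen viewing (BSV, 1-min rest), natural-image
viewing (IVT, 30 images x 5 s) and a landmark line-bisection task
(LT, 11 offsets spanning ±0.68 degrees, 8 repetitions each, 88 trials),
each administered before and after training.

Because the human dataset is not required for any of this, every observer
in this package is synthetic: the generators are first-class, tested code,
and the analysis chain is validated by parameter recovery against them.

## The task engine

**Loudness mapping.** The experiment description fixes only the endpoints
("exponentially mapped", silent on target, maximum at 17.8 degrees), so the
mapping is implemented as the normalised exponential

$$v(d) = \frac{B^{u}-1}{B-1}, \qquad
u = \frac{d - r_0}{d_{\max} - r_0},$$

clamped to $[0,1]$, with $r_0$ the silence radius (default = target radius
4.1), $d_{\max} = 17.8$ and base $B = e$ by default ($B$ is configurable;
any $B > 1$ gives a continuous, strictly increasing, convex curve with the
same endpoints). Whether the original hardware clamped loudness beyond
17.8 degrees is unknowable from the description; clamping is the only
choice that keeps $v$ well defined on the whole screen.

**Dwell rule.** "Fixated for 500 ms" is read as *continuous* dwell: the
accumulator gains one sample period per in-radius valid sample and resets
to zero on exit (or on an invalid sample). The alternative
tolerant-of-exits reading is not implemented; the reset rule is the
stricter one and is configurable through `study_config()`.

**Zones.** The 90-60-30 left-to-right counts are interpreted over the three
left-to-right *column pairs* of the grid — the only partition of the six
columns into three left-to-right zones that sums to 180 and produces a 2:1
hemifield ratio (120 of 180 targets in the biased hemifield). Within a
zone, counts spread as evenly as possible over its six positions, with
remainders assigned deterministically by position index, so the target
multiset depends only on the configuration and never on the seed.

**Coordinates.** Everything runs in screen-centred degrees (+x right,
+y up) at 600 Hz; `px_to_deg()` uses the full arctangent formula for a
23.8-inch 1920x1080 panel at 57 cm. Binocular recording is reduced to a
single (mean-of-eyes) stream throughout; no binocular conjunction checks
are made.

## The synthetic observers

No observer model exists in the source description, so the agent is a
package design choice, kept as small as possible while producing the
phenomena the analysis chain must detect. Nothing here claims to match
human search-time distributions.

**Search agent (run-and-tumble on loudness).** The agent alternates
fixations (mean 0.25 s) and saccades and reads the scalar loudness at each
fixation centroid — never target coordinates. Its heading policy is
gradient descent by alternation:

* loudness decreased since the last fixation: keep the heading, with
  Gaussian wobble (SD 0.3 rad);
* loudness increased: reverse the heading (±2x wobble);
* loudness saturated at both fixations (no gradient): explore with a
  uniformly random heading, recentring toward the screen centre when more
  than 12 degrees away from it. This uses knowledge of the screen, which
  any observer has, and prevents the unbounded corner-wandering a pure
  random walk produces in the gradient-free zone.

Saccade amplitudes are scaled by the current loudness, so steps shrink as
the target nears; on hearing silence the agent holds fixation. Two further
mechanisms create the learning phenomena:

* **Statistical learning** is an exponential-moving-average hemifield prior
  (`update_hemifield_prior()`, rate 0.02 per trial), updated after every
  trial with the target's true hemifield — defensible because the loudness
  feedback reveals the target's approximate location by trial end whether
  or not the dwell criterion was met. The prior biases the *first* saccade
  direction of each trial: the probability of launching toward the biased
  side is $0.5 + s\,(\pi - 0.5)$ with strength $s = 0.8$. Under the 2:1
  target stream the prior converges to about 2/3.
* **Task practice**: the fixation-duration mean is multiplied by
  $1 + 0.5\,e^{-(k-1)/60}$ at trial $k$, so sampling is slower early in
  training. This produces the across-trial performance improvement that
  the learning-curve model is meant to detect.

**Free-viewing generator.** `simulate_fixation_sequence()` draws lognormal
fixation durations and gamma saccade amplitudes; each saccade target is a
mean-reverting AR(1) step toward $(\text{horiz\_bias}, 0)$ plus the
gamma-amplitude displacement in a uniform direction, clamped to the screen.
The stationary mean abscissa is therefore exactly `horiz_bias`, the
quantity the barycenter analysis estimates. The recentring strength
(`pull = 0.7`) keeps the stationary scanpath spread at the few-degree scale
of real screen viewing; with the default blank-screen parameters
(fixation mean ≈ 2.1 s, amplitude mean ≈ 6.8 degrees) the per-record
barycenter SD is near 1 degree, giving pre-to-post shift SDs of the order
seen in practice (≈ 1.5–2 degrees). An `early_bias` offset applies to
fixations in the first second, emulating the early horizontal deviation of
natural viewing, and blinks are inserted as invalid runs at 15 per minute.
`simulate_free_viewing()` renders the sequence at 600 Hz (jittered fixation
samples, 3-sample saccade ramps — sufficient for a velocity-threshold
detector, with no main-sequence dynamics).

**Transfer mechanism.** After training, each participant's free-viewing
bias shifts by $g\,(2\hat\pi - 1)$ toward the trained side, where
$\hat\pi$ is the learned prior and $g = 1.5$ degrees, so a fully learned
2:1 prior yields ≈ 0.5 degrees — the scale of the blank-screen transfer
effect the pipeline is designed to detect. Image viewing expresses only a
fraction (0.4) of that shift, since visual content anchors gaze; the
landmark-task transfer gain defaults to 0 (no transfer), matching the null
that task is expected to show. These are *generator conditions*, chosen
once from the study's summary scales, not quantities any test tunes.

**Cohort assembly.** `generate_cohort()` assigns groups by shuffling a
balanced ordered list and draws per-participant parameters: natural
horizontal bias N(−0.3, 1) degrees (a small population-level leftward
bias), log-normal multipliers (SD 0.15–0.3) on durations, amplitudes and
psychometric slope, true PSEs N(0, 0.2) degrees.

## Preprocessing and event detection

Blink gaps are linearly interpolated in x and y against time
(`interpolate_gaps()`); leading/trailing invalid runs stay invalid. A trial
is discarded when *more than 40% of its samples are missing in one
continuous run* — the rule applies to the longest run, is evaluated before
interpolation, and scattered loss of any total amount does not trigger it.

Saccades are detected with the velocity-threshold method: smoothed
velocity from the 5-sample kernel
$v_i = (x_{i+2} + x_{i+1} - x_{i-1} - x_{i-2})\,f_s/6$ (shortened
one-sided differences at the ends), per-axis robust SDs
$\sigma = \sqrt{\langle v^2\rangle_{med} - \langle v\rangle_{med}^2}$
(floored at machine epsilon so a perfectly still synthetic trace yields no
events), elliptic criterion $(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1$ with
$\eta = \lambda\sigma$, and a minimum saccade duration. Fixation
refinement merges consecutive fixations separated by < 75 ms *and* < 0.5
degrees (the swallowed saccade is dropped, centroids combine
duration-weighted), then discards fixations < 60 ms; the operation is
idempotent. The numeric defaults ($\lambda = 6$, 12 ms, 75 ms, 0.5
degrees, 60 ms) are standard published values for this detector family;
the original study's exact refinement constants live in supplementary
material that is not part of this artifact, so all of them are explicit,
configurable stand-ins. Thresholds are computed per record (per trial /
per 1-min rest / per image).

The detector is verified against an independent brute-force oracle
(per-sample labelling plus explicit run grouping) on 100 random fixtures
per run, and is monotone: raising $\lambda$ never increases the saccade
count.

## Features and viewing styles

Twelve spatiotemporal features summarise each record: fixation count, mean
and total fixation duration, mean duration in an early and a late window
(first/last 1.25 s for 5-s image viewing; first/last 15 s for 1-min rest;
membership by fixation onset), mean/SD/max gaze step (Euclidean distance
between successive samples), horizontal and vertical gaze-flip rates
(sign inversions of successive per-axis displacements, zero displacements
transparent by default), mean saccade amplitude and saccade rate. The
exact feature inventory used originally is supplementary-only; this list
reconstructs every feature named in the main description and pads it with
the two standard event statistics, and is configuration-driven so a
definitive list can be dropped in.

PCA runs on the correlation matrix (features are standardised first —
they have heterogeneous units), keeps the top three components by default,
and fixes signs so each component's largest-magnitude loading is positive,
making results deterministic. On cohorts built from "static" (long
fixations, large steps) versus "dynamic" (short fixations, small steps)
archetypes, PC1 scores separate the archetypes with point-biserial
correlation above 0.8 — the parameter-recovery analogue of the
viewing-styles phenomenon.

## Transfer statistics

* **Barycenter** = unweighted mean horizontal fixation position (a
  duration-weighted variant exists but is non-default, since the quantity
  analysed is the "mean horizontal fixation position").
* **Shifts**: post − pre per participant; image-viewing shifts are computed
  per image and collapsed with the median (robust to the skewed per-image
  distributions); left-bias-group shifts are sign-reversed so positive
  always means "toward the trained side". One-sided one-sample t-tests
  (upper tail) with Cohen's d and the one-sided 95% CI bound.
* **PSE**: two-parameter maximum-likelihood logistic
  $P(\text{right}) = \text{logit}^{-1}\{b(o - \text{PSE})\}$, no lapse or
  guess parameters. Complete separation is flagged non-converged with the
  PSE at the separating midpoint; a numerically flat function returns the
  centre of the tested range, also non-converged.
* **Congruent bias**: |median horizontal fixation position in the first
  second of a pre-test record|, signed + when that side matches the
  participant's trained side.
* **Density maps**: duration-weighted Gaussian KDE of fixation centroids,
  bandwidth 1 degree on a 0.25-degree grid (no values were specified;
  these are smooth-but-resolving defaults), normalised to sum to 1, with
  the first 750 ms excluded and left-group coordinates folded onto the
  right hemifield; per-target-position maps combine by cellwise median and
  renormalisation.
* **Alignment**: the share of participants whose image-viewing and
  blank-screen shift directions both equal their trained side, tested
  one-sided against 0.25 (two independent fair signs) with the exact
  binomial test — exact, not normal-approximate, because n is small.
* **Learning curves**: gaze-target distance is binned as the median within
  500-ms intervals over the trial's live span (bins are left-open,
  right-closed so the deadline sample stays in range; carry-forward
  padding after success exists only as a plotting option). The model is a
  fixed-effects **gamma GLM with log link** on
  `bias * z_trial * z_time` (continuous predictors standardised);
  estimates are reported as multiplicative factors with 1-df
  likelihood-ratio chi-squares obtained by refitting without each model
  column (deviance differences scaled by the Pearson dispersion). The
  original analysis used a random-slopes mixed model; mixed-model
  estimation is outside this package's contribution, so the GLM is the
  in-scope model and the coefficient-table schema
  (`term, estimate, chisq, df, p`) doubles as an adapter contract — a
  mixed-model backend (e.g. `glmmTMB` with
  `distance ~ bias*z_trial*z_time + (1 + ... | participant)`) can be
  slotted behind it.
* **Standardisation** divides by the population SD (divisor $n$), so
  `standardize(c(1,2,3))` is ±1.2247; a sample-SD variant is available.

A note on the learning-curve composition: in this paradigm the biased
hemifield necessarily contains more *eccentric* targets than the unbiased
one (90 of its 120 trials sit in the outer column pair), so the `bias`
main effect partly reflects target eccentricity, not only attention. The
same composition holds in the original design; interpret the bias factor
with that in mind.

## Design and power

Power for the one-sided paired t-test uses the noncentral t exactly:
$P(T'_{n-1,\,d\sqrt n} > t_{1-\alpha,\,n-1})$. At $d = 0.4$,
$\alpha = .05$ this gives 92.2% at $n = 60$ and 79.97% at $n = 40$ — the
design numbers 92%/80%. Note the rounding: because the exact power at 40
is just below 0.80, `required_n(0.4, 0.80)` is 41, while the inverse at
the exactly attained power returns 40.

`sequential_nominal_alpha()` solves for the common per-look level of a
K-look group-sequential (Pocock-type) design by recursive normal
integration over the Markov chain of interim statistics (correlation
$\sqrt{t_i/t_j}$), validated against Monte Carlo. For two equally spaced
looks at two-sided 5% it reproduces the classical 0.0294. The interim
threshold of 0.0329 quoted in this literature is *not* asserted as the
solver's output: its derivation convention (sidedness, table used) is not
stated in the source, so 0.0329 is treated as a configured decision
threshold, and the solver remains generic. For the record, the two-look
one-sided 5% solution here is ≈ 0.0304.

`audit_randomization()` checks the balanced-shuffle contract: exact group
balance within each block of 40 and imbalance over even prefixes.

## Numerical choices

* Bin boundaries: left-open/right-closed, `ceiling(t/0.5) - 1` clamped at 0.
* Dwell comparison uses a 1e-9 tolerance so 300 accumulated sample periods
  of 1/600 s reach 0.5 s despite floating-point accumulation.
* Robust velocity SDs are floored at machine epsilon.
* PCA signs: largest-|loading| positive per component.
* The gamma-GLM refits use the full model matrix minus one column, so
  factor-interaction terms are tested as single degrees of freedom.
* All generators draw from R's single RNG stream; one `set.seed()` call
  makes the entire pipeline bit-reproducible (the per-trial child-seed
  scheme was considered and rejected as needless complexity given the
  single stream).

## What the tests show — and what they cannot

The test-suite cohorts are scaled down (8–40 participants, 12–90 trials,
10–30-s records, 100–400 replicate cohorts for calibration curves; the
acceptance script runs the full 40 x 180 study) — sizes chosen as the
smallest at which the calibration bands are informative. Passing them
shows that the chain *recovers what the generators put in*: negative
learning-curve slopes, a positive sign-corrected shift when a shift was
induced, ≈5% type-I error when none was, monotone power in the induced
shift, PSE recovery within its standard error, and detector agreement with
a brute-force oracle.

It does not show that real eye-tracking data satisfy the generators'
assumptions. The synthetic saccades are 3-sample ramps without main-
sequence kinematics; fixational noise is white, not drift-plus-tremor;
image "content" is a scalar horizontal offset rather than saliency; the
search agent is one convenient policy among many (alternatives are
pluggable behind the same contract); and the transfer mechanism is a
stationary mean shift, with no decay over the post-assessment. Estimates
of, e.g., human search-time distributions or mixed-model variance
components are outside what this artifact can validate.
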