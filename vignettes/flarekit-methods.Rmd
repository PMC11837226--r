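---
title: "Methods: quantifying turn-taking aggressive displays in fighting fish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying turn-taking aggressive displays in fighting fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flarekit)
```

## The scientific problem

Male Siamese fighting fish (*Betta splendens*) settle contests through a
ritualized visual display phase: opponents alternate ("take turns") at
flaring their opercular gill covers while facing each other, interleaved
with lateral presentations. flarekit quantifies this behavior from
pose-tracking output: it cleans keypoint tables, extracts kinematic
features, classifies flaring, and computes the statistics that
characterize the display — loop synchronization to a repeating animated
stimulus, flare-feature correlations, bout-triggered averages, engagement
decay, and dyadic state-transition structure. A synthetic dyad simulator
with known ground truth closes the loop so that every stage can be tested
end to end without video data.

## Kinematics

Keypoints arrive as per-frame (x, y, confidence) triplets per body part at
a fixed frame rate (40 fps default, parameterized everywhere). Cleaning
drops samples with confidence below 0.8 or displacement above 15 px from
the previous *retained* sample, then linearly interpolates interior gaps;
leading/trailing gaps take the nearest valid value so all channels keep
equal length. Comparing against the last retained sample prevents one
outlier from masking subsequent good points; its cost is that a part which
genuinely sweeps faster than the threshold (the tail during fast turns)
can be dropped for a stretch until it returns near the last accepted
position. This is inherent to the rule, affects only fast peripheral
parts, and leaves flare scoring untouched.

Coordinates are image coordinates (origin top-left, y down). Orientation
is the unsigned angle in [0, 180] between the body axis (centroid to
nose) and the inward normal of the stimulus wall; the signed heading is
kept internally for the turning-angle channel. The operculum angle is the
angle at the nose subtended by the two operculum tips — the geometric
signature of flaring in top view. Elevation is measured from the side
view as (floor line − head y)/scale; channels that need a missing view
are reported absent rather than zero-filled. All features pass through an
11-frame centered median filter (0.275 s at 40 fps), which preserves
step edges while removing isolated tracker glitches.

The body-axis definition of orientation (centroid → nose) is one of
several defensible choices (nose-vector, head-to-centroid); it is stable
under partial occlusion of the tail and matches how the renderer
generates headings, and it is the single convention used throughout.

## Flaring classifier

The classifier is a dilated temporal convolutional network: two dilation
blocks, each with two 1-D convolutions (filter 9 timesteps, 32 channels)
followed by leaky-ReLU and dropout p = 0.1, a residual path (with a 1×1
projection where channel counts differ) joined before a final leaky-ReLU;
then a dense softmax head per timestep. Dilation doubles per block
(1, 2), the canonical TCN schedule, since no other schedule is specified
by the training protocol we follow. Symmetric zero padding keeps output
length equal to input length, as per-timestep labels require. "Weight
dropout" is implemented as standard activation dropout; at p = 0.1 the
two are practically interchangeable for this architecture.

Training chunks the record into 1000-timestep sequences (remainder
dropped and logged), splits 90/10 at the sequence level, and minimizes
class-weighted cross-entropy (weight N/N_i for class i, computed on the
training split; zero-count classes are excluded) with Adam at learning
rate 1e-4, batches of 8 sequences, stopping after 20 epochs without
validation improvement and returning the best checkpoint. There is no
deep-learning backend in the supported stack, so the forward and backward
passes are written directly on BLAS matrix products; gradients are
verified against numerical differentiation in the test suite.

F1 is computed as the harmonic mean of precision and recall — the
standard definition — for each class, with classes absent from both truth
and prediction excluded from the macro average. Ties in the per-frame
argmax break toward the lower class index (none < partial < full).

## Loop synchronization

For a stimulus loop of length T frames shown S times, the response folds
into an S × T binary matrix; the across-loop flaring frequency
X_S(t) = Σ_i x_i(t)/S has sample variance σ² (denominator T − 1). Under
phase locking the profile is peaky and σ² large. The null rotates each
row by an independent offset drawn uniformly on the integer frame grid
{0, …, T−1} — a discretization of a continuous uniform shift, since the
response is a frame series — recomputing σ² for 1000 iterations; a fish
is called synchronized when the observed σ² strictly exceeds the 95th
percentile (linear interpolation between order statistics) of the null.
Shifts preserve within-loop bout structure and row sums exactly, so the
test is sensitive to phase locking only. The trailing partial loop (the
".2" of a 16.2-loop exposure) is discarded: equal-length rows are
required by the fold. A constant response is shift-invariant, giving a
degenerate null equal to the observed value, and is correctly not
flagged under the strict inequality.

## Correlations, bout averages, persistence

Flare-feature correlations are point-biserial (Pearson with 0/1 coding),
computed on frames where either opponent flares — restricting to
co-active periods avoids inflating correlations in low-flaring dyads. A
fish that never flares is assigned r = 0. The control fully permutes the
masked feature values (a random shuffle rather than a circular shift,
because the correlation has no temporal structure to preserve), and
observed vs shuffled coefficients are compared across the cohort with a
two-sided paired t-test.

Peri-event time histograms average a feature in ±3 s windows around
isolated flare bout onsets (no flaring for 3 s before, continuous flaring
for 3 s after) and offsets (mirror image); events whose window crosses a
record boundary never qualify. Elevation windows are min-max normalized
per window; a constant window maps to zeros and is flagged degenerate.
SEM uses the n − 1 denominator; events are the unit within a fish, fish
are the unit for cohort averages.

Persistence bins the binary flare series into 8-s bins after a centered
rolling mean of width 0.357 s. A sub-bin window cannot meaningfully act
on 8-s bins, so the rolling mean is applied at frame resolution before
binning by default; the literal bins reading is available via
`smooth_on = "bins"`. The cohort-average curve is fitted with
y(t) = A·exp(−t/τ) + c by bounded least squares (A ≥ 0, τ > 0, c ≥ 0,
multi-start at τ ∈ {10, 60, 300} s, deterministic given the data). The
offset c is included because flaring need not decay to zero within an
exposure. The curve's "maximum height" is its value at exposure start
(A + c); the crossing time at fraction f solves y(t) = f(A + c), which
reduces to τ·ln(1/f) when c = 0 (τ·ln(4/3) ≈ 0.29 τ at f = 3/4).

## Transition graphs

Behavior is discretized into 8 per-fish states (flare on/off × facing,
turning, lateral, turning-away) and 64 dyadic states (8·a + b). The
orientation band boundaries are not standardized anywhere we know of;
the default is the static bands 45/90/135 degrees, which is reproducible
and parameter-free, with an angular-velocity rule (fast rotation away
from the stimulus counts as turning-away, fast rotation toward it as
turning) available as an option. Transition probabilities are estimated
over state-change events with self-transitions excluded — the embedded
jump chain — because with exponential dwell times frame-level
self-transitions are dominated by the frame rate and an edge-probability
threshold of 0.0025 is only meaningful for change events; a frame-level
estimate can be recovered from the recorded dwell times if needed.
Counts pool across sequences but never across a sequence boundary.

Filtering removes states occupied under 2% of pooled time (occupancy is
pooled because the matrices are population-level) and edges below
probability 0.0025 in both of two conditions (single-graph rule when no
companion is given). The layout takes the two leading nontrivial
eigenvectors of the symmetrized matrix (P + Pᵀ)/2 — symmetrization
guarantees a real spectrum and a stable, deterministic embedding; signs
are fixed by making each eigenvector's first nonzero coordinate positive,
and disconnected components are laid out independently with an x offset.
Dwell-time exponentiality is reported per state by a one-sample KS test
against an exponential at the state's empirical mean (conservative, since
the mean is estimated from the same data; it is a descriptive check).

## The synthetic world

The dyad simulator is two coupled agents. Each agent's orientation is a
continuous-time semi-Markov chain on the path facing–turning–lateral–
turning-away with exponential dwells (defaults 2, 0.5, 1.5, 0.5 s: long
holds facing and lateral, brief transitions through turning). Flaring is
a per-frame hazard process: bouts end at rate 1/1.1 s (matching observed
mean bout durations), and initiation follows a hazard that (i) is
suppressed by (1 − c) while the opponent flares, (ii) is transiently
boosted for 1 s after the opponent's flare offset, both scaled by the
coupling c, and (iii) tracks an exposure-long exponential engagement
decay. Hazard-rate modulation (rather than post-hoc label editing)
preserves the semi-Markov structure the transition analyses assume. The
baseline gives ~22% time flaring, typical of real encounters. With c
near 1, alternation becomes near-deterministic and the flare-overlap
correlation reaches about −0.7 on 10-minute trials; real dyads show even
stronger anticorrelation, which would require additional mechanisms
(e.g. shared arousal dynamics) the analyses do not need.

The engagement decay is defined on the flaring *rate*: the initiation
hazard is chosen so the stationary flare occupancy tracks
f₀·exp(−t/τ), inverting the saturation f = h·bout/(1 + h·bout). Applying
the decay naively to the hazard would make the observable fraction decay
non-exponentially (time constant inflated by ≈ 1 + h·bout early in the
exposure), which contradicts the exponential-decay world the persistence
analysis assumes; the quasi-static inversion is exact to within the ~1 s
bout timescale, negligible against τ ≥ 60 s.

The animation-response generator draws per-frame Bernoulli flaring with
probability (1 − s)·p₀ + s·template(t), where the template is a fixed
contiguous window covering 30% of the loop (the lateral epoch of the
animation, which drives flaring). s = 0 is the homogeneous null used for
calibration; s = 1 is a deterministic phase-locked response.

The renderer maps states to keypoints: body axis from the orientation
angle, operculum tips 1 cm behind the nose at half-angles encoding flare
class (20/45/75 degrees closed/partial/full, ±1.5 degrees noise;
classification thresholds at 32 and 60 degrees sit ~13 degrees from each
class mean), state changes ramped over ~0.25 s so frame-to-frame motion
stays physical, positions on a smooth reflected walk at ~2 cm/s, and
elevation coupled to smoothed flaring. Corruption for cleaning tests
injects i.i.d. low-confidence garbage samples and isolated 20-px jumps —
exactly the two defect classes the cleaning rules target.

What a green test does *not* establish: the simulator has no biting or
tail-beating phases, no 3-D body deformation, no response of the stimulus
to the fish, and i.i.d. frame noise rather than correlated tracker error;
classifier performance on it does not predict performance on real video.

## Numerical and protocol choices

- One master seed; per-fish and per-stage sub-seeds derived by an
  integer mixing function (`derive_seed`), always below 2^31.
- Percentiles use linear interpolation (R type 7); the synchronization
  call uses strict `>` at the threshold.
- Whole-percent cohort fractions round half away from zero
  (17/21 → 81%).
- The validation split is random at the sequence level (individuals are
  not held out); evaluation on held-out individuals is a separate,
  stricter protocol the training data here cannot support.
- Configs are JSON-first; YAML is accepted when the `yaml` package is
  installed (it is not part of the guaranteed dependency stack).

## Known limitations

- The jump-rule cascade on fast-swinging parts (above) is faithful to
  the rule but means tail channels should be treated cautiously during
  rapid turns.
- The exponential-fit crossing times are undefined when the fitted
  offset exceeds the requested fraction of the maximum; they are
  reported as NA with the fit diagnostics intact.
- The per-state KS exponentiality check uses estimated means and is
  conservative; calibrated goodness-of-fit (e.g. Lilliefors) is out of
  scope.
- The spectral layout is one member of a family ("spectral layout" is
  not a single canonical algorithm); block structure and symmetry
  properties, not exact coordinates, are the stable output.
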