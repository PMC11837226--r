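# flarekit

Quantitative analysis of turn-taking aggressive displays in Siamese
fighting fish (*Betta splendens*) from pose-tracking output.

Male betta settle contests through a ritualized visual display: opponents
alternate at flaring their opercular gill covers while facing each other,
interleaved with lateral presentations — visual turn taking. flarekit is
a toolkit for researchers quantifying this behavior from video-derived
keypoints: it cleans tracking tables, extracts kinematic features,
classifies flaring with a sequence model, and computes the statistics
that characterize the display — stimulus-locked synchronization,
flare–feature correlations, bout-triggered averages, engagement decay,
and dyadic state-transition structure. A synthetic dyad simulator with
known ground truth lets the entire pipeline be exercised and tested
without any video data.

## The statistics at the core

**Loop synchronization.** For a stimulus animation of length *T* frames
looped *S* times, the binary flare response folds into an *S × T* matrix
with across-loop flaring frequency

X_S(t) = Σᵢ xᵢ(t) / S,  σ² = Σₜ (X_S(t) − X̄_S)² / (T − 1).

Phase-locked flaring makes the frequency profile peaky and σ² large. The
null distribution comes from circularly shifting each loop's response by
an independent offset θᵢ ~ Unif{0, …, T−1} (destroying phase while
preserving bout structure), 1000 times; a fish is *synchronized* when
σ² exceeds the null's 95th percentile.

**Point-biserial correlations** between flaring (0/1) and opponent or
stimulus features, restricted to frames where either fish flares, with a
full-permutation shuffle control and a paired t-test across the cohort.

**Persistence.** The flare series is binned (8 s), averaged across fish,
and fitted with y(t) = A·exp(−t/τ) + c; the time constant τ and the
times at which the curve falls to ¾ or ½ of its initial height summarize
engagement decay.

**Transition graphs.** Behavior is discretized into 8 per-fish states
(flare on/off × facing/turning/lateral/turning-away) and 64 dyadic
states; directional transition probabilities over state-change events
(the embedded jump chain) are filtered (occupancy ≥ 2%, edge p ≥ 0.0025)
and embedded in 2-D with the two leading nontrivial eigenvectors of the
symmetrized transition matrix.

**Flaring classifier.** A dilated temporal convolutional network (two
residual dilation blocks, 32 channels, 9-timestep filters, dropout 0.1;
dense softmax head) maps feature sequences to per-frame none/partial/full
labels, trained with Adam (lr 1e-4) on class-weighted cross-entropy
(weights N/Nᵢ) with sequence-level 90/10 splitting and early stopping.
Implemented in pure R on BLAS matrix products; gradients are verified
against numerical differentiation in the test suite.

## Worked example

```r
library(flarekit)

# a synthetic fish strongly locked to a 37-s animation loop
trial <- simulate_animation_response(animation_sim_config(
  loop_length_s = 37, n_loops = 16, lock_strength = 0.8,
  base_flare_rate = 0.2, seed = 7))

folded <- fold_by_loop(trial$agents[[1]]$flare, loop_length_s = 37,
                       frame_rate = 40)
folded
#> <loop_folded> 16 loops x 1480 frames (16.0 loops shown, 0 frames discarded)

sync_test(folded, n_iter = 1000, seed = 7)
#> <sync_test> observed 0.138 vs threshold 0.0244 (p95 of 1000 shifts): SYNCHRONIZED
```

The observed frequency-profile variance (0.138) sits far above the 95th
percentile of the circular-shift null (0.024): this fish times its flares
to fixed epochs of the animation loop. With `lock_strength = 0` the same
test flags ~5% of fish — the nominal false-positive rate.

```r
# a coupled dyad: turn taking shows up as anticorrelated flaring
dyad <- simulate_dyad(dyad_sim_config(turn_taking_coupling = 0.9, seed = 1))
cor(dyad$agents[[1]]$flare, dyad$agents[[2]]$flare)
#> [1] -0.6999

# keypoints -> features -> rule-based ethogram, end to end
kp <- clean_keypoints(render_keypoints(dyad, agent = 1, view = "top"))
feats <- median_smooth(compute_features(kp, stimulus = rendered_stimulus_geometry()))
eth <- classify_flare_by_threshold(feats)
mean(binary_flaring(eth) == dyad$agents[[1]]$flare)
#> [1] 0.992
```

## Layout

- `R/` — implementation (simulator, kinematics, classifier, synchrony,
  interaction dynamics, transition graphs, pipeline/CLI)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/flarekit-methods.Rmd` — model assumptions, parameter
  choices, numerical decisions, limitations
- `inst/cli/flarekit` — Rscript CLI wrapper
  (`flarekit simulate|sync|persist|report ...`)
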