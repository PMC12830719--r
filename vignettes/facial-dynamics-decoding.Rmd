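---
title: "Decoding conversation context from facial action-unit dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding conversation context from facial action-unit dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faudyn)
```

## The scientific question

When three people talk, does the *social context* of the conversation — a
relaxed get-to-know-each-other chat versus a charged moral-dilemma debate —
leave a decodable trace in their facial behavior alone?  faudyn implements
an analysis pipeline built around that question.  The observable is a
per-participant time series of facial action-unit (AU) intensities:
AU4 (brow lowerer), AU6 (cheek raiser) and AU12 (lip-corner puller), the
three AUs most informative about affective tone in social interaction,
sampled at 25 frames/s with intensities in [0, 1].  The unit of inference
is the *triad*: three participants sharing one conversation and one binary
condition label.

The pipeline has five stages:

1. **Speech masking.**  AU estimates during a participant's own speech are
   contaminated by articulation, so every frame whose 40 ms window overlaps
   one of that participant's speech intervals is zeroed.  Roughly
   three-quarters of each participant's timeline is speech-free under
   triadic turn-taking, so most of the signal survives.
2. **Image encoding.**  Each masked AU channel is min–max normalized to
   [-1, 1], mapped to angles $\Phi_i = \arccos(\hat{x}_i)$, and expanded
   into the Gramian Angular Difference Field
   $M_{ij} = \sin(\Phi_i - \Phi_j)$, an antisymmetric image whose $(i,j)$
   pixel encodes the phase change of the signal between time points $i$
   and $j$.  The three AU channels stack into an RGB-like image
   (AU4 = R, AU6 = G, AU12 = B).
3. **Cross-group classification.**  A small convolutional network predicts
   the condition from each participant's image; participant probabilities
   average into a triad probability.  Validation is 5-fold *cross-group*:
   a triad's participants are never split across training and test sets,
   so the classifier cannot succeed by recognizing individuals.
4. **Controls.**  Temporal permutation (destroys dynamics, keeps the value
   distribution), speech-binary input (keeps only speech timing), and a
   24-feature static-summary baseline (logistic regression / random
   forest) establish that classification rests on temporal structure
   rather than marginal statistics or turn-taking.
5. **Rater statistics.**  A parallel human study — raters classifying
   muted videos — is summarized by accuracy at the rating/video/rater
   level, a 2x2 Matthews correlation, Fleiss' kappa stratified by
   raters-per-video, t-tests of confidence and decision timing, and the
   confidence–decision-time correlation.

## What the synthetic generator emulates

Real recordings cannot ship with a package, so `generate_dataset()`
produces triads with the statistical structure the analysis assumes:

- **Turn-taking speech.**  Alternating exponential turns (mean 6 s) and
  gaps, next speaker uniform among the other two.  The gap mean is derived
  from the target per-participant speech-free fraction (default 0.77, the
  observed order of magnitude for triadic conversation); with one speaker
  at a time, a participant speaks one third of the triad's speaking time,
  so the expected fraction is exact by construction.  Speech timing is
  *condition-independent* by default — deliberately, so the speech-binary
  control sits at chance.
- **Burst-like AU episodes.**  A Poisson process per AU (defaults: 2/min
  for AU4, 3/min for AU6 and AU12) places episodes with gamma durations
  (mean 2 s, SD 1 s), uniform amplitudes in [0.5, 0.95], and a
  rise–plateau–fall (trapezoid) profile over uniform baseline noise in
  [0, 0.08].  The waveform shape is a modelling choice; any smooth bounded
  bump behaves equivalently under GADF.
- **A purely dynamic condition signal.**  In the default, marginals-matched
  configuration both conditions share every per-AU rate, duration and
  amplitude distribution; they differ only in the probability that an AU6
  episode recruits a *synchronous* AU12 episode (0.15 vs 0.85) — the
  Duchenne-smile-like co-activation contrast.  Per-AU static summaries are
  then condition-uninformative *by construction*, while the joint temporal
  alignment of the G and B image channels carries the label.  This is the
  cleanest way to make "dynamics decodable, statics not" true on purpose,
  which is exactly the contrast the control analyses are designed to
  detect.  An `onset_beta` knob can additionally concentrate episodes
  early in the conversation to study segment-position effects.

What the generator does **not** emulate: AU-estimator noise and its
autocorrelation, cross-participant mimicry, laughter/filler events,
camera-loss dropouts, or any real difference in speech timing between
conditions.  Passing tests therefore demonstrate that the pipeline
*recovers a known dynamic signal and rejects known confounds* — not that
real conversations are classifiable at any particular accuracy.

## Numerical and design choices

- **Masking before normalization.**  The inserted zeros participate in the
  per-channel min/max, following the declared processing order (mask, then
  encode).  A fully masked (constant) channel has no scale and is encoded
  as an all-zero channel with a warning.
- **Frame/interval conventions.**  Frame $i$ covers $[40i, 40(i+1))$ ms;
  a frame is speech if its window intersects any speech interval (the
  strictest inclusion rule).  Segment positions: `first` = $[0, L)$,
  `middle` centered on the midpoint frame (left-biased on odd remainders),
  `last` = $[T-L, T)$.
- **Working length.**  A full 15-minute recording is 22 500 frames; its
  raw Gramian field would be $22\,500^2$ per channel.  Series are
  mean-pooled to a working length (default 1024) before GADF and the field
  is bilinearly resized (corner-aligned; exact identity at equal sizes) to
  the network input side.  Analyses in this package use working length 256
  and side 64: at 3–4 s per pooled bin the 2 s episodes remain clearly
  visible as image blocks, and a 5-seed, 5-fold experiment fits in minutes
  on one CPU core.  Side 224, matching common pretrained backbones,
  remains the `encode_participant()` default.
- **The classifier.**  No deep-learning framework is assumed: the network
  (two 3x3 conv + ReLU + max-pool stages, global average pooling, a small
  dense head, sigmoid output) is implemented in compiled code inside the
  package, trained with Adam on binary cross-entropy, early-stopped on
  validation loss (patience 10), all randomness drawn from R's RNG so
  results are exactly reproducible under a seed.  `"tiny"` (8/16 filters)
  is the tested desk-scale backbone; `"small"` doubles the widths.
  Transfer-learned pretrained backbones would require external weights and
  are outside the package's scope.
- **Aggregation and ties.**  A triad's probability is the mean of its
  participants' probabilities (majority vote available); probability
  exactly 0.5 predicts the positive class.
- **Fold plan.**  Test sets partition the triads across the 5 folds
  (stratified by label); a validation set (~10% of triads, stratified) is
  carved from the remainder of each fold, leaving ~70% for training.
- **Metric intervals.**  Accuracy and MCC get `point ± 2.05 × SE` where SE
  is the between-fold standard error — a fold-dispersion summary, not a
  binomial interval, and labelled as such.  The AUC interval uses the
  DeLong U-statistics variance.  MCC is 0 by convention when a confusion
  marginal is empty.
- **Statistics conventions.**  The two-sample t is Student's pooled
  (df $= n_1 + n_2 - 2$, matching the reported df = 93 for a 78-vs-17
  split), not Welch; Cohen's d shares the t's sign convention.  The 2x2
  chi-square is uncorrected by default with a Yates flag.  Fleiss' kappa
  requires equal raters per item, so the rating report stratifies videos
  by their number of raters.  The permutation control shuffles within
  speech-free frames only (scope `"all"` is available), leaving masked
  zeros in place.

## Problem sizes used by the tests

The packaged experiments run the study-scale design — 28 triads of three
participants, 900 s at 25 fps — with the tiny backbone at side 64 /
working length 256, five cross-group folds, five generator/training seeds
(the recovery, permutation and speech-binary experiments share data and
fold plans per seed).  Smaller configurations appear in unit tests only to
exercise code paths, never to report performance.

## Known limitations

- Generator parameters are plausibility choices, not fits to recordings;
  absolute accuracies on synthetic data do not transfer to real data.
- The scratch CNN is deliberately small; with pretrained features the
  image pipeline would likely separate weaker dynamic signals.
- Between-fold CI widths depend on the fold count (k = 5) and are wide;
  they should be read as dispersion summaries.
- The speech-segment process is memoryless and condition-independent;
  studying condition-dependent turn-taking requires passing per-condition
  speech parameters explicitly.
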