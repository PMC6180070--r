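---
title: "Trajectory segmentation analysis of Morris Water Maze swimming paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory segmentation analysis of Morris Water Maze swimming paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwmtsa)
```

## The problem

In the Morris Water Maze a rodent swims in a circular pool (here 200 cm in
diameter) until it finds a hidden platform (12 cm in diameter) or a 90 s
timeout elapses.  Classical endpoints — escape latency, path length, mean
speed — summarise a trial with one number and miss *how* the animal
searched.  Whole-trial classification into exploration strategies
(thigmotaxis, incursion, scanning, focused search, chaining response,
self-orienting, scanning surroundings, target scanning, direct finding) is
better, but a single trial usually contains several behaviours in
sequence, so forcing one label per trial discards information.

`mwmtsa` implements segment-level strategy analysis: swimming paths are cut
into heavily overlapping windows of constant arc length, each window is
described by eight geometric features and classified into one of the nine
strategies by an ensemble of semi-supervised clustering classifiers, and
the overlapping window classes are smoothed back onto the full path.
Group comparisons are then run per strategy on the smoothed profiles.

## The procedure and its assumptions

1. **Segmentation.**  Each trajectory is divided into segments of a fixed
   arc length (2--3 arena radii R; `segmentation_config()`), consecutive
   segments sharing 70--90% of their arc.  Boundaries snap to the nearest
   tracking sample at or beyond the target arc position, so segments are
   true sample runs; the trailing partial window is discarded.
   Trajectories shorter than one segment cannot be segmented at all; they
   are the signature of a direct platform run and are classified Direct
   Finding end to end (a whole-path label can override this).

2. **Features.**  Eight descriptors per segment, all invariant to
   rotation, translation and uniform rescaling of the setup: median and
   IQR of the distance to the pool centre (in units of R), focus,
   eccentricity of the coordinate covariance, path efficiency, the
   coefficient of variation of the distance to the centre, the summed
   absolute heading change, and the minimal distance to the platform (in
   R).  Columns are standardised by median/IQR and winsorised at ±4
   robust units — the turn sum in particular is heavy-tailed, and without
   clamping a handful of outlying segments dominates every distance the
   clustering later computes.

3. **Partial labels and constraints.**  An expert labels roughly 8--12% of
   segments with one or, for segments straddling two behaviours, two
   strategies.  Single-labelled segments sharing a strategy yield
   must-link pairs; segments with disjoint label sets yield cannot-link
   pairs.  Two-label segments never anchor a must-link and never receive
   a cannot-link against either of their own labels: a straddling segment
   genuinely belongs to both classes and a hard constraint would be
   wrong.  Must-links are sampled as a sparse connected chain (plus a few
   random extras) through each class rather than as a dense random graph:
   with hundreds of same-class pairs the violation penalties weld all of
   a class's labels into a single cluster, which starves the
   cluster-to-class mapping as soon as the target cluster count exceeds
   the number of classes.

4. **MPCK-Means classifiers.**  The core classifier is metric pairwise
   constrained k-means with one learned diagonal metric per cluster.  The
   objective per point is the metric-weighted squared distance to its
   cluster centroid minus the metric's log-determinant, plus penalties
   for violated must-links (half the sum of the pair distance under both
   endpoint metrics) and violated cannot-links (the complement of the
   pair distance against the per-cluster maximum separation).  Fitting
   alternates a sequential greedy assignment sweep, a centroid update and
   an exact per-dimension metric update; each step is coordinate descent
   on the same objective, so the objective trace is non-increasing — this
   is asserted in the test suite on every fixture.  Centroids initialise
   from the must-link transitive closure (one neighbourhood mean per
   connected label group); the remainder is drawn by seeded
   distance-proportional (D²) sampling over constraint-anchored points.
   A deterministic farthest-point traversal was evaluated instead and
   repeatedly seeded centroids at extreme outliers, leaving clusters with
   no labelled members and 15--35% unclassifiable predictions, so the
   randomised D² variant was adopted.  Clusters are mapped to the modal
   strategy among their labelled members (two-label records count 1/2
   towards each label); unlabelled or tied clusters stay unassigned and
   predict `UNDEFINED`.

5. **Cross-validation and the ensemble.**  One classifier is fitted per
   target cluster count K (10--100 by default; problem-sized subranges
   such as 10--40 behave equivalently on the synthetic conditions below).
   Each is scored by 10-fold cross-validation stratified by first label;
   folds are shared across the pool so the ensemble can later be scored
   on the very same held-out splits.  Per fold the model is refitted on
   the full feature matrix (clustering is transductive — unlabelled
   segments always participate) with constraints touching held-out
   segments removed.  A held-out prediction is correct when it lies in
   the record's label set; `UNDEFINED` counts as an error.  Classifiers
   with CV error strictly below 25% are *strong*; at least 40 strong
   members are required by default before any result is reported
   (`select_strong()` fails with an "insufficient labelling" error
   otherwise), and the ensemble classifies by equal-weight majority vote.
   Member abstentions are discarded before counting and a strict tie
   leaves the segment `UNDEFINED`: an abstention is not an opinion, and
   this choice is what lets the ensemble's unclassified rate fall well
   below each member's.

6. **Smoothing onto paths.**  Paths are re-divided into consecutive
   non-overlapping intervals of length R.  Each interval takes the class
   maximising the sum, over classified segments that overlap it in arc
   and lie within twice the kernel width of its centre, of the class
   weight times a Gaussian kernel of the centre-to-centre distance
   (width sigma = R).  The kernel cutoff is implemented as `exp(-2)`
   (0.1353…, commonly printed as 0.14) so a segment at exactly twice the
   width still votes.  Class weights are inversely proportional to the
   class's share of classified segments, with shares clipped into
   [0.01, 0.5] *before* inversion and the weights renormalised to sum to
   one.  The alternative reading — clipping the final weights into
   [0.01, 0.5] — would hand rare classes the smallest weights and defeat
   the stated purpose of protecting them from common classes, so the
   clip-then-invert order is used.  Share clipping happens at the
   experiment level: weights are class-level quantities, not per-trial
   ones.

7. **Statistics.**  Two cohorts are compared per strategy (and for the
   per-trial count of strategy transitions) with a Friedman test: one
   block per trial, two columns holding the per-group means of the
   per-animal measure.  Blocks cannot pair animals because the cohorts
   are unequal (30 vs 27 in the emulated design), so trial-blocked group
   aggregates are the consistent reading of a k = 2, df = 1 design.  The
   statistic uses mid-ranks and the tie correction
   (`sum(r^2)`-denominator form); base R's `friedman.test` omits the
   correction, which is why the package carries its own implementation —
   the two agree to 1e-10 on tie-free data, which the test suite checks.
   On top of the ensemble's verdict, every strong member is asked whether
   *its own* classification yields a significant difference; the share of
   members agreeing is summarised by an exact Clopper–Pearson 95%
   binomial interval, and a conclusion is only CONFIRMED when the whole
   interval lies above 0.5.  The exact interval was chosen over a normal
   approximation because member counts are small (about 40) and observed
   proportions sit near 0 or 1, where the Wald interval fails.

## The synthetic cohort generator

Because the original stress-rat recordings cannot be redistributed, the
package ships a seeded generator that emulates the study conditions: a
200 cm arena, 12 cm platform half-way between centre and wall, 90 s
timeout, 10 Hz sampling, 25 cm/s swimming speed, and two cohorts
(defaults 30 and 27 animals, 12 trials each as 4 trials over 3 days).
Each trial is a concatenation of strategy bouts drawn from the group's
mixture; every bout is a correlated random walk shaped per stereotype
(wall-hugging at 0.925 R for thigmotaxis, inward excursions for
incursion, a central random walk for scanning, a tight mean-reverting
search away from the platform for focused search, circling at the
platform's wall distance for chaining, a loop then interior reorientation
for self-orienting, a close platform pass followed by mid-pool wandering
for scanning surroundings, a search concentrated around the platform for
target scanning, and a near-straight platform run for direct finding).
Bout arcs are drawn uniformly between 2 and 4 arena radii: the framework
cannot resolve behaviours shorter than two radii of arc, so the generator
stays at or above that scale to keep its own ground truth recoverable.
Trials end at platform contact or timeout, and all randomness descends
from one master seed.

`auto_label()` emulates the expert labelling stage: a stratified sample
(10% of all segments by default) drawn from segments whose dominant bout
covers at least 65% of their arc — a human labels segments they can
recognise and skips hopeless blends — labelled with the majority bout
class, plus a second label when another bout covers at least 25%.

What the generator does *not* emulate: learning across trials (mixtures
are stationary), inter-animal variability beyond sampling noise, tracking
artefacts (dropouts, reflections, jitter beyond the kinematic noise), and
any cognitive model of navigation.  Passing the recovery suites therefore
shows that the pipeline recovers planted, stationary, kinematically clean
structure — not that it would classify any particular real dataset
correctly.

## Numerical choices and degenerate inputs

* Constraint-violation penalty weights default to 1 in standardised
  feature units; metric entries are floored at 1e-6 and capped at 1e6.
* The assignment loop runs to an assignment fixpoint or 200 iterations,
  whichever comes first, and always performs at least two iterations so
  the first M-step is never skipped.
* Empty clusters keep their previous centroid; clusters with no members
  keep identity metrics.
* Zero-IQR feature columns standardise with scale 1 and a warning.
* Rows with missing or non-numeric coordinates are dropped (and counted)
  rather than interpolated; out-of-arena samples within 5% of R are kept,
  as wall-hugging data with tracking jitter would otherwise vanish.
* All-identical segment points are a degeneracy and raise an error;
  elapsed time of zero in `path_metrics()` likewise.
* Exact vote ties — in the ensemble and in the interval vote — yield
  `UNDEFINED` rather than an arbitrary winner.

## Problem sizes used in the validation suites

The test suite exercises the full workflow on cohorts of 2 × 10 animals
× 12 trials (thigmotaxis mixture 0.45 vs 0.15, 10% labels, K = 10..40,
at least 15 strong members), on which it checks the unclassified rate,
the ensemble-versus-member error ordering, and detection of the planted
thigmotaxis difference across ten seeds.

The segmentation-robustness suite compares the conclusive strategy set
(Friedman significant *and* binomial interval clearly above 50%) between
2 R and 2.5 R segmentations at the same overlap, on a cohort whose
mixtures differ decisively in exactly two strategies (thigmotaxis and
incursion, with the remaining classes carrying identical shares in both
groups).  Mixtures are compositional: when every class share differs a
little between groups, some strategy inevitably sits at the statistical
power boundary and its significance flag flips between segmentations by
sampling noise alone, which would test power stability rather than
segmentation sensitivity.  Balancing the "loud" mass (0.50 in each
group) keeps the quiet classes at genuinely equal shares; incursion was
chosen as the second loud strategy because platform-seeking strategies
terminate trials early and would bias every other class's share through
the denominator.  The type-I suite runs
the trial-blocked Friedman comparison on 100 cohorts of 2 × 5 animals
with identical mixtures and a 45 s timeout, using ground-truth strategy
shares.  These sizes were chosen so the planted effect is comfortably
detectable while each suite completes in minutes; the trial-blocked
two-column Friedman design is discrete (ranks per block are a single
binary comparison), which makes the test slightly conservative at the
5% level — the suite asserts exactly that.

## Known limitations

* Strategies shorter than about two arena radii of arc cannot be
  resolved; very short trajectories are classified Direct Finding by
  construction.
* The cluster-to-class mapping needs labelled members in most clusters;
  with very sparse labelling, large K classifiers degrade and the strong
  gate (deliberately) fails.
* The per-cluster metrics are diagonal; strongly correlated feature
  pairs within a class are modelled only up to axis-aligned scaling.
* Friedman blocks are trial-level group means, so the test compares
  group profiles over trials and does not model animal-level pairing.
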