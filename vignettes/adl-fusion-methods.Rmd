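---
title: "Evidence fusion for egocentric activity recognition: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence fusion for egocentric activity recognition: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlfuse)
```

## The recognition problem

A wearable device (chest-worn camera plus a 6-axis IMU, with GPS from a
paired phone) observes a person's day as three loosely coupled streams:
an egocentric image every 4 s, accelerometer/gyroscope traces at 90 Hz,
and occasional GPS fixes.  The task is to label each image instant with
one of 15 activities of daily living (ADLs): cleaning, computer use,
eating, entertainment, lying down, meeting, reading, shopping, talking,
telephone use, transportation, walking outside, washing up, watching TV,
writing.

No single stream is sufficient.  Image content distinguishes
environments but confuses activities with near-identical object sets
(reading vs. writing); motion separates locomotion from stillness but
not one sedentary activity from another; a person's routine is
informative but coarse.  `adlfuse` treats each stream as an evidence
*source* that emits a basic belief assignment (BBA) over the activity
frame, and combines them with Dezert–Smarandache theory (DSmT) using
proportional conflict redistribution.

## Belief model

The frame of discernment Θ is the ordered set of 15 activities
(`adl_frame()`); the order is total and breaks all ties
deterministically.  A BBA assigns non-negative mass to focal elements —
subsets of Θ — summing to 1 with zero mass on the empty set.  The
package implements the power-set (Shafer) model: distinct activities are
mutually exclusive, so singleton focal elements intersect to the empty
set, and the full frame Θ is admissible (the vacuous BBA represents
total ignorance and is neutral under combination).  Every source in this
pipeline emits *Bayesian* BBAs (all mass on singletons); set-valued
focal elements are supported throughout (combination, restriction,
serialization) but intersections of distinct hypotheses — the free-DSm
part of the hyper-power set — are never enumerated as focal elements,
because nothing in the pipeline produces them.

Mass vectors published in rounded form (4 decimals) do not sum exactly
to 1; the constructor renormalizes deviations up to $10^{-3}$ with a
warning and rejects anything larger.

## Combination rules

For two sources, PCR5: the conjunctive consensus assigns each pair of
focal elements the product of their masses on their intersection; each
*conflicting* product $m_1(X_1)m_2(X_2)$ with $X_1 \cap X_2 =
\varnothing$ is redistributed back to $X_1$ and $X_2$ proportionally to
$m_1(X_1)$ and $m_2(X_2)$.  For $s$ sources, PCR6 generalizes the same
redistribution: a conflicting tuple's product goes back to its
generating focal elements, source $i$ receiving the fraction
$m_i(X_i)/\sum_j m_j(X_j)$.  PCR6 reduces exactly to PCR5 at $s = 2$; a
redistribution term with zero denominator necessarily has a zero
numerator and is defined as 0 (continuity convention).

The implementation enumerates focal-element tuples and accumulates
shares; the test suite checks it against an independent
focal-element-centric enumeration (the closed-form expression summed per
receiving element) on the full 0.05-mass grid over 3-label frames, plus
random cases to size 15.  `combine_pcr5()` canonicalizes its argument
order internally, so symmetry holds bit-for-bit, not merely to rounding.
`combine_pcr6_bayesian()` is a vectorized batch path for Bayesian
sources used for large-scale verification and high-throughput scoring.

## The three sources

**Knowledge.**  A wearer authors one or more condition–activity tables
scoring each activity 0 (impossible) to 10 (assured) per clock-time
period, optionally per location and per previous activity, with separate
weekday/weekend time tables.  A printed period "a–b" is canonicalized to
the half-open interval [a, next period's start); an end time of 00:00
means midnight.  The row covering a timestamp is normalized by its sum
into a Bayesian BBA (so scaling a row changes nothing).  An all-zero row
abstains — uniform BBA with a warning — rather than vetoing the other
sources.  Timestamps in uncovered gaps follow a configurable policy
(nearest period by default; the package's generated tables tile the day,
leaving only the first minute of the day uncovered).  When location or
previous-activity context is supplied and the profile holds those
tables, the per-table BBAs are chained with PCR5 in the fixed order
time, location, transition; the chaining order is this package's choice,
as is PCR5 for the job (any associative-enough combination would do at
this granularity).

**Image tags.**  An external annotator (a pre-trained CNN in the
original setting; any tool honouring the JSON-lines contract works)
emits ~20 textual tags per image — a bag of tags (BoT).  Training pools
per-activity tag statistics and scores each (tag, class) pair with an
entropy-weighted TF-IDF: term frequency over the class's pooled tags,
smoothed inverse document frequency over all BoT-documents (natural
log, one BoT = one document), an occurrence-entropy factor $e1$ across
the class's documents (base 2; uniform occurrence maximizes it at
$\log_2$ of the class size), and a document-entropy factor $e2$ across
classes remapped by $R(e2) = 1 - e2/(\log_2 K + \lambda)$ so that tags
spread evenly over classes are damped; $\lambda = 0.01$ keeps $R$
strictly positive.  The naming follows the field's convention for this
construction ($e1$ "inter-class", $e2$ "intra-class"), even though $e1$
is computed within one class and $e2$ across classes — the formulas are
authoritative.  The $M = 20$ top-weighted tags per class form its
centre; idf's "+1" smoothing can push weights of ubiquitous tags
negative, and negative weights are clipped to 0 because the centres feed
a ranking and a cosine space where negative mass has no meaning.  The
idf statistics are computed over all documents, not per class — the only
reading that defines one idf per tag.  Classification embeds a bag's raw
tag counts and every centre in the union vocabulary of the centres,
takes cosine similarities, and sum-normalizes them into a Bayesian BBA
(similarity vectors do not sum to 1 on their own; a bag sharing no tag
with any centre yields the uniform BBA with a low-confidence flag).
Ties in the top-M ranking break lexicographically; tags are casefolded
and trimmed, never stemmed.

**Motion sensors.**  IMU streams are cut into non-overlapping 3-s
windows centred on each image timestamp (270 samples at 90 Hz; short
edge windows are padded by edge replication and flagged, timestamps with
no samples within ±1.5 s are skipped).  Each window yields a
127-dimensional vector.  The feature families are standard for
body-worn inertial classification; their exact composition is this
package's documented layout:

| block | per channel | count |
|---|---|---|
| mean, sd, range, RMS | 4 × 6 channels | 24 |
| Burg AR coefficients, order 6 | 6 × 6 channels | 36 |
| binned distribution, 10 equal-width bins over the window's min–max | 10 × 6 channels | 60 |
| accelerometer pairwise correlations | — | 3 |
| signal magnitude area (accelerometer) | — | 1 |
| GPS speed, latitude, longitude | — | 3 |

Degenerate inputs are defined away explicitly: zero-variance channels
get zero AR coefficients and zero correlations; a flat channel puts all
binned mass in bin 1; a missing GPS fix falls back to the most recent
fix, or zeros with a missing flag when none exists.  Burg estimation is
used because it is stable on 270-sample windows.  A one-against-one
multiclass SVM with an RBF kernel (libsvm via `e1071`) is trained on
standardized features; `(cost, gamma)` are chosen by 5-fold
cross-validation over a logarithmic grid whose gamma arm brackets
$1/127$ (the natural scale for standardized features) and extends to the
larger values reported as operating points for this kind of data.
Sigmoid (Platt) calibration turns decision values into class posteriors,
which are the singleton masses of the sensor BBA; frame labels absent
from the training data get mass 0.

## Hierarchical fusion with descending candidates

Knowledge and image are high-priority sources; motion is low-priority
and consulted only on conflict.  Level 1 fuses knowledge and image with
PCR5.  The default conflict predicate is disagreement of the two
sources' arg-max decisions (ties resolved by frame order before
comparing); an alternative predicate — conjunctive conflict mass of the
pair above a threshold — is selectable, since the two readings of
"conflicting result" are both defensible.  Without conflict the level-1
arg-max is final and the sensors are never consulted.  On conflict, the
$N_c$ top-mass singletons of the *level-1 fused* BBA (not of either raw
source) become the candidate set — the text's "candidates identified by
two-source fusion" — all three source BBAs are restricted to the
candidates and renormalized, and a three-source PCR6 fusion decides; the
final label always lies in the candidate set.  $N_c = 3$ by default,
matching the observation that no more than three activities are
frequently confused with any one sedentary activity.  Ties at the
candidate boundary keep the earlier frame label.  A restriction that
would drop all mass returns the uniform BBA over the candidates and
flags the event.

The simplified variant covers wearers without knowledge tables:
candidates come directly from the image BBA, and image and sensors fuse
with PCR5 over the restricted frame.  With $N_c$ equal to the frame size
and the conflict rule forced true, the full network degenerates to plain
three-source PCR6, which is how the package reproduces the published
worked example (`reproduce_worked_example()`).

## The synthetic benchmark

No deposited dataset exists for this pipeline, so the package ships a
seeded generator (`generate_dataset()`) that emulates the statistical
structure each stage assumes; all of its distributions are this
package's modelling choices, recorded in `default_activity_profiles()`.

* **Tags**: each image draws 20 tags from a mixture of the activity's
  8-tag signature vocabulary (probability 0.5) and a 40-tag shared
  background with a Zipf-like profile.  A signature draw leaks, with
  probability 0.35, to a *visually confusable neighbour* (reading ↔
  writing, computer use ↔ telephone use, watching TV ↔ entertainment,
  …), emulating shared objects in view.  These two rates place the
  image source near the ~80 % accuracy that vision-only recognition
  achieves on real egocentric data — good but genuinely imperfect —
  rather than saturating it.
* **IMU**: four regimes — sedentary (low-variance noise around
  gravity), periodic (a ~2 Hz gait oscillation for walking, slower for
  shopping), irregular (bursty noise for cleaning and washing up) and
  reoriented (gravity rotated to the device's x-axis for lying down) —
  with per-window amplitude and frequency jitter.  All sedentary
  activities share one regime by design, so motion alone cannot separate
  them, mirroring what body-worn sensors actually resolve.
* **GPS**: log-normal speeds (≈10 m/s transport, ≈1.4 m/s walking,
  ≈0.6 m/s shopping, near zero otherwise), anchored coordinates with
  small jitter, and a 5 % fix-dropout rate to exercise carry-forward.
* **Schedules**: each activity holds one to three clock-time windows
  with scores 8–10 for routine anchors (meals, commutes, sleep) and 6–8
  for leisure; the generated weekday/weekend tables score each hourly
  row by its overlapping windows.  A sample's timestamp falls inside its
  activity's own windows with probability 0.8, else uniformly over the
  day, so the knowledge source is informative but far from decisive.

The design goal is the property the fusion claims need: each source
alone is imperfect (on the default seed, macro-F1 ≈ 0.19 knowledge,
≈ 0.86 image, ≈ 0.45 sensors at 100 samples per class) and their errors
are only partially dependent, so hierarchical fusion gains several
macro-F1 points over the best single source.  What passing these tests
does *not* show: real CNN annotators emit open vocabularies with
correlated noise, real routines drift across days, and real IMU data
carry device-orientation and calibration artifacts none of which the
generator models.  The benchmark validates the fusion machinery, not
field performance.

## Numerical and scale choices

* Acceptance-scale runs use 100 samples per class for training and
  testing (3 000 windows totalling ~8·10⁵ IMU samples); unit tests use
  2–30 samples per class on reduced frames.  These sizes give stable
  macro-F1 estimates while keeping a full run in minutes on one core.
* The SVM grid is cost ∈ {4, 16, 64} × gamma ∈ {0.008, 0.033, 0.13,
  0.57}; the first maximum in grid order wins, making selection
  deterministic under ties.  All stochastic steps (generation, fold
  assignment, calibration) run under explicit seeds, and two runs with
  one seed are byte-identical, including written artifacts.
* Evaluation reports per-class precision/recall/F1 (harmonic mean, 0
  when P + R = 0), unweighted macro averages, and sample-weighted
  accuracy; both macro and micro views are reported because "average
  accuracy" is ambiguous between them.  A class absent from predictions
  and gold is scored 0 and flagged rather than dropped.

## Known limitations

* The free-DSm hyper-power set is not enumerated; sources emitting
  genuine intersection hypotheses would need a richer focal-element
  model.
* Only two fusion levels and three sources are wired; temporal smoothing
  across consecutive images (activity durations, transition dynamics
  beyond the optional transition table) is out of scope.
* The tag classifier ignores tag order within a bag by construction.
* Retrained sensor accuracies are not comparable to any published figure
  obtained with a different (unstated) 127-feature composition; the
  layout above is authoritative only for this package.
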