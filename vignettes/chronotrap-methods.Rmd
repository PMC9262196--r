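---
title: "From sticky-trap image series to community chronoecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sticky-trap image series to community chronoecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Camera-equipped adhesive traps photograph the same sticky card every
20 minutes for a week. Each frame shows every insect captured so far, so the
series is a cumulative record: a new arrival appears as a new blob and stays
(mostly) put, while occasional escapes, predation and transient occlusions
erode the record. `chronotrap` turns such series into per-taxon capture
times and the circadian statistics built on them. This vignette explains
the models and the choices behind each stage; the README shows a worked
example.

## 1. Detection on overlapping tiles

Instance segmentation runs per frame through a pluggable per-tile segmenter.
Tiles (default 1024 px, 4 x 3 on a 2592 x 1944 px image, planned by
`plan_tiles()`) are evenly spaced with the first tile at the origin and the
last flush with the far edge, which leaves more than 500 px of overlap —
enough that any insect narrower than 500 px is complete in at least one
tile. A candidate instance B is kept if and only if its Jaccard index with
every already-accepted instance from neighbouring tiles is below 0.5; tiles
are visited in fixed row-major order so the rule is deterministic and
idempotent.

Two practical rules surround the Jaccard test. First, the frame is padded by
a 32 px margin before tiling so border insects keep context; the default
padding value is the image median (the card background) because the shipped
classical segmenter would read a black border as foreground, whereas a
learned backend trained with zero padding can pass `pad_value = 0`. Second,
a mask cut by an *interior* tile edge is discarded before deduplication:
the layout guarantees the same insect is complete in a neighbouring tile,
and a fragment smaller than half the full mask would otherwise slip past
the J < 0.5 rule and duplicate the insect.

Detections shorter than 30 px or longer than 600 px (longest bounding-box
side, both bounds inclusive) are discarded — below 30 px (about 2 mm at the
imaging scale of 15.5 px/mm) objects are ambiguous even to annotators, and
objects above 600 px are almost always artefacts. The same filter applies
to SVG annotations read with `read_svg_annotations()`.

The shipped segmenter is deliberately classical: Otsu's threshold on the
inverted intensities, capped at `median + max(min_contrast, 6 MAD)` above
the background level — the cap matters when the scene holds insects of
several darkness modes, where an unconstrained Otsu can land *between*
insect modes and shatter the darker blobs — followed by a 3 px
morphological closing and connected-component labelling (with an optional
watershed split for touching blobs). It is adequate for the synthetic
scenes used in testing; field imagery should attach a learned backend
through the same per-tile contract.

## 2. Pairwise matching

Whether two detections in different frames are the same insect is scored by
`M(m, n) in [0, 1]`, computed from five features:

* **S**, naive similarity: descriptor similarity of m's masked crop in its
  frame versus n's masked crop in its frame;
* **Q**, delayed self-similarity: m's masked crop versus the *same pixel
  footprint* in the later frame. High Q says the first insect never moved —
  evidence against matching it to a different blob;
* the Euclidean centroid distance (px);
* `|log(A_m / A_n)|`, the absolute log area ratio;
* `log(dt + 1)` with dt in hours (hours because the gap-bridging rule is
  expressed in hours; the unit is a package choice).

The descriptor contract takes crops rescaled to 105 x 105 px and returns a
similarity in [0, 1], symmetric with D(x, x) = 1. The default backend is
normalized cross-correlation clipped below at zero: clipping (rather than
the affine map (r + 1)/2) keeps unrelated pairs near 0 instead of exactly
at the 0.5 decision threshold. A Siamese network trained on field data
plugs in through the same contract.

The decision head is a 5-4-3-1 fully connected network (rectifiers after
the first two layers, sigmoid output) over z-scored features; the
normalization constants are stored with the head. `fit_matcher()` follows a
three-phase schedule — backend pretraining, head-only training, joint
fine-tuning — with each batch re-balanced to 50% negatives regardless of
the input mix. With the default (non-trainable) backend, phases 1 and 3
are structural no-ops recorded in the returned schedule. A logistic
regression on the same five features is available as a fallback head.

## 3. Three-pass tracking into tuboids

Tracking is graph construction: detections are vertices, edges run strictly
forward in time, and every vertex has at most one incoming and one outgoing
edge. Each weakly connected component is one "tuboid" — the multi-frame
record of one trapped insect.

1. **Contiguous linking.** For each frame transition, an instance connects
   to its best-scoring candidate in the next frame when the score clears
   k = 0.5. Two instances can prefer the same target; candidate pairs of a
   transition are therefore processed in descending score order, accepting
   a pair only while both endpoints are unused. This resolution is the
   package's choice (ties break by smaller centroid distance, then smaller
   vertex id); an exhaustive reference implementation in the test suite
   confirms the greedy sweep equals recursive global-argmax extraction on
   every small fixture.
2. **Gap bridging.** Tuboid tails (out-degree 0) are matched to tuboid
   heads (in-degree 0) more than one frame but less than 12 h later,
   repeatedly adding the single highest-scoring admissible edge above
   k = 0.5 and re-evaluating, until none remains. This reconnects insects
   that were occluded or missed for a few frames.
3. **Conjoint merging.** Two tuboids are *conjoint* when they overlap in
   time but share no coincident frame. For each conjoint pair the mean
   score over neighbouring vertex pairs (each vertex against its immediate
   predecessor and successor in the other tuboid) is computed; the
   highest-scoring pair above k = 0.25 is merged (vertices interleaved by
   time, edges re-chained) and merging repeats to a fixpoint, so newly
   merged tuboids are re-examined. A single sweep would be the other
   defensible reading; the fixpoint is this package's choice.

Components with fewer than 4 vertices are then dropped: an object seen in
fewer than 4 frames over a week is more plausibly noise than an insect.
Degree and forward-time invariants are asserted after every pass rather
than assumed.

One desk-scale concession: the series scorer gates candidate pairs by
centroid distance (default 150 px) and scores distant pairs 0 without
invoking the descriptor. Trapped insects jitter by a few px, so on the
synthetic scenes the gate only skips hopeless pairs; disable it with
`gate_px = Inf`.

## 4. Multi-frame classification

Each tuboid receives one taxonomic label from several frames at once:
the first frame plus 5 drawn uniformly (without replacement when possible,
with replacement otherwise — tuboids can be as short as 4 frames) from the
first 24 h. Each sampled crop is embedded by a pluggable per-frame
embedder; the fused vector is the element-wise median, which is invariant
to frame order and robust to a minority of corrupted frames (insects decay,
get partially occluded, or change illumination). The object's physical
scale — the median longest bbox side, converted to mm at 15.5 px/mm — is
appended once after fusion: the scale is frame-invariant for a tuboid, so
appending it per frame before a median over identical values would be
equivalent; appending once is simpler and is the package's documented
placement.

The label head is multinomial logistic regression (`nnet::multinom`) over
the fused features — the "last fully connected layer" of the architecture,
fit directly. The default embedder (radial darkness histogram, Hu moments,
global statistics) separates synthetic taxa of distinct size and darkness;
field imagery should attach a deep per-frame embedder through the same
contract. Label schemes are explicit, ordered and mergeable (e.g.
collapsing the two catch-all classes "Background objects" and "Undefined
insects"); merged probabilities are summed, so rows still sum to 1.

## 5. Chronobiology

**Warped Zeitgeber time.** Zeitgeber time (hours since sunrise) makes days
of different lengths incomparable at dusk. WZT rescales ZT piecewise
linearly so sunrise maps to 0 and sunset always to half a day: `W(z) = a z`
for `z <= d`, else `a' z + b'`, with `a = 1/(2d)`, `a' = 1/(2(1-d))`,
`b' = 1 - a'` where d is day length as a day fraction. Solar noon then sits
at 1/4 day and solar midnight at 3/4 day for any d, and at d = 1/2 the map
is the identity. The map is continuous, strictly increasing and invertible;
`wzt_params()` treats sunrise and day length as inputs, either supplied
per day or computed from latitude/longitude by the standard NOAA sunrise
equation (`sun_times()`, a textbook calculation implemented here and good
to a few minutes, which diel binning tolerates).

**Low-pass filtering.** Per-frame counts from laboratory series carry
single-frame detection noise. A running median (k = 5) on the counts,
first differencing to the instantaneous capture rate dN/dt, and a uniform
moving average (k = 5) on the rate act together as a low-pass filter with
an approximate span of k x 20 min = 100 min at the standard frame
interval. Edges use shrinking windows; a unit step in counts keeps total
rate mass of exactly one insect through the filters.

**Rhythmicity.** Per replicate series (device x week), the Pearson
autocorrelation of the rate at the bin lag closest to 24 h; per group, a
two-sided one-sample t-test of the per-series autocorrelations against 0.
The estimator uses the overlapping span with no tapering; bin width is 1 h
for event data and one frame for laboratory counts. Two-sidedness is the
conservative default. On white noise the test's type-I error is nominal
(checked at 1,000 simulations); on simulated crepuscular populations it is
strongly positive.

**Diel profiles and windows.** Profiles are means (with standard errors)
over replicate-level rates per WZT hour bin, replicates being device x
week. Window fractions compare the observed share of events inside a set
of WZT windows against the exact uniform null (total merged window length
/ 24) with a 10,000-replicate percentile bootstrap CI. Window definitions
are explicit configuration: published window conventions conflict between
sources, so the package never guesses — callers state their windows.

**Temporal niches.** Between-taxon dissimilarity is derived from the
Pearson correlation r of hourly activity profiles as
`d = sqrt((1 - r)/2)`, which maps r = 1 to 0 and perfect anti-phase to 1
and is a proper metric; a `method = "linear"` switch gives `(1 - r)/2` for
sensitivity analysis (the two orderings agree; the square root merely
restores metricity). Embedding is classical metric MDS
(`stats::cmdscale`), which is deterministic — no restarts or seeds — and
indistinguishable from stress-majorization at these problem sizes (a
handful of taxa, 24-bin profiles). Uncertainty comes from resampling
capture instances with replacement independently per taxon, 500 times;
each replicate's MDS is aligned to the point estimate by orthogonal
Procrustes (`vegan::procrustes` — rotation, reflection, translation)
before pooling, and a 95% ellipse per taxon is fit to the pooled cloud
under a bivariate t model (`MASS::cov.trob`).

**Trap saturation.** If capture is unaffected by accumulated insects, the
count in the first 3 days of a 6-day trial is a binomial half of the
total. Per taxon, the response `N_[0,3]/N_[0,6]` per trap-week is
regressed on the trap-week's total count (all taxa); t-tests of intercept
minus 1/2 and of the slope detect saturation. Trap-weeks without captures
of the taxon are excluded and counted. The intercept is an extrapolation
to an empty trap, so the test is only informative when trap totals vary
across weeks — the simulations used in testing build in that variation.

## 6. The synthetic scene generator

Every stage is testable without field data because the generator emulates
the statistical structure the pipeline assumes:

* per-taxon arrivals from an inhomogeneous Poisson process with intensity
  `base_rate x diel_profile(WZT(t))`, simulated by thinning. Profiles are
  wrapped-Gaussian bumps over one or two peak phases plus a uniform floor,
  normalised to mean 1 over 24 h so `base_rate` is the marginal rate —
  three parameters per peak cover flat, unimodal and crepuscular/bimodal
  patterns;
* insects rendered as textured ellipses (per-individual fixed speckle, so
  appearance matching has a stable signal), body length drawn per taxon
  and clamped to [30, 600] px;
* bounded random-walk positional jitter (default sd 1 px, max 5 px —
  trapped insects wiggle but do not travel);
* transient occlusion as a two-state Markov chain (default 2% per frame to
  occlude, 50% to reappear), chosen to mimic transient occlusion events
  without modelling the occluders; and permanent escape as a per-frame
  geometric hazard. Published sources do not quantify occlusion or escape
  frequencies, so these defaults are free parameters of the simulator, not
  calibrated claims;
* frames every 20 min; times are UTC epoch seconds throughout, WZT is
  applied only in analysis.

What the generator does *not* emulate — photorealistic appearance,
illumination drift, rain, dust, decay of specimens, vertebrate predation,
densely overlapping insects — bounds what passing tests show: they
validate the algorithms' logic and statistics, not field-grade detection
or classification accuracy, which depend on learned backends and real
training data.

Problem sizes used by the tests and the acceptance script are chosen for a
single-CPU desk run: a 504-frame device-week at 960 x 720 px with ~25-30
insects, 1,000 white-noise groups for the type-I check, 10,000 events for
peak recovery, 500 bootstrap MDS replicates, 100 saturation trials. Event
streams are deterministic given a seed; every random routine takes one.

## 7. Numerical conventions and degenerate inputs

Pixel coordinates are 0-based, x right, y down; a pixel covers the
half-open unit square and membership is tested at pixel centres; bounding
boxes are half-open. Jaccard and IoU are computed on rasterized masks at
native resolution. Size-filter bounds are inclusive. Ties in tracking break
by smaller centroid distance then smaller vertex id. Empty inputs return
empty outputs (dedup, size filter, tuboid extraction); an empty truth and
prediction set scores precision = recall = 1 with a logged message;
constant-profile taxa are excluded from MDS with a warning; series shorter
than the filter order skip the low-pass with a warning flag. Detection
evaluation matches one-to-one greedily by descending IoU at a 0.5
threshold (the threshold is a package choice, stated in the signature).
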