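# chronotrap

Chronoecology from time-lapse sticky-trap image series.

Camera traps that photograph an adhesive card every ~20 minutes record,
frame by frame, every insect captured so far. `chronotrap` turns such
series into per-taxon capture times and circadian statistics for whole
insect communities: who flies when, and how the community partitions the
24 h day.

The pipeline has three image-analysis stages and a statistics layer:

1. **Detection** — per-frame instance segmentation through a pluggable
   per-tile segmenter on an overlapping tile layout (default 12 tiles of
   1024 px in 4 x 3 over a 2592 x 1944 px image). Candidates are
   deduplicated across tiles by the Jaccard rule (keep B iff J(A_i, B) <
   0.5 against accepted instances from neighbouring tiles) and filtered to
   object lengths in [30, 600] px.
2. **Matching and tracking** — a matching score M(m, n) ∈ [0, 1] from a
   small decision head (layers 5-4-3-1, sigmoid output) over five
   features: naive appearance similarity S, delayed self-similarity Q
   (same pixel footprint re-examined in the later frame), centroid
   distance, |log area ratio| and log(Δt + 1). Tracking builds a directed
   graph (in/out degree ≤ 1) in three passes: contiguous-frame linking at
   k = 0.5, gap bridging (> 1 frame, < 12 h, best pair first), and
   merging of conjoint tuboids (time-interleaved, no coincident frames) at
   mean neighbour score ≥ 0.25. Components with ≥ 4 vertices become
   "tuboids" — one tracked insect each.
3. **Classification** — per tuboid, 6 frames from the first day (first
   frame + 5 random) are embedded, fused by the element-wise median,
   augmented with the object's scale (15.5 px/mm), and labelled by a flat
   multinomial head.
4. **Chronobiology** — Warped Zeitgeber time `W(z) = az` (day) /
   `a'z + b'` (night) with `a = 1/(2d)`, `a' = 1/(2(1−d))`, `b' = 1 − a'`,
   so sunset always maps to half a day; low-pass filtering of lab count
   series (median k = 5, uniform k = 5 on dN/dt; 100-min span at 20-min
   frames); lag-24 h autocorrelation rhythmicity with one-sample t-tests;
   diel profiles with device x week replication; diel-window capture
   fractions against the exact uniform null with bootstrap CIs; bootstrap
   MDS of temporal niches (d = sqrt((1 − r)/2) from profile correlations,
   500 replicates, Procrustes-aligned, 95% bivariate-t ellipses); and a
   trap-saturation linearity test (N_[0,3]d / N_[0,6]d regressed on trap
   load; intercept-vs-1/2 and slope-vs-0 t-tests).

A synthetic scene generator (diel-modulated Poisson arrivals, textured
ellipse rendering, jitter / occlusion / escape) makes the whole pipeline
testable end to end without field data; learned detection and embedding
backends attach through documented contracts.

## Worked example

Simulate a device-week with a diurnal and a nocturnal taxon, run the full
pipeline, and look at tracking quality and the diel profile:

```r
library(chronotrap)

taxa <- list(
  taxon_spec("diurnal_fly",    0.08, peaks = 6,  peak_sd = 2,
             size_px = c(50, 5), darkness = 0.7),
  taxon_spec("nocturnal_moth", 0.08, peaks = 18, peak_sd = 2,
             size_px = c(72, 6), darkness = 0.55))

res <- run_pipeline(taxa, out = "week1", seed = 7,
                    n_frames = 504, frame_interval_min = 20,
                    width = 960, height = 720)

length(res$tuboids)
#> [1] 33
round(unlist(res$tracking[c("purity", "completeness")]), 3)
#>       purity completeness
#>        0.964        0.962
head(res$profiles[res$profiles$mean > 0, c("taxon", "bin", "mean")], 3)
#>         taxon bin      mean
#> 2 diurnal_fly   1 0.2857143
#> 3 diurnal_fly   2 0.1428571
#> 4 diurnal_fly   3 0.5714286
```

Here `purity` is the per-tuboid majority-truth fraction and
`completeness` the per-truth-track largest-tuboid fraction; values near 1
mean almost every simulated insect was recovered as one uncontaminated
track. The profile table gives the mean capture rate (per hour) per Warped
Zeitgeber hour bin and per predicted taxon; over the whole week the
diurnal taxon's captures concentrate around WZT 6 h (solar noon), the
nocturnal taxon's around WZT 18 h. Artifacts
(events.csv, detections.json, tuboids.csv, predictions.csv,
diel_profile.csv and a manifest with config hash and checksums) are
written under `week1/`.

A thin command-line wrapper with `simulate`, `detect`, `track`, `chrono`
and `run` subcommands ships in `inst/cli/chronotrap.R`.

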