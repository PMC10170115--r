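# enteromap

Quantitative analysis of enteric nervous system (ENS) organization and gut
motility, built around two workflows from developmental ENS biology:

1. **Wholemount spatial statistics.** Neurons of the myenteric plexus (MP)
   reorganize during development from a near-random sheet into
   circumferentially oriented stripes, with "bridging" neurons spanning the
   gaps at a deeper z position. enteromap segments somata from wholemount
   z-stacks, maps neighbour density around each neuron with a conditional
   intensity function (CIF), and tests departure from spatial randomness
   with a z-score difference against hard-core complete-spatial-randomness
   (CSR) nulls.
2. **Ex vivo motility analysis.** Gut segments in an organ bath progress
   from muscle-intrinsic bidirectional "ripples" to neurally driven,
   distally propagating contractions that tetrodotoxin (TTX) abolishes.
   enteromap reduces tube videos to spatiotemporal maps (STMs) of diameter,
   detects and classifies contraction events, and compares baseline and
   TTX recordings.

Because such imaging data are rarely shareable, the package ships a seeded
synthetic-tissue generator (point patterns, wholemount z-stacks,
cross-section images, motility videos) with complete ground truth, so every
estimator in the chain is validated end to end.

## The statistics in brief

For a soma pattern `{p_i}` in a window `[0,W) × [0,H)`, the CIF bins the
offsets `p_j − p_i` of all ordered pairs on a lag grid over `[−L, L]²`
(default `L = 200` μm, 4 μm bins), applies a translation edge correction
(each lag divided by the fraction of reference points for which the offset
stays in the window), normalizes per reference point, and smooths with a
20 μm SD Gaussian. The map is reduced to the coefficient of variation
`S = sd/mean`, which is 0 for a flat neighbourhood map and grows with
clustering or striping. With `S_data` and a matched null ensemble
`{S_k}` from hard-core CSR (minimum separation 5 μm, 500 samples by
default),

    z_data = (S_data − mean(S)) / sd(S),
    z_k    = leave-one-out z of each null sample,
    z_diff = z_data − mean(z_k),

reported with the 2.5–97.5 percentile band of `{z_k}` (the random-value
range). Stripe spacing is estimated from the periodogram of the collapsed
CIF profile. Neuron number in dense tissue is estimated as labelled area /
138 μm² (the area of a 9.374 μm diameter soma), and subtype fractions as
double-positive counts over that estimate. STM diameter is the thresholded
silhouette extent per position and frame; events are connected regions of
diameter deficit, with velocity from a least-squares fit to the contraction
front.

## Worked example

```r
library(enteromap)

# a striped MP field: 300 somata, 150 um period, hard-core 5 um
p  <- generate_point_pattern("striped", n = 300, seed = 1)
zs <- zscore_difference(p, n_sim = 100, seed = 2)
zs
#> <ens_zscore> n = 300, z_diff = 76.672 (null band [-1.720, 2.559], 100 samples, d_min 5 μm)

# L = 400 resolves several stripe cycles (warns: far lags use fewer points)
stripe_periodicity(compute_cif(p, L = 400))
#> # A tibble: 1 × 5
#>   period orientation             significant peak_ratio at_range_limit
#>    <dbl> <chr>                   <lgl>            <dbl> <lgl>
#> 1   150. circumferential_stripes TRUE              14.9 FALSE
```

The striped field sits 76 null standard deviations above randomness —
far outside the grey random-value band of roughly ±2 — and the recovered
stripe period matches the generated 150 μm.

```r
# a 21-week-like motility recording and its TTX counterpart
vid <- motility_scenario("distal", duration_s = 600, seed = 3)
stm <- compute_stm(vid)
classify_pattern(detect_contractions(stm), stm)[
  c("label", "ripple_freq", "asymmetry", "n_distal")]
#>                label ripple_freq asymmetry n_distal
#> 1 distal_propagating    2.333333         1        7

ttx <- motility_scenario("distal", ttx = TRUE, duration_s = 600, seed = 4)
compare_conditions(stm, compute_stm(ttx))[
  c("label_from", "label_to", "ripple_freq_change")]
#>           label_from     label_to ripple_freq_change
#> 1 distal_propagating ripples_only           3.422222
```

The baseline recording is classified as exclusively distally propagating;
under TTX the distal pattern disappears and the myogenic ripple frequency
rises by ~3.4 events/min. `autoplot()` methods draw the point patterns,
CIF maps, z-score bands and STMs; `tidy()`/`glance()` return tibbles.

Batch runs go through `run_wholemount_pipeline()` /
`run_motility_pipeline()` (manifest in, tidy results out), or the thin
command-line wrapper in `inst/scripts/enteromap-pipeline.R`.

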