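# microstate

Resting-state EEG microstate analysis and the statistics needed to trust
it. The package segments multichannel EEG into *microstates* — brief
(~80–120 ms) periods during which a single quasi-stable scalp potential
topography dominates — extracts the classical features of the microstate
time series, and quantifies their test–retest reliability, the question
that decides whether those features can serve as within-patient
neurophysiological biomarkers.

It is aimed at EEG researchers who want a scriptable, fully reproducible
alternative to GUI toolchains for microstate work, and at methodologists
who need the reliability layer (Cronbach's α, SEM, smallest detectable
change, TANOVA) alongside the signal chain.

## What it computes

**Segmentation.** The global field power of the average-referenced
topography `v(t)`,

    GFP(t) = sqrt( (1/n) Σᵢ (vᵢ(t) − v̄(t))² ),

is the spatial standard deviation across the `n` electrodes; local GFP
maxima mark the instants of highest topographic signal-to-noise, and the
maps at those peaks (the *original maps*) are the unit of analysis.
Original maps are clustered into K = 4 template maps (classes A–D) with
either of two polarity-invariant algorithms — topographic
atomize-and-agglomerate hierarchical clustering (TAAHC) or modified
k-means with best-of-`r` restarts — under three derivation strategies
(one *global* set of maps, maps *by session*, maps *by recording*).
Cluster quality is the GFP-weighted global explained variance

    GEV = Σⱼ (GFPⱼ · Cⱼ)² / Σⱼ GFPⱼ²,

with `Cⱼ` the absolute spatial correlation between original map `j` and
its template. Back-fitting labels every peak with its best-correlated
template; midpoint boundaries between unlike-labeled peaks turn the
label sequence into segments, from which each class's mean **lifespan**
(ms), **frequency** (appearances/s) and **coverage** (time fraction)
follow.

**Reliability.** Feature tables over repeated sessions feed Cronbach's
α (≡ ICC(3,k)), the standard error of measurement (√MS_error of the
subject × session ANOVA), and the 95% smallest detectable change
`1.96·√2·SEM`. Topographic differences between map sets are tested with
TANOVA: a randomization test on the global map dissimilarity
`GMD = sqrt(2(1 − C))` between GFP-normalized group-average maps.

**Synthetic ground truth.** A generator produces multichannel EEG with
known microstate structure (four canonical-style template maps, Markov
dwell sequence with truncated-Gamma durations, ~10 Hz carrier with
polarity inversions, spatially smooth noise, subject-level dwell-time
effects shared across sessions), so the entire chain is validated by
parameter recovery rather than by eye.

## Worked example

```r
library(microstate)

cfg   <- synth_config(n_subjects = 4, n_sessions = 3, record_length = 60, seed = 1)
study <- generate_study(cfg)

psets <- lapply(study$recordings, function(r)
  find_gfp_peaks(preprocess_recording(r, target_hz = NULL)))
maps  <- derive_maps(psets, strategy = "global", algorithm = "taahc", K = 4)
maps$mapsets$global
#> <mapset> 4 maps [A,B,C,D] x 30 channels (taahc, global), source GEV 1.000

feats <- do.call(rbind, lapply(psets, microstate_features, ms = maps$mapsets$global))
head(feats, 5)
#>   subject session class mean_lifespan frequency coverage   gev
#> 1     S01      T1     A           117      2.13    0.250 0.942
#> 2     S01      T1     B           113      2.45    0.277 0.942
#> 3     S01      T1     C           106      2.15    0.229 0.942
#> 4     S01      T1     D           111      2.20    0.244 0.942
#> 5     S01      T1   All           112      8.93    1.000 0.942

rel <- reliability_report(feats)
rel[rel$feature == "mean_lifespan", c("class","mean","sd","alpha","sem","sdc95")]
#>   class mean    sd alpha  sem sdc95
#> 1     A  107 11.87 0.935 5.40 14.97
#> 2     B  107 10.29 0.963 3.50  9.70
#> 3     C  103  9.51 0.895 5.29 14.66
#> 4     D  105 10.12 0.829 6.89 19.09
#> 5   All  106  9.72 0.978 2.69  7.46
```

Reading the output: each microstate class dwells for ~105 ms on average
and appears ~2.2 times per second, covering a quarter of the recording;
the back-fitted templates explain ~94% of the GFP-weighted topographic
variance. Across the three sessions, mean lifespans have α ≈ 0.83–0.98
(high test–retest reliability, driven by genuine between-subject
variation in dwell time) and an SEM of a few ms; a change larger than
`sdc95` in a repeated measurement of one individual is unlikely to be
measurement noise. `run_study()` executes the full montage × algorithm ×
strategy grid of such analyses in one call, and
`inst/cli/microstate` exposes the same steps as shell subcommands.

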