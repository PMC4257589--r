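---
title: "Microstate analysis and its reliability: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis and its reliability: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the method literature is silent.

## The microstate model

Multichannel resting-state EEG, viewed as a time series of scalp
potential topographies, spends most of its time in a handful of
quasi-stable configurations. The analysis rests on three assumptions:

1. **Topographies at GFP peaks are representative.** The global field
   power — the spatial SD across average-referenced electrodes — waxes
   and wanes with the dominant generator's oscillation; at its local
   maxima the topography has the highest signal-to-noise ratio and is
   approximately constant between surrounding GFP minima. The analysis
   therefore reduces the recording to the maps at strict local GFP
   maxima ("original maps").
2. **Polarity is meaningless at rest.** An oscillating generator flips
   the sign of its scalp map every half-cycle without changing its
   configuration, so all similarity computations use the absolute
   spatial (Pearson) correlation. This single assumption propagates
   everywhere: cluster members must be sign-aligned to their mean before
   averaging (otherwise antipodal members cancel to zero), templates are
   compared by `|corr|`, and TANOVA group averages are polarity-aligned
   to the grand mean.
3. **Four classes suffice.** K = 4 is fixed a priori, matching the
   dominant practice; the cross-validation criterion
   (`cv_criterion()`, residual variance × ((n−1)/(n−1−K))²) is exposed
   as a diagnostic for readers who want a data-driven check, not used to
   select K.

## Signal conditioning

The chain (`preprocess_recording()`) is: 55–65 Hz notch → 1–50 Hz
band-pass (2nd-order Butterworth, forward–backward so the phase is
zero) → 2-s epoching → deterministic amplitude-threshold epoch
rejection (±100 µV default, replacing manual review for
reproducibility) → average re-referencing → optional integer-factor
downsampling behind an anti-alias low-pass → 1–30 Hz band-pass.
Band powers (delta 1–3.5, theta 4–7, alpha 8–12, beta 12–30 Hz; Welch
estimate from Hann-windowed epoch periodograms averaged over channels)
are computed on the 1–50 Hz data, before the final 1–30 Hz filter;
relative power is normalized by total 1–30 Hz power (the analysis
band — the conventional choice when no denominator is stated).
Filters never run across epoch boundaries, and GFP peaks are likewise
found within epochs only: after artifact rejection, adjacent epochs are
not temporally contiguous, and a "peak" straddling a splice would be an
artifact of concatenation. Epoch-edge samples are never peaks, and a
tied plateau emits none (the strict reading of "higher than the
preceding and following point"; exact ties are pathological at
floating-point resolution).

## Clustering

**TAAHC** starts from singleton clusters and repeatedly atomizes the
worst cluster — lowest summed `|corr|` between members and cluster
mean — redistributing its members one at a time, in input order, to the
surviving cluster they correlate with most strongly; the receiving mean
is updated after each arrival. Sequential (rather than simultaneous)
reassignment is a documented choice where the method descriptions are
ambiguous; together with lowest-index tie-breaking it makes the
algorithm fully deterministic for a given input order. First-level maps
are GFP-normalized before being pooled for second-level clustering, so
every recording contributes equally regardless of amplitude.

**Modified k-means** seeds each restart with K randomly chosen
non-identical maps, alternates polarity-invariant assignment with
sign-aligned template re-estimation, and stops when GEV improves by
less than 1e-7 (cap 1000 iterations); the best of `restarts` seeds by
GEV wins. 300 restarts reproduce the reference practice; the desk
profile uses 50, which on the synthetic study changes GEV only in the
7th decimal. An emptied cluster is re-seeded with the worst-fitted map.

**Label matching** solves the K = 4 assignment problem exhaustively
(24 permutations), maximizing total `|corr|` against a reference set.
The global TAAHC map set is the reference for every other run of the
same montage; the global set itself is labeled against built-in
canonical archetype gradients (A: left-posterior→right-anterior, B:
mirrored, C: posterior–anterior, D: fronto-central focal), so "class A"
means the same thing across algorithms and montages.

## Features

Back-fitting assigns each peak to the template with the highest
`|corr|` (ties break in label order A<B<C<D). Segments are runs of
same-labeled consecutive peaks; boundaries sit at the temporal midpoint
between the flanking peaks of unlike label, and the first/last segment
of each epoch is cut at the epoch edge and flagged `truncated`.
Truncated segments **are** included in all three features. Rationale:
with them included, coverage = frequency × mean lifespan holds exactly
per class and coverages sum to exactly 1 per recording, which the test
suite asserts to 1e-9; excluding them would break the identity and bias
frequency. The flag allows a sensitivity re-analysis. No temporal
smoothing or minimum-duration rejection is applied: the "statistical
smoothing" sometimes mentioned alongside back-fitting is never defined
in the method literature, so the default is none (an explicit,
documented absence rather than an invented filter).

## Reliability statistics

Cronbach's α is computed in its raw-score form,
`α = K/(K−1) · (1 − Σσ²ᵢ/σ²_Y)`, and the suite verifies its exact
equivalence to ICC(3,k) from an independent ANOVA decomposition. The
SEM has no universally printed formula; the package uses
`√MS_error` from the two-way subject × measurement ANOVA — the variant
consistent with α-as-ICC(3,k), which removes the systematic session
effect from the error term — and offers `SD·√(1−ICC(3,1))` as a
cross-check (`sem_measurement(..., "icc")`). The smallest detectable
change is `z·√2·SEM`. No multiple-testing correction is applied
anywhere; all p-values are reported raw, as is conventional in this
literature.

TANOVA's p-value counts permuted statistics **at least as large as**
the observed one. The tie-inclusive rule (rather than strictly greater)
is deliberate: it is the exact-test convention that keeps the test
valid, and it is the only reading under which two identical groups
yield p = 1 instead of p = 0. For continuous data the two rules
coincide almost surely.

## The synthetic-data generator

`generate_study()` emulates a 10-subject × 3-session eyes-closed
resting study: 30 channels on a built-in 10–20 coordinate table, 120 s
per recording at 200 Hz. Defaults, with units and reasons:

| parameter | default | why |
|---|---|---|
| mean dwell time | 100 ms | centre of the canonical 80–120 ms range |
| dwell distribution | Gamma(shape 4), truncated at 30 ms | positive, right-skewed, SD ≈ 50 ms matching reported spreads |
| between-subject SD of mean dwell | 10 ms | gives the ~10% between-subject spread that makes lifespan reliability high by design |
| carrier | 10 Hz sinusoid, random phase per segment | alpha-band generator; polarity inverts every half-cycle |
| SNR (signal/noise power) | 2 | clearly noisy yet recoverable; clustering at this level recovers templates at `|corr|` > 0.99 |
| noise | white Gaussian, spatially smoothed (Gaussian kernel, 0.45 head radii) | raw white noise is spatially implausible and makes clustering artificially easy |
| transitions | uniform off-diagonal | no syntax statistics exist to calibrate against; config-exposed |

Subject-level dwell factors are shared across a subject's sessions —
this is the *only* source of between-subject variance, and therefore
the only reason test-retest α can be high. A corollary worth knowing:
coverage has essentially **no** between-subject variance under the
default generator (all classes are equally likely for everyone), so
coverage α on synthetic data hovers near zero. That is correct
behaviour, not a bug; real data gain coverage reliability from stable
individual class preferences the generator deliberately does not
invent. Template maps get a seeded smooth perturbation and a
deterministic decorrelation pass capping pairwise `|corr|` at 0.6,
because the canonical posterior–anterior and fronto-central patterns
overlap beyond 0.7 on the sparse 8-channel montage.

What the generator does **not** emulate: biophysical lead fields, eye
blinks and muscle artifact, 1/f background spectra, non-stationary
alpha power, or subject-specific topographies. Passing recovery tests
therefore shows the algorithms are correct and calibrated, not that
real recordings will reach the same GEV (~0.94 here vs ~0.70 typical of
real data) or reliability.

## Numerical choices and degenerate inputs

- Spatial correlation mean-centers both maps even though
  average-referenced maps are already centered — harmless, and robust
  to non-centered input.
- `gmd()` refuses maps whose GFP differs from 1 by more than 1e-6;
  normalize first.
- α is `NA` with a warning when between-subject variance is zero;
  classes absent from a recording yield `NA` lifespans and are dropped
  listwise per reliability row, with the count reported.
- All stochastic steps (generator, k-means seeding, TANOVA swaps) draw
  from explicit seeded streams that never touch the caller's RNG state;
  `run_study()` fans one master seed out to per-stage seeds by a fixed
  counter scheme, so any stage can be rerun independently and a rerun
  of the same config is byte-identical.
- Problem sizes in the shipped tests and acceptance script: the full
  default study (30 recordings × 120 s), 50 k-means restarts at first
  level, 1000-permutation TANOVA runs, 200-run null calibration. These
  are the package's desk-scale analysis settings; the `"full"` profile
  switches to 300 restarts / 5000 permutations.

## Known limitations

- EDF support is minimal (continuous 16-bit recordings, uniform
  sampling across channels); EDF+ annotations are not parsed.
- The amplitude-threshold artifact rule is a reproducible stand-in for
  expert review, not its equal on real data (no EOG regression, ICA, or
  bad-channel interpolation).
- TAAHC from singletons is O(m²) in the number of original maps;
  beyond a few tens of thousands of peaks per clustering unit it will
  become the bottleneck.
- Reliability machinery assumes complete subject × session designs
  after listwise deletion; unbalanced designs are deleted to balance,
  not modeled.
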