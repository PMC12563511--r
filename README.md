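# msptirr

Multiscale permutation time irreversibility analysis of neurophysiological
time series.

## What this is for

Many physiological signals — MEG and EEG prominently — are outputs of
driven, dissipative, nonlinear systems, and such systems are typically
*time-irreversible*: their statistics differ when read forward versus
backward in time. Stationary linear Gaussian processes, by contrast, are
exactly time-symmetric, so departure from reversibility is a signature of
nonlinear, nonequilibrium dynamics. This package quantifies that departure
with an ordinal-pattern statistic and tracks it across time scales, the
setting in which it has been used to contrast clinical groups (e.g.
schizophrenia patients versus healthy controls) on resting-state MEG.

It is intended for researchers analysing multichannel electrophysiological
recordings who want a reversibility-based index next to the familiar
permutation entropy, together with the surrounding machinery: band
filtering, sensor-region grouping, per-scale group statistics, and a fully
synthetic validation cohort.

## The statistics

For an embedding dimension *m* and delay *τ*, each embedding vector
(x(t), x(t+τ), …, x(t+(m−1)τ)) is encoded by its **amplitude
permutation** (j₁, …, jₘ): jᵢ is the position the i-th element takes in
the stably ascending-sorted vector, with tied elements collapsed to their
tie group's minimum position (so (5, 5, 3) ↦ (2, 2, 1)). Writing p(π) for
the empirical probability of forward pattern π and π̄ for its tuple
reversal (the pattern of the time-reversed vector):

- **Permutation entropy** PE = −Σ p(π) log p(π), summed over the U
  observed forward patterns (natural log; 0 ≤ PE ≤ log m!).
- **Permutation time irreversibility**
  PTIRR = Σ p(π) · |p(π) − p(π̄)| / (p(π) + p(π̄)), summed over the V
  patterns observed forward or as reversals of observed patterns.
  Algebraically this equals Σ over unordered {π, π̄} pairs of
  |p(π) − p(π̄)|, so PTIRR ∈ [0, 1]: 0 for pattern-symmetric series
  (linear Gaussian processes, in expectation), 1 for a strict ramp.

The **multiscale** versions (MsPE, MsPTIRR) evaluate these indices on
coarse-grained copies of the series, x_s(N) = mean of the s-sample window,
for scale factors s = 1…100. Defaults m = 3, τ = 2 follow the modal choice
of false-nearest-neighbor and C-C selection on resting MEG; both selectors
are included (`fnn_dimension()`, `cc_delay()`, `aggregate_by_mode()`).

## Worked example

```r
library(msptirr)

# a reversible reference (Gaussian AR) and an irreversible burst train
noise <- gen_gaussian_ar(20000, 0.5, seed = 1)
burst <- gen_burst_train(20000, seed = 1)

for (x in list(noise = noise, burst = burst)) {
  d <- pattern_distribution(x, m = 3, tau = 2)
  cat(sprintf("PE = %.4f  PTIRR = %.4f\n",
              permutation_entropy(d),
              permutation_time_irreversibility(d)))
}
#> PE = 1.7878  PTIRR = 0.0154
#> PE = 0.5568  PTIRR = 0.9669

ms_profile(burst, scales = c(1, 5, 10, 20), kind = "PTIRR")
#>   scale     value
#> 1     1 0.9668934
#> 2     5 0.6764264
#> 3    10 0.4659319
#> 4    20 0.2610442
```

The Gaussian AR series sits at the reversible baseline: PE within 0.004 of
the m = 3 maximum log 6 ≈ 1.7918, PTIRR near 0. The burst train — sharp
onsets with slow multi-timescale decay — is almost maximally irreversible
at scale 1, and remains far above the null band as coarse-graining
averages it out.

A full cohort analysis is three calls:

```r
cfg <- run_config(out_dir = "run1", scales = 1:20, seed = 7, kinds = "PTIRR",
                  cohort = list(n_per_group = c(HC = 10, SZ = 10),
                                n_channels = 20, n_samples = 12000,
                                sample_rate_hz = 300))
man <- cmd_simulate(cfg)          # recordings + manifest on disk
cfg$manifest <- attr(man, "manifest_path")
cmd_compute(cfg)                  # per-subject MsPTIRR profiles
res <- cmd_compare(cfg)           # per-scale t tests, whole head + regions
res$intervals                     # significant scale intervals per stratum
```

`cmd_compare()` writes tidy `stats.tsv` (per-scale t statistics, p values,
log-base-0.05-transformed p values, group means ± SEM) and
`intervals.tsv` (maximal runs of consecutive significant scales per
stratum).

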