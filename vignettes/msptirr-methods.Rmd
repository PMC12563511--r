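---
title: "Multiscale permutation time irreversibility: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale permutation time irreversibility: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msptirr)
```

This vignette is the package's own account of the methods it implements:
the ordinal statistics and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
design choices made where the methodology left room.

## 1. The model: ordinal patterns and time reversal

A stationary process is *time-reversible* when every finite-dimensional
distribution is invariant under reversing the time axis. Stationary linear
Gaussian processes are reversible; nonlinear or non-Gaussian dynamics
generally are not, and in neurophysiology irreversibility is read as a
signature of directed, nonequilibrium information flow. The package
measures it through ordinal patterns, which are cheap, rank-based, and
immune to monotone distortions of the measurement scale.

### Amplitude permutation and the tie rule

Given dimension $m \ge 2$ and delay $\tau \ge 1$, each embedding vector
$(x(t), x(t+\tau), \dots, x(t+(m-1)\tau))$ is encoded by the tuple
$(j_1, \dots, j_m)$, where $j_i$ is the position of the $i$-th element in
the stably ascending-sorted vector and every member of a tie group
receives the group's minimum position. For exact ties this is precisely
`rank(x, ties.method = "min")`, computed vectorised as
$j_i = 1 + \#\{k : x_k < x_i\}$. Two consequences matter:

- **Reversal theorem.** Because the rank of an element depends only on the
  multiset of values, the permutation of the reversed vector is exactly
  the tuple reversal of the forward permutation — including all tie
  configurations. The backward pattern is therefore *derived* from the
  forward one rather than estimated by a second backward scan; the two
  differ only through $O(1/n)$ boundary vectors. The test suite checks
  the theorem exhaustively over all $4^m$ value tuples for $m \le 4$.
- **Tie handling.** Ties are first-class patterns (a constant vector maps
  to $(1,1,\dots,1)$), not jittered away. The default tie tolerance is 0
  (exact floating-point equality); a positive `tie_tol` treats values
  within the tolerance as tied, decided *pairwise*, which is useful for
  coarsely quantized data but non-transitive on chains — documented, and
  off by default.

### The indices

With $p(\pi)$ the empirical forward probability of pattern $\pi$ and
$\bar\pi$ its reversal,

$$\mathrm{PE} = -\sum_{U} p(\pi)\log p(\pi), \qquad
\mathrm{PTIRR} = \sum_{V} p(\pi)\,
\frac{|p(\pi) - p(\bar\pi)|}{p(\pi) + p(\bar\pi)},$$

where $U$ counts the observed forward patterns and $V$ the patterns that
occur forward *or* as reversals of observed ones. Patterns in $V$ with
zero forward probability contribute zero terms but are retained in the
count. $0\log 0 := 0$. The PTIRR sum collapses algebraically to
$\sum_{\{\pi,\bar\pi\}} |p(\pi) - p(\bar\pi)|$ over unordered pairs
(self-reverse patterns drop out), which bounds it in $[0,1]$ and is the
identity the tests verify to $10^{-12}$ on random distributions.

Two rendering choices were genuinely open and are resolved as follows.
The logarithm in PE carries no base in common usage; the package uses the
natural log (maximum $\log m!$), with `base` and `normalized` options.
The middle factor of the PTIRR sum is implemented with absolute-value
bars: without them the index could be negative, contradicting its role as
a nonnegative divergence, and the pairwise identity above would fail.

### Multiscale extension

Scale $s$ replaces the series by non-overlapping window means
$x_s(N) = \tfrac1s \sum_{n=s(N-1)+1}^{Ns} x(n)$, discarding the trailing
remainder; scale 1 is the identity. The embedding delay acts on the
coarse-grained series as is — the delay is *not* rescaled with $s$, which
is the natural reading of applying the same estimator to each $x_s$ and
keeps scale 1 exactly equal to the single-scale index. An MsPE/MsPTIRR
profile is the index as a function of $s$; the analysis default is
$s = 1\ldots100$, and a profile is only defined where the coarse series
still admits an embedding vector
($\lfloor l/s \rfloor \ge (m-1)\tau + 1$), with errors naming the largest
feasible scale.

Note one subtlety the tests pin down: ordinal indices are invariant under
*any* strictly increasing transform at scale 1, but only *affine* maps
commute with the window averaging of coarser scales.

## 2. Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `m` | 3 | embedding dimension; modal FNN choice across MEG channels, and small enough that $m! = 6$ patterns are well estimated on desk-scale series |
| `tau` | 2 | embedding delay (samples on the coarse series); modal C-C choice |
| `scales` | 1–100 | coarse-graining factors, step 1 |
| `tie_tol` | 0 | tie tolerance; positive values only for quantized data |
| `alpha` | 0.05 | significance level throughout |
| bands | δ 1–4, θ 5–8, α 9–12, β 13–29, γ 30–65 Hz | standard decomposition table (`meg_bands()`) |

Subject-level indices are unweighted arithmetic means of per-channel
profiles (`subject_profile()`); group curves are means of subject means
with the standard error across subjects.

## 3. Embedding-parameter selection

The selectors are advisory — the pipeline default stays $m=3$, $\tau=2$
without running them — but both are implemented in full.

**False nearest neighbors** (`fnn_dimension()`): for each $m$, each
embedded point's nearest Euclidean neighbor is flagged false when the
added $(m{+}1)$-th coordinate separates the pair, either relatively
(ratio > `r_tol` = 10) or absolutely (expanded distance > `a_tol` = 2
standard deviations); the chosen dimension is the smallest with a false
fraction below 1%. These thresholds are the standard defaults of the
method. Two numerical guards: the neighbor search is capped at 2000
points (even subsampling) to bound its quadratic cost, and the ratio
criterion carries a floor of $10^{-8}\sigma$ because exact state revisits
(periodic signals) produce distances at rounding-noise level whose ratio
is meaningless. Deterministic low-dimensional signals behave as expected:
a scalar map like the logistic map already has no false neighbors at
$m = 1$; a sinusoid needs the plane.

**C-C delay selection** (`cc_delay()`): the correlation-integral
statistic $S(m, r, t)$ is averaged over $m \in \{2,\dots,5\}$ and radii
$\{0.5, 1, 1.5, 2\}\sigma$ across $t$ disjoint strided sub-series, and
the chosen delay is the first local minimum of the radius-spread curve
$\Delta\bar S(t)$; if none occurs within `max_tau`, `max_tau` is returned
with `converged = FALSE`. One empirical caveat found during development
and reflected in the tests: the folk expectation that a pure sinusoid
yields $t \approx T/4$ does **not** hold for this canonical statistic —
the first local minimum settles near $t = 3$–4 across periods and lengths,
while a slow AR(1) process is selected near its correlation time. The
tests therefore assert the defensible property (the chosen delay reduces
the dependence spread relative to $t=1$) rather than the folklore value.

Per-channel choices are aggregated by their mode
(`aggregate_by_mode()`), ties broken toward the smaller — more
conservative — value.

A practical note baked into the test signals: sinusoids with a period
that is rational in samples revisit states *exactly*, degenerating both
selectors; test signals use irrational periods such as $13\pi$ samples.

## 4. Preprocessing

All filters are zero-phase by construction: they apply a real, even gain
in the frequency domain (with 2 s reflection padding against edge
artifacts) equal to the squared magnitude of the corresponding analog
design — a 4th-order Butterworth for low-/band-pass, a 2nd-order notch
(width 2 Hz) for the 50 Hz line. This matches what forward–backward
recursive filtering computes, but avoids the coefficient ill-conditioning
of transfer-function recursions at very narrow normalized bands (a 1–4 Hz
pass band at 1200 Hz sampling is unusable in `filtfilt` form). Zero phase
is not cosmetic here: a phase-distorting filter injects spurious temporal
asymmetry into exactly the statistic this package estimates, and the
tests verify that a filtered Gaussian AR signal stays inside the
irreversibility null band.

Sensor grouping parses CTF-convention labels (`MLC11`: hemisphere from
the 2nd character, region from the 3rd) into a hemisphere × {central,
frontal, occipital, parietal, temporal} partition. Midline (`Z`)
channels are included in whole-head analyses but excluded from
hemispheric contrasts, whose scheme is strictly left/right; unparsable
labels are reported, never dropped silently.

## 5. Group statistics

Per scale, the two groups' subject-level indices are compared with a
two-tailed independent-samples t test; an F test decides between the
pooled-variance and Welch forms at each scale (Welch on failure — the
assumption checks otherwise carry no consequence). Kolmogorov–Smirnov
normality checks are available (`assumption_checks()`). p values are
reported raw *and* on the log-base-0.05 scale
($\log p / \log 0.05$; values above 1 mean $p < 0.05$), and per-scale
results are summarised as maximal runs of consecutive significant scales
(`significance_intervals()`). No multiple-testing correction is applied
across scales by default, matching per-scale reporting practice in this
literature; Benjamini–Hochberg is available via `p_adjust = "BH"`.

Band and region contrasts at a single fixed scale use a standard two-way
fixed-effects ANOVA, `value ~ group * factor` with interaction
(`two_factor_anova()`). The factor layout (group × region, group × band,
one scale at a time) is one reasonable reading of a two-factor design for
this data shape; the choice is deliberate and documented rather than
forced. Exactly constant designs return zero F statistics rather than
0/0.

## 6. The synthetic cohort: what it emulates, and what it does not

`gen_cohort()` exists so that every pipeline stage is testable without
any recording on disk. Its defaults state the emulated study geometry —
15 + 19 subjects, 275 CTF-labelled channels, two minutes at 1200 Hz,
irreversibility mixes 0.3 (control-like) vs 0.1 (patient-like) — and
examples scale the free geometry (channels, duration, rate) down
explicitly; the desk-scale conditions used throughout the tests are
10 + 10 subjects, 20 channels, 40 s at 300 Hz, scales 1–20.

Each channel is built as
$\sqrt{1-\lambda}\,\mathrm{bg} + \sqrt{\lambda}\,\mathrm{irr}$, where
$\lambda$ is the group's irreversibility mix — a *variance fraction* —
and:

- **bg** is a weighted sum of band-limited Gaussian noise (default
  powers δ 1, θ 0.7, α 1.5, β 0.6, γ 0.3 — alpha-dominant resting
  spectrum) plus $1/f$ noise, standardized. As a Gaussian process it is
  time-reversible by construction, whatever its spectrum.
- **irr** is a burst train (`gen_burst_train()`): Poisson events
  (rate 1/30 per sample) with exponential amplitudes, convolved with a
  kernel that rises instantaneously and decays as a sum of exponentials
  (time constants 3, 12, 48 samples). Every burst is a sharp onset with
  a multi-timescale relaxation, so ordinal asymmetry is strong at sample
  resolution *and* survives coarse-graining across the analyzed range.

The burst-train choice is deliberate and empirical. Ordinal
irreversibility is fragile under additive symmetric noise: mixing a
logistic-map orbit (or an amplitude-modulated envelope of one) into a
Gaussian background at these mix weights dilutes its asymmetry below
detectability, and summing independent irreversible layers at different
timescales mutually dilutes them as well. A single event train driving a
multi-timescale asymmetric kernel keeps the asymmetry coherent across
scales and is, at the same time, a physiologically evocative caricature
of avalanche-like neural population events. The logistic map remains the
package's single-series positive control
(`gen_logistic_map()` versus `phase_randomized_surrogate()`).

What the generator does *not* emulate: measurement artifacts (ECG/EOG),
head movement, source-space mixing between sensors (channels are
independent), spatial correlation structure, or between-subject
heterogeneity beyond sampling noise (groups differ only through the mix).
Passing cohort tests therefore demonstrate that the pipeline recovers a
known irreversibility contrast from realistic amplitudes and spectra —
not that any particular clinical effect size is reproduced. The clinical
headline numbers of the motivating setting were computed on recordings
that are not publicly deposited and are out of reach by design.

## 7. Numerical choices and degenerate inputs

- Coarse-graining discards the trailing partial window.
- Pattern tabulation is vectorised over all embedding vectors via the
  strictly-smaller-count formulation of minimum ranks, with patterns
  base-$m$ encoded; $m \le 8$ keeps the code table within memory.
- PTIRR's denominator never vanishes inside $V$ by construction of $V$.
- Series too short for one embedding vector raise an error naming the
  required minimum length; infeasible scales name the largest feasible
  one; degenerate (constant) series are rejected by the selectors that
  cannot define neighbors on them, and map to the all-ties pattern
  (PE = 0, PTIRR = 0) in the ordinal indices.
- All generators are bit-reproducible given a seed, and the pipeline
  (`cmd_simulate` → `cmd_compute` → `cmd_compare`) writes numerics with
  10 significant digits so reruns are byte-identical.
- The desk-scale problem sizes used by tests and the acceptance script
  (series of $10^5$ for calibration; cohorts of 10 + 10 × 20 channels ×
  12000 samples; 1000-replicate t-test calibration) were chosen once as
  the smallest sizes at which the statistical checks are comfortably
  stable, and are stated here as the package's own study conditions.

## 8. Known limitations

- PTIRR estimated from finite series is nonnegative by construction and
  therefore biased upward under the null, increasingly so at coarse
  scales where the coarse series is short. Group comparisons share this
  bias across groups; absolute values near the null band should be read
  against surrogate or Gaussian references, not against zero.
- The backward-pattern probabilities are derived from the forward pass;
  on very short series the $O(1/n)$ boundary discrepancy with a literal
  backward scan is visible only below lengths where the estimator is
  unreliable anyway.
- The C-C selector's behavior on noiseless periodic signals departs from
  folklore (see Section 3); on stochastic signals it behaves
  conventionally.
- `two_factor_anova()` assumes a balanced-enough fixed-effects layout;
  heavily unbalanced designs are the user's responsibility.
- No HDF5 container: recordings travel as delimited text with a declared
  sampling rate.
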