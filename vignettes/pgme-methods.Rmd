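---
title: "Phase-dependent generalized multiscale entropy of walking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-dependent generalized multiscale entropy of walking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgme)
```

## The problem

Falls in community-dwelling older adults correlate with subtle changes in
the regularity of everyday walking. Tri-axial accelerometers worn on the
lower back record the trunk's anterioposterior (AP), mediolateral (ML) and
vertical (V) acceleration at 100 Hz for days at a time. Conventional
entropy measures summarize the irregularity of such recordings with a
single number per signal, which hides two things: *where in the step cycle*
the irregularity lives (heel strike, push-off and swing are dynamically
different regimes), and *how strongly* rare versus common patterns should
count. This package computes a phase-dependent generalized multiscale
entropy (PGME): one irregularity estimate per temporal scale, per
step-cycle phase, per Tsallis q-order, and feeds it into a fall-prediction
pipeline.

## The measure

**State-space reconstruction.** The three acceleration channels of a 30-s
epoch (3,000 samples at 100 Hz) are delay-embedded into two nested state
spaces,

\[ X_j = (a^{AP}_j, a^{ML}_j, a^{V}_j,
         a^{AP}_{j+l}, a^{ML}_{j+l}, a^{V}_{j+l}), \qquad
   Y_j = (X_j,\; a^{AP}_{j+2l}, a^{ML}_{j+2l}, a^{V}_{j+2l}), \]

so every 9-dimensional point extends a 6-dimensional one. The lag `l` is
chosen per epoch as the first lag at which the average mutual information
(AMI, averaged over the three axes) stops decreasing by more than 0.01 nats
per sample. Both spaces are built over the shared index range
`j = 1..N-2l`; this makes the match-count inequality below structural
rather than statistical.

**Multiscale decomposition.** The embedded dynamics are decomposed by
multivariate empirical mode decomposition (MEMD) into intrinsic mode
functions (IMFs) ordered high to low frequency. The scale-k coarse-grained
dynamics are

\[ \bar d_k(t) = \sum_{k'=k}^{M} d_{k'}(t) + \text{residual}, \]

equivalently the signal minus its first `k-1` IMFs — scale 1 is the
original dynamics and higher scales progressively low-pass-filtered
versions whose cutoff adapts to the signal itself. Scales 1–6 are used:
they retain the intra-step detail above the ~2 Hz step rhythm.

**Generalized sample entropy.** Within an index set \(I\) (all admissible
points, or a phase window), let \(n_x\) be the fraction of ordered pairs
\(i \ne j\) whose 6-dimensional points lie within max-norm distance
\(r\), and \(n_y\) the same fraction for the 9-dimensional points, with a
shared denominator. The q-order sample entropy is

\[ \mathrm{qSaEn}_q = \ln_q n_x - \ln_q n_y, \qquad
   \ln_q n = \frac{n^{1-q} - 1}{1-q}, \]

with \(\ln_1 n = \ln n\) recovering the conventional sample entropy
\(\ln(n_x/n_y)\). The tolerance is `r = 0.3` times the mean of the three
raw-channel SDs, computed once per epoch and held fixed across scales,
phases and q. The q grid is 21 evenly spaced values on \([-1, 1]\):
negative q amplifies high match probabilities (regular passages), positive
q penalizes low ones (irregular passages).

**Phase conditioning.** Step cycles are the intervals between consecutive
local minima of the vertical trunk velocity (estimated by trapezoid
integration of the demeaned acceleration, MEMD-detrended with a 0.5 Hz
zero-crossing cutoff). For each valid cycle of duration `T` samples and
each phase `p ∈ {0, 20, 40, 60, 80}` percent, the window covers
`floor(0.10 T)` samples starting `round(pT/100)` after the cycle start;
windows pool across cycles. The result per epoch is a 6 × 5 × 21 tensor;
per subject, the elementwise median across epochs.

## Key structural facts the tests lean on

* **Nested match counts.** Because the 9-dimensional points extend the
  6-dimensional ones coordinate-wise and the max-norm is used,
  \(n_y \le n_x\) for every index set, hence \(\mathrm{qSaEn} \ge 0\)
  whenever defined (\(\ln_q\) is increasing in its argument for every q).
  A Euclidean metric would not give this guarantee.
* **q-monotonicity.** \(\ln_q n\) is non-increasing in q for every fixed
  n > 0. A property sometimes stated in the opposite direction for
  n < 1 — that is incorrect, and the test suite asserts the true one.
* **Counts-once evaluation.** \(n_x, n_y\) do not depend on q, so the
  entire q grid is evaluated from one counting pass; the tests verify this
  equals per-q recomputation exactly.
* **Telescoping coarse grain.** \(\bar d_k\) equals the signal minus IMFs
  1..k-1, so the entropy pipeline may stop the decomposition after
  `max(scales) - 1` IMFs without changing any value.

## Numerical and design choices

* **MEMD sifting** projects onto 64 Hammersley-distributed unit directions
  (inverse-normal map of a low-discrepancy cube sequence), passes natural
  cubic splines through the signal at projected-extrema times with mirror
  extension of two extrema per end, and subtracts the mean envelope until
  the envelope-to-candidate norm ratio falls below 0.075 on two consecutive
  sifts (cap 15). Extraction stops when fewer than three extrema survive in
  every projection or the remainder is numerically exhausted. All constants
  are exposed in the API.
* **Undefined cells.** If a phase window yields \(n_y = 0\) the cell is
  missing (`NA`), not infinite; subject-level medians skip missing cells
  and mark a cell missing when more than half the epochs are missing
  there. Scales beyond the number of extractable IMFs are missing, never
  padded.
* **Lag selection** uses 32 equal-width histogram bins (range-anchored, so
  AMI is invariant to affine rescaling of the signal) and averages the
  axis-wise curves before applying the flattening rule; one lag per epoch,
  reused at all scales. An upturn of the curve counts as flattening; a
  strictly decreasing curve falls back to its last lag.
* **Step-cycle conventions.** Minima of the vertical velocity are the
  default cycle boundary (`extremum = "maxima"` is available; the
  literature uses both conventions). Minima need 0.3 s separation and
  prominence of 0.1 channel-SD; cycles outside 0.3–1.0 s are flagged
  invalid and contribute no phase-window indices. The peak finder is
  plateau-aware (flat-topped extrema are represented by their central
  sample), which matters for noise-free test signals.
* **Walking screen.** The published inclusion screen is visual; the
  package substitutes a spectral proxy: an epoch is accepted when, on at
  least 80% of sliding 3-s subwindows, the V or AP channel has its
  dominant spectral peak inside 1.2–3.5 Hz with at least 4× median-power
  prominence and an impact-peak count within 30% of the
  dominant-frequency-predicted step count. All thresholds are in
  `screen_config()` and the screen can be disabled.
* **PLS pipeline.** NIPALS PLS1 (tolerance 1e-10, cap 500 inner
  iterations) with LDA on the latent scores; the component count (max 10)
  minimizes internal 10-fold CV error under the one-standard-error
  parsimony rule. Backward elimination removes, per round, the feature
  whose exclusion yields the lowest internal CV error and returns the
  visited subset with the global minimum. Holdouts move whole matched
  pairs (80/20), so test sets are always label-balanced. AICc uses a
  binomial likelihood on held-out LDA posteriors with
  `k = components + 1` — a modeling interpretation, since no likelihood is
  canonical for a discriminant classifier; it is reported as such.
  Bootstrap CIs are percentile, 1,000 resamples of the repetition-level
  metrics.

## The synthetic generator

`simulate_epoch()` emulates the signal class the method targets: stride
intervals jittered around a 2 Hz step rhythm (3% CV), a six-harmonic
Fourier waveform per axis phase-locked to the (two-step) stride, a damped
12 Hz oscillation at each cycle start standing in for the heel-strike
impact, and additive Gaussian noise whose SD may vary across five
step-cycle phase bins. The vertical harmonic phases are zero so that the
integrated vertical velocity has an exact minimum at every cycle start —
generated and detected phases then coincide, which is what makes
phase-localized effects attributable. `simulate_cohort()` draws matched
pairs sharing demographic values, with per-subject random effects on step
frequency and noise level; the faller effect multiplies the noise SD in
one phase bin (default 0.5 at 60%).

What the generator does *not* emulate: real heel-strike asymmetries,
turning and transitional bouts, sensor tilt and drift, and
inter-individual waveform differences beyond amplitude/rate effects.
Passing tests therefore demonstrate the estimator's internal correctness
and its sensitivity to phase-localized irregularity changes under
controlled conditions — not clinical validity on field recordings.

A regime caveat worth knowing: within phase windows, stride jitter
misaligns steep waveform segments across cycles, so match probabilities
are far below 1. In this regime, *reducing* noise in one phase raises
\(n_x - n_y\) and hence the q < 1 entropies there, while the q = 1
(ratio-based) entropy falls — so the sign of a group difference at q < 1
depends on the match-probability regime, and the suite asserts the
empirically verified directions. The group contrast itself (which cells
differ, under Benjamini-Hochberg control) is regime-independent and is
what the acceptance checks require.

## Problem sizes used by the test suite

The full study conditions (30-s epochs, 64 directions, 500 holdouts,
hundreds of epochs per subject) are the package defaults. The automated
checks run the same code at reduced sizes chosen as the package's own
validation protocol: 8–10 s epochs, 8–16 MEMD directions, sift cap 8,
scales 1–3 with q ∈ {−1, 0, 1} for the cohort replicates (20 matched
pairs, 5 epochs per subject, 20 replicates per arm), and 50 holdout
repetitions for the prediction sanity checks. For those short epochs the
AMI histogram uses 16 bins per margin rather than the 30-s default of 32:
with 800 samples spread over a 32 × 32 joint histogram the MI decrements
sit at the resolution floor and the selected lag becomes sensitive to
incidental signal properties, which smears any phase-localized effect into
a weak global one. The MEMD ordering check runs
at the six-scale depth the entropy uses: beyond it, slow modes carry too
few zero crossings for a stable frequency estimate and envelope-based
sifters are known to split them.

## Known limitations

* Cycle detection assumes a dominant step-periodic vertical component;
  pathological or very slow gait may need the maxima convention or
  adjusted prominence.
* The entropy's phase attribution blurs over roughly `2l` samples (the
  embedding span): an effect localized in one generator bin also moves
  windows one to two bins earlier, as both the simulations and the
  original phase-resolved findings show for adjacent phases.
* AICc values across feature subsets compare models through an assumed
  binomial posterior likelihood; treat them as relative, not absolute.
* MEMD mode ordering is reliable over the scales used (1–6); deeper modes
  are length-limited, as discussed above.
```
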