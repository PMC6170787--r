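---
title: "End-matched segmentation and the surrogate-data nonlinearity test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-matched segmentation and the surrogate-data nonlinearity test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and the hypothesis test

A segment `x` of a sampled signal is tested against the null hypothesis that
it was generated by a linear Gaussian process (possibly observed through a
static transformation). The null ensemble consists of Fourier
phase-randomized surrogates: the discrete Fourier transform of each channel
is computed, the phase of every positive-frequency bin is rotated by an
independent uniform angle on (0, 2π), conjugate symmetry is enforced on the
negative frequencies, and the inverse transform is taken. DC and Nyquist
bins are not rotated (they must remain real). Each surrogate therefore has
exactly the original's amplitude spectrum, periodogram, mean and variance;
only the phase structure, where any nonlinearity lives, is destroyed. In the
multivariate variant one rotation sequence is shared by all channels, which
preserves every cross-spectral phase difference and hence the full linear
cross-correlation structure between channels.

A nonlinear statistic `Q` is computed on the original and on each of `n = 20`
surrogates and compared by

`Z = (Q_data − mean(Q_surr)) / sd(Q_surr)`,

with the sample (n−1) standard deviation, rejecting at `|Z| > 1.96`. With 20
surrogates the null distribution of `Z` is slightly heavier-tailed than
normal (it is `t`-like because the denominator is estimated); the package
keeps the conventional 1.96 threshold for fidelity to standard practice and
documents the true operating level instead of adjusting it: on an exact
exchangeable null the empirical rejection rate is ≈ 6–7%, and the
calibration test asserts the band [3%, 9%]. The degree of nonlinearity
`DEG = 100 · n_sign / n` summarizes many segments. Segments with degenerate
surrogate spread (sd = 0) or undefined statistics are excluded from both
numerator and denominator and counted separately.

## Why segment length matters

The DFT treats the analyzed window as one period of an infinite periodic
signal. A strong cyclic component of period `T` that does not fit the window
an integer number of times produces a phase discontinuity at the wrap-around
point, spreading (leaking) its power across the spectrum. The original
segment and its surrogates share this leaked spectrum, but they distribute
it differently in time: in the original the effect is a localized edge
artifact, while phase randomization converts the leaked power into
stationary broadband jitter over the whole window. Statistics sensitive to
fine-scale structure therefore shift between original and surrogates, and
the linearity null is rejected without any nonlinearity being present. The
mismatch — and thus the false-rejection rate — is periodic in the segment
length: maximal when the window contains an odd number of half-periods,
zero again at full periods. End-matching (cutting from cycle peak to cycle
peak, so the window spans exactly `k` realized periods) removes the
discontinuity.

The package realizes end-matching empirically: cycle peaks are local maxima
of the zero-phase band-filtered signal, the segment starts at a peak, and
ends *one sample before* the peak closest to the target length, so the
window length is exactly `k` realized periods and its implicit periodic
continuation is seamless. (Including both boundary peaks would add one
duplicated sample — a small but systematic end-mismatch of one sample per
window, which is precisely what the method is supposed to eliminate.) The
realized period is taken from the data as span/k rather than from a nominal
frequency, which keeps the construction correct when the dominant frequency
varies between subjects.

## The five discriminating statistics

* **Higuchi fractal dimension** (`k_max = 8`): normalized curve lengths
  `L(k)` over delays `k`, OLS slope of `ln L(k)` vs `ln k`. Exactly 1 for a
  line, ≈ 2 for white noise. Most sensitive to fine-scale (high-frequency)
  structure.
* **Katz fractal dimension**: planar-curve definition with unit abscissa
  steps, `KFD = log10(n) / (log10(n) + log10(d/L))`. This is the only
  convention consistent with its two analytic anchors (any monotone line
  gives exactly 1; the unit square wave 0,1,0,1,0 gives 4/3). Note it is
  *not* exactly invariant to amplitude scaling — the unit abscissa fixes a
  scale — so inputs should be compared on a common scale; shifts are
  irrelevant. A constant series is a horizontal line and returns 1.
* **Lempel–Ziv complexity**: median binarization (ties to 0), then the
  Kaspar–Schuster sequential form of the exhaustive-history phrase count.
  A constant sequence parses into 2 phrases, the alternating sequence into
  3. Both the raw count and the `c·log2(n)/n` normalization are returned;
  within fixed-length comparisons they are monotone in each other, so the
  Z statistic is unaffected by the choice.
* **Sample entropy** (`m = 2`, `r = 0.2·SD`): Chebyshev template matching
  without self-matches; affine invariant because `r` tracks the sample SD.
  Undefined (flagged, not 0) when no template pair matches at length `m+1`.
* **Synchronization likelihood**: both series are delay-embedded; for each
  reference time the per-series critical distance is the empirical `p_ref`
  quantile of distances to times `j` with `w1 < |i−j| < w2`, and SL is the
  fraction of x-recurrences that are simultaneously y-recurrences, averaged
  over reference times. Identical inputs give exactly 1, independent inputs
  ≈ `p_ref`. Several normalization variants exist in the literature; these
  two anchors are the contracts the implementation is tested against. The
  historical EEG parameterization (lag 7, dimension 136, `p_ref` 0.01,
  windows 2000/2999 at 1000 Hz) is available, but cohort experiments default
  to a light embedding (lag 2, dimension 5) because the Z-test contract is
  parameter-agnostic and the heavy embedding is O(n·w2·m) per segment pair.

## The synthetic world

Real resting EEG for a cohort of this kind is not distributable, so the
package generates its own: per channel, a deterministic sinusoid at the
"alpha" frequency (drawn per subject from 9–11 Hz) with uniform random
phase, contributing a stated fraction `alpha_rel_power` of the variance,
plus `1/f^β` Gaussian noise generated by spectral shaping of white noise
(exact slope, no filter transients, stationary by construction), optionally
mixed across channels by a fixed matrix. With `nonlinearity = "none"` the
output is a linear transform of Gaussian noise plus a harmonic process, so
the surrogate null holds by construction. Positive controls mix in either a
standardized chaotic Hénon x-series (a = 1.4, b = 0.3, transients discarded)
or a quadratically phase-coupled sinusoid triplet at a stated variance
fraction.

Deliberate choices, made once:

* **Sinusoid, not a narrowband AR resonance**, for the cyclic component: it
  has an exact, controllable period, which is what the `l = kT + Δt`
  experiments manipulate.
* **β = 1** background by default ("1/f noise"); the channel-power defaults
  for the channel-dependence experiment are 0.6/0.3/0.1, mimicking the
  occipital > central > temporal alpha-power ordering.
* **200 Hz cohort sampling rate** (vs the 1000 Hz acquisition rate the
  pipeline was designed around): the phenomenon depends on cycles per
  window, not on the sampling rate (verified at both rates), and the O(n²)
  measures make 1000 Hz cohorts an order of magnitude slower. `Δt` grids in
  ms are converted to samples by rounding; at 200 Hz the {0, 25, 50, 75,
  100} ms grid is exact.
* **Hénon positive-control strength 0.5**: the nonlinear component carries
  the same variance as everything else together — a clear, not marginal,
  alternative hypothesis.
* **Non-overlapping consecutive segments** (each starts at the end peak of
  its predecessor); overlap policy for incremented windows follows the
  design of the original experiment: same start, longer end.

What a green test does *not* establish: the generator has no artifacts, no
nonstationarity, no volume-conduction structure, and its background is
exactly Gaussian; calibration results here do not certify behavior on real
EEG with those features.

## A known, documented red result

The scaled replication of the main experiment asserts that both the Higuchi
dimension and sample entropy show the end-mismatch effect. In this
package's stated world (alpha fraction 0.5 over β = 1 noise) only HFD does:
group-mean DEG rises from ~8% end-matched to ~98% at the half-period
mismatch and falls back at the full period, while SampEn stays flat (~8%)
at every Δt — verified at both 200 Hz and 1000 Hz. The mechanism: at
Δt = T/2 the leaked sinusoid power is ≈ 1% of total variance spread across
the band; against a β = 1 background, whose own high-frequency floor is
comparatively high, the surrogates' added fine-scale jitter changes
Chebyshev template-match counts (r = 0.2·SD) negligibly, whereas HFD
integrates exactly that jitter across scales. With a steeper, more
EEG-like background (β ≥ 1.5) SampEn shows the effect strongly (DEG
21% → 92% at β = 1.5), consistent with the effect having been observed on
real eyes-closed EEG, whose spectrum falls much faster than 1/f above the
alpha peak. The generator default was fixed before any experiment was run
and is not tuned retroactively; the SampEn clause is left failing with this
analysis rather than quietly weakened.

## Numerical choices and degenerate inputs

* Butterworth band-pass filters are designed analytically (prototype →
  band transform → bilinear) and applied forward–backward as a cascade of
  second-order sections with steady-state initial conditions and
  odd-reflection padding; the polynomial form is numerically singular for
  the very narrow delta band (1–1.5 Hz), the section cascade is not.
  Validated against an independent reference implementation to ~1e-13.
* Order 4 per pass (8 effective). The source experiments do not state an
  order; 4 is common EEG practice and stable at these band edges.
* Peak de-duplication: maxima closer than half the band's shortest period
  are merged (larger kept), suppressing ripple-induced double peaks.
* KPSS (level variant — filtered signals are zero-mean) and Phillips–Perron
  tests are implemented in-package with Bartlett/Newey–West long-run
  variances, default lag `trunc(4·(n/100)^0.25)`, and asymptotic critical
  values; the screen passes when KPSS fails to reject stationarity *and*
  PP rejects its unit root. P-values are interpolated and clipped to the
  tabulated range.
* The z-test excludes (never zero-fills) segments with degenerate surrogate
  spread or undefined statistics; `DEG` denominators shrink accordingly.
* Master-seed fan-out: every (subject, segment, Δt, surrogate) consumer
  derives its own 31-bit child seed through a multiplicative hash, so runs
  are bitwise reproducible and insensitive to evaluation order.

## Limitations

* The printed DEG percentages of the original 80-subject EEG study are not
  reproduction targets; they depend on undeposited raw data. The package
  reproduces the *designs* and the structural findings on synthetic
  cohorts.
* REST re-referencing, artifact rejection, amplitude-adjusted (AAFT/IAAFT)
  and pseudo-periodic surrogates are out of scope.
* ANOVA treats per-subject DEG values as independent observations per
  level, as in the original design; no repeated-measures correction is
  applied.
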