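# surrseg

Surrogate-data nonlinearity testing with end-matched segmentation for
strongly cyclic biomedical time series.

## The problem

Resting eyes-closed EEG carries a strong ~10 Hz (alpha) cyclic component.
The standard way to ask "is this signal nonlinear, or just linearly filtered
noise?" is the surrogate-data method: build an ensemble of phase-randomized
surrogates that share the original segment's amplitude spectrum, compute a
nonlinear statistic `Q` on the original and on every surrogate, and reject
the linearity null when

```
Z = (Q_data − mean(Q_surrogate)) / sd(Q_surrogate),   |Z| > 1.96
```

The *degree of nonlinearity* summarizes a recording as
`DEG = 100 · n_sign / n`, the percentage of analyzed segments with |Z| > 1.96.

The trap: the discrete Fourier transform implicitly treats the analyzed
segment as periodic. If the segment length is not an integer multiple of the
dominant period `T` — segment length `l = kT + Δt` with `Δt ≠ 0` — the cyclic
power leaks across frequency bins, the surrogates redistribute that leaked
power as broadband phase-random noise, nonlinear statistics computed on the
surrogates shift, and linearity is falsely rejected. The cure is
*end-matching*: cut segments from cycle peak to cycle peak so they span
exactly `k` full periods.

`surrseg` implements the complete pipeline and demonstrates the phenomenon on
synthetic cohorts: zero-phase Butterworth filtering (second-order sections),
KPSS/Phillips–Perron stationarity screening, alpha-peak detection,
end-matched segmentation and `Δt` increments, univariate and multivariate
phase-randomized surrogate ensembles, five discriminating statistics
(Higuchi and Katz fractal dimensions, Lempel–Ziv complexity, sample entropy,
synchronization likelihood), the Z/DEG decision layer, and cohort-level
sweep experiments over `Δt`, channel, frequency band, and segment length with
one-way ANOVA + Bonferroni group statistics.

## Worked example

```r
library(surrseg)

# a 20-pseudo-subject cohort: 10 Hz cyclic component (half the variance)
# over 1/f noise, 200 Hz sampling, 20 end-matched ~5-s segments per subject
co <- cohort_spec(n_subjects = 20, n_segments = 20, seed = 1)

# sweep the segment-length increment over {0, T/4, T/2, 3T/4, T} in ms
sw <- run_delta_t_sweep(co, measure = "hfd",
                        delta_t_ms = c(0, 25, 50, 75, 100),
                        n_surrogates = 20, bonferroni_m = 2)
print(sw)
#> <sweep_result> factor = delta_t, measure = hfd, 20 subjects x 5 levels
#> group-mean DEG (%): 0=7.8, 25=65.8, 50=97.8, 75=52.8, 100=9.2
#> one-way ANOVA: F = 237.533, p = 1.5e-48 (Bonferroni m = 2) -> significant
```

Read: with properly end-matched segments (Δt = 0) the test is calibrated —
DEG ≈ 8%, close to the ~6–7% empirical level of a 1.96 threshold with 20
surrogates. Stretching every segment by half an alpha period (Δt = 50 ms)
drives false rejection to 97.8% of segments on this *purely linear* signal,
and a full period (Δt = 100 ms) restores calibration: the dependence is
non-monotonic with the interior maximum at the odd half-period, exactly the
spectral-leakage signature.

Single-segment usage:

```r
cfg <- synth_config(sampling_rate_hz = 200, duration_s = 30, seed = 7)
rec <- generate_linear_cyclic(cfg)
peaks <- detect_cycle_peaks(rec, 1, "alpha")
seg <- extract_end_matched(rec, peaks, target_length_s = 5)
ens <- build_ensemble(seg, n = 20, seed = 42)
test_segment(ens, "hfd")
#> <nl_test_result> q = 1.452, surrogate 1.4494 +/- 0.005089, z = 0.518 -> no rejection
```

## Command line

```sh
Rscript inst/cli/surrseg sweep-dt my_config.txt
```

with a `key: value` config file (see `?surrseg_cli` for the keys). Each run
writes tidy TSV result tables and a `run_metadata.txt` log.

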