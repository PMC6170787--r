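# Cohort-level experiment harness: synthetic pseudo-subjects run end-to-end
# through peak detection, end-matched segmentation, surrogate ensembles and
# the z-test, swept over the segment-length increment, channel, band-matched
# grids, or segment length.

#' Specify a synthetic cohort
#'
#' A cohort stands in for a multi-subject resting-state recording session.
#' Each pseudo-subject gets its own recording: a dominant cyclic component
#' whose frequency is drawn uniformly from `alpha_freq_range_hz` (the 9–11 Hz
#' spread typical of adult eyes-closed alpha), over 1/f^beta background
#' noise, with per-channel cyclic power fractions `alpha_rel_power`. All
#' randomness fans out deterministically from `seed`.
#'
#' The default 200 Hz sampling rate is a deliberate desk-scale reduction of
#' the 1000 Hz acquisition rate the pipeline was designed around: the
#' end-mismatch phenomenon depends on cycles per analysis window, not on the
#' sampling rate, and the lower rate keeps the O(n^2) measures affordable.
#'
#' @param n_subjects Number of pseudo-subjects.
#' @param n_segments Segments analyzed per subject (Eq. DEG denominator).
#' @param sampling_rate_hz Sampling rate of generated recordings.
#' @param target_length_s End-matched segment target length (seconds).
#' @param alpha_freq_range_hz Range the per-subject dominant frequency is
#'   drawn from.
#' @param alpha_rel_power Cyclic variance fraction per channel (vector
#'   defines the channel count together with `channel_labels`).
#' @param channel_labels Channel names (default from `alpha_rel_power`).
#' @param noise_exponent Background spectral slope beta.
#' @param nonlinearity,nonlinearity_strength Passed to [synth_config()]
#'   (positive-control cohorts).
#' @param seed Master seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, n_segments = 20,
                        sampling_rate_hz = 200, target_length_s = 5,
                        alpha_freq_range_hz = c(9, 11),
                        alpha_rel_power = 0.5,
                        channel_labels = NULL,
                        noise_exponent = 1,
                        nonlinearity = "none",
                        nonlinearity_strength = 0,
                        seed = 1L) {
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_along(alpha_rel_power))
  stopifnot(n_subjects >= 1, n_segments >= 1,
            length(alpha_rel_power) == length(channel_labels))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_segments = as.integer(n_segments),
                 sampling_rate_hz = sampling_rate_hz,
                 target_length_s = target_length_s,
                 alpha_freq_range_hz = alpha_freq_range_hz,
                 alpha_rel_power = alpha_rel_power,
                 channel_labels = as.character(channel_labels),
                 noise_exponent = noise_exponent,
                 nonlinearity = nonlinearity,
                 nonlinearity_strength = nonlinearity_strength,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# deterministic per-subject recording, long enough for the requested
# segmentation including increment margins
generate_subject_recording <- function(cohort, subject, max_dt_ms = 0,
                                       target_length_s = NULL,
                                       n_segments = NULL) {
  target <- target_length_s %||% cohort$target_length_s
  nseg <- n_segments %||% cohort$n_segments
  margin <- max_dt_ms / 1000 + 0.5
  duration <- 2 + nseg * (target + 0.5 * target / 4 + margin)
  sseed <- derive_seed(cohort$seed, subject)
  set.seed(derive_seed(cohort$seed, subject, 7919))
  f <- runif(1, cohort$alpha_freq_range_hz[1], cohort$alpha_freq_range_hz[2])
  cfg <- synth_config(
    sampling_rate_hz = cohort$sampling_rate_hz, duration_s = duration,
    alpha_freq_hz = f, alpha_rel_power = cohort$alpha_rel_power,
    noise_exponent = cohort$noise_exponent,
    channel_labels = cohort$channel_labels,
    nonlinearity = cohort$nonlinearity,
    nonlinearity_strength = cohort$nonlinearity_strength,
    seed = sseed)
  if (cohort$nonlinearity == "none") generate_linear_cyclic(cfg)
  else generate_nonlinear(cfg)
}

new_sweep_result <- function(factor, levels, deg_matrix, measure,
                             bonferroni_m, n_segments, alpha = 0.05,
                             details = NULL, extra = list()) {
  an <- tryCatch(one_way_anova(lapply(seq_len(ncol(deg_matrix)),
                                      function(j) deg_matrix[, j])),
                 error = function(e) list(F = NA_real_, p = NA_real_))
  structure(c(list(factor = factor, levels = levels,
                   deg_matrix = deg_matrix, measure = measure,
                   anova_F = an$F, anova_p = an$p,
                   bonferroni_m = as.integer(bonferroni_m),
                   significant = isTRUE(an$p < alpha / bonferroni_m),
                   n_segments = n_segments, details = details),
              extra),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> factor = %s, measure = %s, %d subjects x %d levels\n",
              x$factor, x$measure, nrow(x$deg_matrix), ncol(x$deg_matrix)))
  means <- colMeans(x$deg_matrix)
  cat("group-mean DEG (%):",
      paste(sprintf("%s=%.1f", x$levels, means), collapse = ", "), "\n")
  cat(sprintf("one-way ANOVA: F = %.3f, p = %.3g (Bonferroni m = %d) -> %s\n",
              x$anova_F, x$anova_p, x$bonferroni_m,
              if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}

#' Write a sweep result as a tidy table
#'
#' @param x A `sweep_result`.
#' @param path Output TSV path.
#' @return The tidy data frame, invisibly.
#' @export
write_sweep_result <- function(x, path) {
  df <- expand.grid(subject = seq_len(nrow(x$deg_matrix)),
                    level = x$levels)
  df$factor <- x$factor
  df$measure <- x$measure
  df$deg_percent <- as.vector(x$deg_matrix)
  write.table(df[, c("factor", "measure", "subject", "level", "deg_percent")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

# core: one subject's DEG profile over a dt grid, for one analysis channel
subject_dt_profile <- function(cohort, subject, rec, measure_fun, band,
                               dts, n_surrogates, channel, channels_used,
                               target_length_s = NULL) {
  target <- target_length_s %||% cohort$target_length_s
  peaks <- detect_cycle_peaks(rec, channel, band)
  segs <- extract_segment_series(rec, peaks, target, cohort$n_segments,
                                 margin_s = max(dts) / 1000 + 0.1,
                                 channels = channels_used)
  deg <- numeric(length(dts))
  rows <- vector("list", length(dts) * length(segs))
  ri <- 0L
  for (d in seq_along(dts)) {
    res <- vector("list", length(segs))
    for (g in seq_along(segs)) {
      seg_d <- if (dts[d] == 0) segs[[g]]
               else increment_segment(rec, segs[[g]], dts[d],
                                      channels = channels_used)
      ens <- build_ensemble(seg_d, n_surrogates,
                            derive_seed(cohort$seed, subject, g, d))
      res[[g]] <- test_segment(ens, measure_fun)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        subject = subject, delta_t_ms = dts[d], segment = g,
        q_data = res[[g]]$q_data, q_surr_mean = res[[g]]$q_surr_mean,
        q_surr_std = res[[g]]$q_surr_std, z = res[[g]]$z,
        rejected = res[[g]]$rejected)
    }
    deg[d] <- degree_of_nonlinearity(res)$deg_percent
  }
  list(deg = deg, details = do.call(rbind, rows[seq_len(ri)]))
}

#' Sweep the segment-length increment (the end-mismatch experiment)
#'
#' For each pseudo-subject: detect cycle peaks of the dominant component,
#' cut `n_segments` end-matched base segments, extend each by every increment
#' of the grid, build a surrogate ensemble per (segment, increment), apply
#' the z-test, and summarize as DEG per subject per increment. A one-way
#' ANOVA across increments (subjects as observations) tests whether the
#' increment influences the outcome — on purely linear cyclic cohorts it
#' should, which is exactly the calibration failure of non-end-matched
#' segmentation.
#'
#' @param cohort A [cohort_spec()].
#' @param measure Measure name (see [measure_function()]) or function.
#' @param band Band whose cyclic component drives segmentation.
#' @param delta_t_ms Increment grid in ms (default: the band's full series).
#' @param n_surrogates Surrogates per segment (default 20).
#' @param channel Reference channel for peak detection and analysis.
#' @param bonferroni_m Number of comparisons in the family this sweep belongs
#'   to (divides the 0.05 level).
#' @param keep_details Keep the per-segment tidy z-table in the result.
#' @return A `sweep_result` with `factor = "delta_t"`.
#' @export
run_delta_t_sweep <- function(cohort, measure = "hfd", band = "alpha",
                              delta_t_ms = NULL, n_surrogates = 20,
                              channel = 1, bonferroni_m = 1,
                              keep_details = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (cohort$n_subjects < 2) stop("ANOVA needs at least 2 subjects")
  band <- as_band(band)
  dts <- delta_t_ms %||% delta_t_series(band)
  mfun <- if (is.character(measure)) measure_function(measure) else measure
  mname <- if (is.character(measure)) measure else "custom"
  channels_used <- if (identical(mname, "sl"))
    cohort$channel_labels[1:2] else channel
  deg <- matrix(NA_real_, cohort$n_subjects, length(dts))
  details <- if (keep_details) vector("list", cohort$n_subjects) else NULL
  for (s in seq_len(cohort$n_subjects)) {
    rec <- generate_subject_recording(cohort, s, max_dt_ms = max(dts))
    prof <- subject_dt_profile(cohort, s, rec, mfun, band, dts,
                               n_surrogates, channel, channels_used)
    deg[s, ] <- prof$deg
    if (keep_details) details[[s]] <- prof$details
  }
  new_sweep_result("delta_t", dts, deg, mname, bonferroni_m,
                   cohort$n_segments,
                   details = if (keep_details) do.call(rbind, details))
}

#' Channel dependence of the end-mismatch effect
#'
#' Runs the increment sweep once per channel (each channel supplies its own
#' cycle peaks and is itself analyzed) and reports the deflection — the
#' max-minus-min group-mean DEG over the grid — per channel. With channels
#' ordered by cyclic power (like occipital > central > temporal alpha), the
#' deflections should follow the same order.
#'
#' @inheritParams run_delta_t_sweep
#' @param channels Channels to compare (default: all in the cohort).
#' @return List of class `channel_dependence` with per-channel
#'   `sweep_result`s and a `deflection` vector.
#' @export
run_channel_dependence <- function(cohort, measure = "hfd", band = "alpha",
                                   delta_t_ms = NULL, n_surrogates = 20,
                                   channels = NULL, bonferroni_m = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  channels <- channels %||% cohort$channel_labels
  if (length(channels) < 2) stop("need at least 2 channels to compare")
  bonferroni_m <- bonferroni_m %||% length(channels)
  sweeps <- lapply(channels, function(ch)
    run_delta_t_sweep(cohort, measure, band, delta_t_ms, n_surrogates,
                      channel = ch, bonferroni_m = bonferroni_m))
  names(sweeps) <- channels
  deflection <- vapply(sweeps, function(sw) {
    m <- colMeans(sw$deg_matrix); max(m) - min(m)
  }, numeric(1))
  structure(list(factor = "channel", channels = channels, sweeps = sweeps,
                 deflection = deflection, measure = sweeps[[1]]$measure),
            class = "channel_dependence")
}

#' @export
print.channel_dependence <- function(x, ...) {
  cat("<channel_dependence> DEG deflection (max - min over increments):\n")
  for (ch in x$channels)
    cat(sprintf("  %s: %.1f%%\n", ch, x$deflection[[ch]]))
  invisible(x)
}

#' Band-matched increment sweeps
#'
#' Repeats the increment experiment with segmentation and increment grid
#' matched to each band's cyclic component (delta, theta, alpha, beta by
#' default) and reports the per-band deflection. When the dominant component
#' sits inside one band, that band's grid should show the largest deflection.
#'
#' @inheritParams run_delta_t_sweep
#' @param bands Band names to sweep.
#' @param grid_points If not NULL, thin each band's full increment series to
#'   this many evenly spaced points (including 0 and the endpoint) to keep
#'   runtime down.
#' @return List of class `band_sweep` of `sweep_result`s plus a `deflection`
#'   vector.
#' @export
run_band_sweep <- function(cohort, measure = "hfd",
                           bands = c("delta", "theta", "alpha", "beta"),
                           grid_points = NULL, n_surrogates = 20,
                           channel = 1, bonferroni_m = NULL) {
  bonferroni_m <- bonferroni_m %||% length(bands)
  sweeps <- lapply(bands, function(b) {
    dts <- delta_t_series(b)
    if (!is.null(grid_points))
      dts <- unique(round(seq(0, max(dts), length.out = grid_points)))
    run_delta_t_sweep(cohort, measure, band = b, delta_t_ms = dts,
                      n_surrogates = n_surrogates, channel = channel,
                      bonferroni_m = bonferroni_m)
  })
  names(sweeps) <- bands
  deflection <- vapply(sweeps, function(sw) {
    m <- colMeans(sw$deg_matrix); max(m) - min(m)
  }, numeric(1))
  structure(list(factor = "band", bands = bands, sweeps = sweeps,
                 deflection = deflection),
            class = "band_sweep")
}

#' @export
print.band_sweep <- function(x, ...) {
  cat("<band_sweep> DEG deflection by band-matched grid:\n")
  for (b in x$bands)
    cat(sprintf("  %s: %.1f%%\n", b, x$deflection[[b]]))
  invisible(x)
}

#' Segment-length study at end-matched lengths
#'
#' DEG per subject at several substantially different end-matched segment
#' lengths (increment 0), sharing each segment's surrogate ensemble across
#' all requested measures. ANOVA across lengths per measure.
#'
#' @inheritParams run_delta_t_sweep
#' @param measures Character vector of measure names.
#' @param lengths_s Target lengths in seconds.
#' @param n_segments Segments per subject per length (the DEG denominator;
#'   default 10).
#' @return Named list of `sweep_result`s (factor `"segment_length"`), one per
#'   measure.
#' @export
run_segment_length_study <- function(cohort, measures = c("hfd", "sampen"),
                                     lengths_s = c(5, 10, 15, 20),
                                     n_segments = 10, n_surrogates = 20,
                                     channel = 1, bonferroni_m = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  band <- as_band("alpha")
  bonferroni_m <- bonferroni_m %||% (length(lengths_s) * length(measures))
  mfuns <- lapply(measures, measure_function)
  deg <- array(NA_real_,
               c(cohort$n_subjects, length(lengths_s), length(measures)))
  for (s in seq_len(cohort$n_subjects)) {
    rec <- generate_subject_recording(
      cohort, s, max_dt_ms = 0, target_length_s = max(lengths_s),
      n_segments = n_segments)
    peaks <- detect_cycle_peaks(rec, channel, band)
    for (li in seq_along(lengths_s)) {
      zs <- matrix(NA_real_, n_segments, length(measures))
      segs <- extract_segment_series(rec, peaks, lengths_s[li], n_segments,
                                     margin_s = 0.05, channels = channel)
      for (g in seq_len(n_segments)) {
        ens <- build_ensemble(segs[[g]], n_surrogates,
                              derive_seed(cohort$seed, s, g, li))
        for (mi in seq_along(measures)) {
          r <- test_segment(ens, mfuns[[mi]])
          zs[g, mi] <- if (r$valid) r$z else NA_real_
        }
      }
      for (mi in seq_along(measures))
        deg[s, li, mi] <- degree_of_nonlinearity(zs[, mi])$deg_percent
    }
  }
  out <- lapply(seq_along(measures), function(mi)
    new_sweep_result("segment_length", lengths_s, deg[, , mi, drop = TRUE],
                     measures[mi], bonferroni_m, n_segments))
  names(out) <- measures
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F is the ratio of between-group to
#' within-group mean squares, with its F-distribution tail probability.
#'
#' @param groups List of numeric vectors (>= 2 groups of >= 2 values).
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @examples
#' one_way_anova(list(rnorm(5), rnorm(5), rnorm(5) + 3))
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values")
  all_v <- unlist(groups)
  gm <- mean(all_v)
  n <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- sum(n) - length(groups)
  if (ssw == 0 && ssb == 0) stop("zero variance everywhere: F undefined")
  if (ssw == 0) return(list(F = Inf, p = 0, df_between = dfb, df_within = dfw))
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = pf(F, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}
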