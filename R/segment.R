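#' Segment-length increment series per frequency band
#'
#' The arithmetic increment grids used for the band-matched sweeps:
#' delta 0, 20, ..., 1000 ms; theta 0, 3, ..., 126 ms; alpha 0, 2, ..., 108 ms;
#' beta 0, 1, ..., 46 ms. Each grid spans roughly one period of the band's
#' characteristic frequency.
#'
#' @param band Band name or [band_definition()] (not broadband).
#' @return Numeric vector of increments in milliseconds.
#' @examples
#' length(delta_t_series("alpha"))  # 55
#' @export
delta_t_series <- function(band) {
  band <- as_band(band)
  switch(band$name,
    delta = seq(0, 1000, by = 20),
    theta = seq(0, 126, by = 3),
    alpha = seq(0, 108, by = 2),
    beta  = seq(0, 46, by = 1),
    stop("no increment series defined for band '", band$name, "'"))
}

new_segment <- function(samples, plan, channel_labels) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  structure(list(samples = samples, plan = plan,
                 channel_labels = channel_labels),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf(
    "<segment> %d samples x %d channel(s), k = %d periods, T = %.2f ms, dt = %g ms, start = %d\n",
    nrow(x$samples), ncol(x$samples), x$plan$k, x$plan$T_ms,
    x$plan$delta_t_ms, x$plan$start_index))
  invisible(x)
}

#' Extract an end-matched segment
#'
#' Cuts a window starting at a detected cycle peak and spanning an exact
#' integer number `k` of realized periods: the window ends one sample before
#' the peak nearest the target length, so its length is `k * T` samples and
#' the implicit periodic extension of the discrete Fourier transform is
#' seamless. `T` is realized empirically from the peak-to-peak span (robust
#' to inter-subject variation of the dominant frequency); the realized
#' length may deviate from the target by up to half a period.
#'
#' @param rec A [multichannel_recording()]. Segments are cut from all
#'   `channels` of this recording (typically the broadband-filtered signal),
#'   while `peaks` usually come from a narrowband reference channel.
#' @param peaks Increasing peak indices from [detect_cycle_peaks()].
#' @param target_length_s Desired segment length in seconds (>= 2 periods).
#' @param start_peak Index into `peaks` at which the segment starts.
#' @param channels Channels to include (default all).
#' @return A `segment` whose `plan` records `k`, `T_ms`, `delta_t_ms = 0`,
#'   `start_index`, `length_samples` and the peak bookkeeping.
#' @export
extract_end_matched <- function(rec, peaks, target_length_s,
                                start_peak = 1L, channels = NULL) {
  stopifnot(inherits(rec, "multichannel_recording"))
  rate <- rec$sampling_rate_hz
  if (length(peaks) < 3) stop("need at least three detected peaks")
  if (start_peak < 1 || start_peak > length(peaks) - 2)
    stop("start_peak out of range")
  start <- peaks[start_peak]
  desired_end <- start + round(target_length_s * rate)
  later <- peaks[(start_peak + 1):length(peaks)]
  j <- which.min(abs(later - desired_end))
  end <- later[j]
  k <- j  # inter-peak intervals spanned
  if (k < 2) stop("peaks do not span two periods at the target length")
  if (abs(end - desired_end) > (end - start) / k / 2 + 1)
    warning("realized segment length deviates from target by more than half a period")
  len <- end - start  # end-exclusive: exactly k realized periods
  T_ms <- (end - start) / k * 1000 / rate
  if (is.null(channels)) channels <- seq_len(ncol(rec$samples))
  idx <- vapply(channels, function(ch) channel_index(rec, ch), integer(1))
  plan <- list(k = as.integer(k), T_ms = T_ms, delta_t_ms = 0,
               start_index = as.integer(start),
               length_samples = as.integer(len),
               start_peak = as.integer(start_peak),
               end_peak = as.integer(start_peak + j),
               sampling_rate_hz = rate)
  new_segment(rec$samples[start:(start + len - 1L), idx, drop = FALSE],
              plan, rec$channel_labels[idx])
}

#' Extend a segment by a stated increment
#'
#' Returns a window with the same start as `base` but `round(dt * rate/1000)`
#' extra samples, re-extracted from the recording. `delta_t_ms = 0` returns
#' the base segment itself.
#'
#' @param rec The source [multichannel_recording()].
#' @param base A `segment` (or its `plan`).
#' @param delta_t_ms Non-negative increment in milliseconds.
#' @param channels Channels to include (default: those of the base plan).
#' @return A `segment` with updated `delta_t_ms` and `length_samples`.
#' @export
increment_segment <- function(rec, base, delta_t_ms, channels = NULL) {
  stopifnot(inherits(rec, "multichannel_recording"))
  plan <- if (inherits(base, "segment")) base$plan else base
  if (delta_t_ms < 0) stop("delta_t_ms must be non-negative")
  rate <- rec$sampling_rate_hz
  extra <- round(delta_t_ms * rate / 1000)  # half-up irrelevant on stated grids
  len <- plan$length_samples + extra
  start <- plan$start_index
  if (start + len - 1L > nrow(rec$samples))
    stop("incremented window exceeds the recording end")
  if (is.null(channels)) {
    if (inherits(base, "segment")) channels <- base$channel_labels
    else channels <- seq_len(ncol(rec$samples))
  }
  idx <- vapply(channels, function(ch) channel_index(rec, ch), integer(1))
  plan$delta_t_ms <- delta_t_ms
  plan$length_samples <- as.integer(len)
  new_segment(rec$samples[start:(start + len - 1L), idx, drop = FALSE],
              plan, rec$channel_labels[idx])
}

#' Extract consecutive non-overlapping end-matched segments
#'
#' Each segment starts at the end peak of the previous one (plus any margin
#' needed for later increments).
#'
#' @inheritParams extract_end_matched
#' @param n_segments Number of segments to extract.
#' @param margin_s Seconds to keep free after each segment so every segment
#'   can later be extended by the largest increment of a sweep.
#' @return List of `segment` objects.
#' @export
extract_segment_series <- function(rec, peaks, target_length_s, n_segments,
                                   margin_s = 0.2, channels = NULL) {
  out <- vector("list", n_segments)
  sp <- 1L
  rate <- rec$sampling_rate_hz
  for (i in seq_len(n_segments)) {
    seg <- extract_end_matched(rec, peaks, target_length_s, sp, channels)
    if (seg$plan$start_index + seg$plan$length_samples - 1L +
        round(margin_s * rate) > nrow(rec$samples))
      stop("recording too short for ", n_segments, " segments (got ", i - 1, ")")
    out[[i]] <- seg
    sp <- seg$plan$end_peak
    if (sp > length(peaks) - 2L && i < n_segments)
      stop("not enough peaks for ", n_segments, " segments (got ", i, ")")
  }
  out
}

#' Write a segment manifest table
#'
#' @param segments List of `segment` objects.
#' @param path Output TSV path (use `""` to return the data frame only).
#' @param subject Optional subject identifier column.
#' @return The manifest data frame, invisibly if written.
#' @export
write_segment_manifest <- function(segments, path = "", subject = NA) {
  df <- do.call(rbind, lapply(segments, function(s) {
    data.frame(subject = subject,
               channel = paste(s$channel_labels, collapse = ","),
               start_index = s$plan$start_index, k = s$plan$k,
               T_ms = s$plan$T_ms, delta_t_ms = s$plan$delta_t_ms,
               length_samples = s$plan$length_samples)
  }))
  if (nzchar(path)) {
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
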