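#' EEG frequency band definitions
#'
#' Named band edges used throughout the pipeline: delta (1–1.5 Hz), theta
#' (4–8 Hz), alpha (7.5–13 Hz), beta (13–30 Hz) and broadband (1–45 Hz).
#'
#' @param name One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"broadband"`, or `"custom"` (then `low_hz`/`high_hz` are required).
#' @param low_hz,high_hz Band edges for a custom band.
#' @return A list of class `band_definition` with `name`, `low_hz`, `high_hz`.
#' @examples
#' band_definition("alpha")
#' @export
band_definition <- function(name = c("alpha", "delta", "theta", "beta",
                                     "broadband", "custom"),
                            low_hz = NULL, high_hz = NULL) {
  name <- match.arg(name)
  edges <- switch(name,
    delta = c(1, 1.5), theta = c(4, 8), alpha = c(7.5, 13),
    beta = c(13, 30), broadband = c(1, 45),
    custom = c(low_hz, high_hz))
  if (name == "custom" && (is.null(low_hz) || is.null(high_hz)))
    stop("custom band needs low_hz and high_hz")
  if (edges[1] <= 0 || edges[1] >= edges[2])
    stop("band must satisfy 0 < low < high")
  structure(list(name = name, low_hz = edges[1], high_hz = edges[2]),
            class = "band_definition")
}

as_band <- function(band) {
  if (inherits(band, "band_definition")) return(band)
  if (is.character(band) && length(band) == 1L) return(band_definition(band))
  if (is.numeric(band) && length(band) == 2L)
    return(band_definition("custom", band[1], band[2]))
  stop("cannot interpret `band`")
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Forward–backward application of an order-`order` Butterworth band-pass
#' filter (order `2*order` effective magnitude response, exactly zero phase
#' shift). All channels are filtered identically.
#'
#' @param rec A [multichannel_recording()].
#' @param band A [band_definition()], band name, or length-2 numeric edges.
#' @param order Filter order per pass (default 4).
#' @return A filtered [multichannel_recording()].
#' @examples
#' rec <- multichannel_recording(sin(2 * pi * 10 * (0:999) / 250), 250)
#' filt <- bandpass_zero_phase(rec, "alpha")
#' @export
bandpass_zero_phase <- function(rec, band, order = 4) {
  stopifnot(inherits(rec, "multichannel_recording"))
  band <- as_band(band)
  rate <- rec$sampling_rate_hz
  if (band$high_hz >= rate / 2)
    stop("band upper edge must be below the Nyquist frequency (", rate / 2, " Hz)")
  sos <- butter_bandpass_sos(band$low_hz, band$high_hz, rate, order)
  out <- apply(rec$samples, 2, function(x) filtfilt_sos(sos, x))
  multichannel_recording(out, rate, rec$channel_labels)
}

#' Detect cycle peaks of the dominant band component
#'
#' Zero-phase filters one channel into `band` and returns the sample indices
#' of local maxima. Maxima closer together than half the band's shortest
#' period are de-duplicated (the larger one is kept), suppressing
#' ripple-induced double peaks.
#'
#' @param rec A [multichannel_recording()].
#' @param channel Channel label or index.
#' @param band Band to isolate the cyclic component (default alpha).
#' @param order Butterworth order per pass.
#' @return Strictly increasing integer vector of peak sample indices.
#' @export
detect_cycle_peaks <- function(rec, channel = 1, band = "alpha", order = 4) {
  band <- as_band(band)
  j <- channel_index(rec, channel)
  f <- bandpass_zero_phase(
    multichannel_recording(rec$samples[, j, drop = FALSE],
                           rec$sampling_rate_hz, rec$channel_labels[j]),
    band, order)$samples[, 1]
  n <- length(f)
  core <- f[2:(n - 1)]
  is_peak <- which(core >= f[1:(n - 2)] & core >= f[3:n]) + 1L
  # drop flat-run duplicates (equal neighbours): keep first of each run
  if (length(is_peak) > 1L)
    is_peak <- is_peak[c(TRUE, diff(is_peak) > 1L)]
  if (length(is_peak) == 0L) stop("no cycle peaks found")
  min_gap <- 0.5 * rec$sampling_rate_hz / band$high_hz
  keep <- rep(TRUE, length(is_peak))
  last <- 1L
  for (i in seq_along(is_peak)[-1]) {
    if (is_peak[i] - is_peak[last] < min_gap) {
      if (f[is_peak[i]] > f[is_peak[last]]) { keep[last] <- FALSE; last <- i }
      else keep[i] <- FALSE
    } else last <- i
  }
  is_peak[keep]
}
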