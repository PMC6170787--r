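#' Multichannel recording container
#'
#' The universal carrier between pipeline stages: a numeric time-by-channel
#' sample matrix with a sampling rate and channel labels. Units are arbitrary
#' (microvolts for real EEG).
#'
#' @param samples Numeric matrix (rows = time points, columns = channels) or a
#'   numeric vector for a single channel.
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @param channel_labels Optional character vector of channel names; defaults
#'   to `ch1`, `ch2`, ...
#' @return An object of class `multichannel_recording`: a list with elements
#'   `samples`, `sampling_rate_hz`, `channel_labels`.
#' @examples
#' rec <- multichannel_recording(matrix(rnorm(2000), ncol = 2), 100)
#' rec
#' @export
multichannel_recording <- function(samples, sampling_rate_hz, channel_labels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be a single positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("recording samples must be finite (no NA/NaN/Inf)")
  nch <- ncol(samples)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  if (length(channel_labels) != nch)
    stop("`channel_labels` length (", length(channel_labels),
         ") does not match channel count (", nch, ")")
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         channel_labels = as.character(channel_labels)),
    class = "multichannel_recording"
  )
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("<multichannel_recording> %d samples x %d channel(s) @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz,
              nrow(x$samples) / x$sampling_rate_hz))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.multichannel_recording <- function(x) dim(x$samples)

#' Number of samples in a recording
#' @param rec A `multichannel_recording`.
#' @return Integer number of time points.
#' @export
n_samples <- function(rec) nrow(rec$samples)

channel_index <- function(rec, channel) {
  if (is.character(channel)) {
    i <- match(channel, rec$channel_labels)
    if (is.na(i)) stop("channel '", channel, "' not found")
    return(i)
  }
  i <- as.integer(channel)
  if (i < 1L || i > ncol(rec$samples)) stop("channel index out of range")
  i
}

#' Write / read a recording as plain delimited text
#'
#' The on-disk format is a tab-separated numeric table (one column per
#' channel, header row of channel labels) plus a sidecar `<path>.meta` file of
#' `key: value` lines carrying the sampling rate, labels and any extra
#' metadata (seed, generator config echo).
#'
#' @param rec A `multichannel_recording`.
#' @param path Output file path for the sample table.
#' @param meta Named list of extra metadata to echo into the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, meta = list()) {
  stopifnot(inherits(rec, "multichannel_recording"))
  df <- as.data.frame(rec$samples)
  names(df) <- rec$channel_labels
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta_path <- paste0(path, ".meta")
  fields <- c(
    list(sampling_rate_hz = rec$sampling_rate_hz,
         channel_labels = paste(rec$channel_labels, collapse = ","),
         n_samples = nrow(rec$samples)),
    meta
  )
  lines <- vapply(names(fields), function(k)
    paste0(k, ": ", paste(format(fields[[k]], digits = 17), collapse = ",")),
    character(1))
  writeLines(lines, meta_path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path))
    stop("sidecar metadata file not found: ", meta_path)
  meta <- read_key_value(meta_path)
  if (is.null(meta$sampling_rate_hz))
    stop("metadata is missing 'sampling_rate_hz'")
  tab <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
  multichannel_recording(tab, as.numeric(meta$sampling_rate_hz),
                         colnames(tab))
}

# parse "key: value" text into a named list of character values
read_key_value <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    i <- regexpr(":", ln, fixed = TRUE)
    if (i < 0) next
    key <- trimws(substr(ln, 1L, i - 1L))
    out[[key]] <- trimws(substr(ln, i + 1L, nchar(ln)))
  }
  out
}
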