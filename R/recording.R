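#' Multichannel physiological recording
#'
#' The in-memory container shared by every pipeline stage: a list of equal
#' length per-channel sample vectors in physical units (microvolts), a common
#' sampling rate, unique channel labels, and the wall-clock start time.
#'
#' @param signals List of numeric vectors, one per channel, equal lengths.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique labels, one per channel.
#' @param start_time \code{POSIXct} start time of the first sample.
#' @return An object of class \code{psg_recording}.
#' @export
psg_recording <- function(signals, sampling_rate, channel_labels,
                          start_time = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  if (!is.list(signals) || length(signals) == 0)
    stop("signals must be a non-empty list of numeric vectors")
  lens <- vapply(signals, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("all channels must have the same length")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (length(channel_labels) != length(signals))
    stop("one label per channel required")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  names(signals) <- channel_labels
  structure(list(
    signals = signals,
    sampling_rate = sampling_rate,
    channel_labels = channel_labels,
    start_time = as.POSIXct(start_time, tz = "UTC")
  ), class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  n <- length(x$signals[[1]])
  cat(sprintf("<psg_recording> %d channels x %d samples @ %g Hz (%.2f h)\n",
              length(x$signals), n, x$sampling_rate,
              n / x$sampling_rate / 3600))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat("  start:", format(x$start_time, "%Y-%m-%d %H:%M:%S"), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param recording A \code{psg_recording}.
#' @return Integer sample count.
#' @export
n_samples <- function(recording) length(recording$signals[[1]])

#' Recording duration in seconds
#' @param recording A \code{psg_recording}.
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording)
  n_samples(recording) / recording$sampling_rate

#' Indices of the EEG channels
#'
#' EEG channels are those whose label starts with "EEG"; everything else
#' (EMG, reference) is excluded from EEG-only computations.
#' @param recording A \code{psg_recording}.
#' @return Integer vector of channel indices.
#' @export
eeg_channels <- function(recording)
  which(startsWith(recording$channel_labels, "EEG"))
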