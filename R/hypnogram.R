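#' Hypnogram: epoch-wise sleep/wake state labels
#'
#' A sequence of state labels over fixed-length scoring epochs (4 s by
#' convention). The label set is closed: WAKE, NREM, REM, ARTIFACT.
#'
#' @param labels Character vector of labels in
#'   \code{c("WAKE","NREM","REM","ARTIFACT")}.
#' @param epoch_s Epoch length in seconds (> 0).
#' @return Object of class \code{hypnogram}.
#' @export
hypnogram <- function(labels, epoch_s = 4) {
  labels <- as.character(labels)
  bad <- which(!labels %in% HYPNOGRAM_STATES)
  if (length(bad) > 0)
    stop(sprintf("unknown state label '%s' at epoch %d", labels[bad[1]], bad[1]))
  if (epoch_s <= 0) stop("epoch_s must be > 0")
  structure(list(labels = labels, epoch_s = epoch_s), class = "hypnogram")
}

#' Closed state label set
#' @export
HYPNOGRAM_STATES <- c("WAKE", "NREM", "REM", "ARTIFACT")

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = HYPNOGRAM_STATES))
  cat(sprintf("<hypnogram> %d epochs of %g s (%.2f h)\n",
              length(x$labels), x$epoch_s,
              length(x$labels) * x$epoch_s / 3600))
  print(tab)
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Write a hypnogram to CSV
#'
#' Columns: \code{epoch_index} (0-based), \code{start_s}, \code{label}.
#' @param hyp A \code{hypnogram}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- length(hyp$labels)
  df <- data.frame(
    epoch_index = seq_len(n) - 1L,
    start_s = (seq_len(n) - 1L) * hyp$epoch_s,
    label = hyp$labels
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' Rejects unknown state strings, naming the offending row. An empty file
#' (header only) yields a zero-length hypnogram with a warning.
#' @param path CSV file with columns epoch_index, start_s, label.
#' @param epoch_s Epoch length if the file is empty (otherwise inferred).
#' @return A \code{hypnogram}.
#' @export
read_hypnogram <- function(path, epoch_s = 4) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "start_s", "label") %in% names(df)))
    stop("hypnogram CSV must have columns epoch_index, start_s, label")
  if (nrow(df) == 0) {
    warning("empty hypnogram file: ", path)
    return(hypnogram(character(0), epoch_s = epoch_s))
  }
  bad <- which(!df$label %in% HYPNOGRAM_STATES)
  if (length(bad) > 0)
    stop(sprintf("unknown state label '%s' at row %d of %s",
                 df$label[bad[1]], bad[1], path))
  ep <- if (nrow(df) >= 2) df$start_s[2] - df$start_s[1] else epoch_s
  hypnogram(df$label, epoch_s = ep)
}

#' Map hypnogram epochs onto recording sample indices
#'
#' Epoch k (0-based) covers the half-open sample interval
#' [k*L*fs, (k+1)*L*fs), where L is the epoch length.
#'
#' @param recording A \code{psg_recording}.
#' @param hyp A \code{hypnogram}; its span must not exceed the recording.
#' @return Data frame with 0-based \code{first_sample} and exclusive
#'   \code{last_sample} per epoch, plus \code{label}.
#' @export
align_hypnogram <- function(recording, hyp) {
  spe <- hyp$epoch_s * recording$sampling_rate
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch length must be an integer number of samples")
  spe <- as.integer(round(spe))
  n_ep <- length(hyp$labels)
  if (n_ep * spe > n_samples(recording))
    stop(sprintf("hypnogram spans %d samples but recording has only %d",
                 n_ep * spe, n_samples(recording)))
  data.frame(
    epoch_index = seq_len(n_ep) - 1L,
    first_sample = (seq_len(n_ep) - 1L) * spe,
    last_sample = seq_len(n_ep) * spe,
    label = hyp$labels
  )
}

#' Read/write event lists (poly-spikes, artifacts)
#'
#' Events CSV contract: columns \code{onset_s}, \code{duration_s},
#' \code{type}, \code{channel}, sorted by onset.
#' @param events Data frame with those columns.
#' @param path File path.
#' @return \code{path} (write) or the data frame (read).
#' @export
write_events <- function(events, path) {
  req <- c("onset_s", "duration_s", "type", "channel")
  stopifnot(all(req %in% names(events)))
  if (any(events$duration_s < 0)) stop("durations must be >= 0")
  events <- events[order(events$onset_s), req, drop = FALSE]
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("onset_s", "duration_s", "type", "channel")
  if (!all(req %in% names(df)))
    stop("events CSV must have columns onset_s, duration_s, type, channel")
  if (is.unsorted(df$onset_s)) stop("event onsets must be non-decreasing")
  df
}
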