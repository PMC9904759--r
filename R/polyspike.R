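#' Poly-spike detection and episode clustering
#'
#' An episode of poly-spikes is a cluster of three or more sharp EEG
#' transients on any of the EEG channels. Spikes are detected as local
#' extrema exceeding a robust-z amplitude threshold with half-amplitude
#' width inside configured bounds; spikes pooled across channels are
#' single-linkage clustered with a maximum inter-spike gap, and clusters of
#' at least three spikes become episodes.
#'
#' @name polyspike
NULL

# half-amplitude width (ms) of the extremum at index i of |z|
half_amp_width_ms <- function(z, i, fs, max_half_samples) {
  thr <- z[i] / 2
  lo <- i
  lim <- max(1L, i - max_half_samples)
  while (lo > lim && z[lo - 1L] > thr) lo <- lo - 1L
  hi <- i
  lim <- min(length(z), i + max_half_samples)
  while (hi < lim && z[hi + 1L] > thr) hi <- hi + 1L
  (hi - lo + 1L) / fs * 1000
}

#' Detect sharp transients on the EEG channels
#'
#' @param recording A preprocessed \code{psg_recording} (detrended,
#'   notch-filtered).
#' @param z_thresh Detection threshold in robust z-units (median/MAD per
#'   channel over the whole recording).
#' @param width_ms Length-2 numeric: admissible half-amplitude width bounds
#'   in milliseconds.
#' @param refractory_ms Events on one channel closer than this are merged,
#'   keeping the larger.
#' @param exclude_mask Optional \code{artifact_mask}; spikes inside flagged
#'   windows are dropped.
#' @return Data frame of spike events: \code{time_s}, \code{channel},
#'   \code{amplitude_z}, \code{width_ms}, sorted by time.
#' @export
detect_spikes <- function(recording, z_thresh = 6, width_ms = c(20, 70),
                          refractory_ms = 30, exclude_mask = NULL) {
  if (n_samples(recording) == 0) stop("empty recording")
  fs <- recording$sampling_rate
  max_half <- as.integer(ceiling(width_ms[2] / 1000 * fs))
  out <- NULL
  for (ch in eeg_channels(recording)) {
    x <- recording$signals[[ch]]
    med <- stats::median(x)
    scale <- stats::mad(x)
    if (is.na(scale) || scale == 0) next
    z <- abs(x - med) / scale
    above <- z > z_thresh
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    peaks <- integer(0)
    for (r in which(runs$values)) {
      seg <- starts[r]:ends[r]
      peaks <- c(peaks, seg[which.max(z[seg])])
    }
    # refractory merge, keep larger
    if (length(peaks) > 1) {
      keep <- logical(length(peaks))
      cur <- 1L
      for (k in 2:length(peaks)) {
        if ((peaks[k] - peaks[cur]) / fs * 1000 <= refractory_ms) {
          if (z[peaks[k]] > z[peaks[cur]]) cur <- k
        } else {
          keep[cur] <- TRUE
          cur <- k
        }
      }
      keep[cur] <- TRUE
      peaks <- peaks[keep]
    }
    w <- vapply(peaks, function(i) half_amp_width_ms(z, i, fs, max_half), 0)
    ok <- w >= width_ms[1] & w <= width_ms[2]
    if (any(ok)) {
      out <- rbind(out, data.frame(
        time_s = (peaks[ok] - 1L) / fs,
        channel = recording$channel_labels[ch],
        amplitude_z = z[peaks[ok]],
        width_ms = w[ok]
      ))
    }
  }
  if (is.null(out))
    out <- data.frame(time_s = numeric(0), channel = character(0),
                      amplitude_z = numeric(0), width_ms = numeric(0))
  out <- out[order(out$time_s), , drop = FALSE]
  if (!is.null(exclude_mask)) {
    win <- floor(out$time_s / exclude_mask$window_s) + 1L
    win <- pmin(win, exclude_mask$n_windows)
    out <- out[!exclude_mask$flagged[win], , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Cluster spikes into poly-spike episodes
#'
#' Spikes (pooled across EEG channels) are chained by single linkage with
#' inter-spike gap at most \code{max_gap_ms}; chains with at least
#' \code{min_spikes} spikes become episodes, smaller chains are discarded.
#'
#' @param spikes Spike event data frame sorted by \code{time_s}.
#' @param max_gap_ms Maximum inter-spike gap within an episode.
#' @param min_spikes Minimum spikes per episode.
#' @return Data frame of episodes: \code{start_s}, \code{end_s},
#'   \code{n_spikes}, \code{channels} (comma-joined set).
#' @export
cluster_episodes <- function(spikes, max_gap_ms = 200, min_spikes = 3) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), channels = character(0))
  if (nrow(spikes) == 0) return(empty)
  if (is.unsorted(spikes$time_s)) stop("spikes must be sorted by time")
  gaps <- diff(spikes$time_s) * 1000
  grp <- cumsum(c(1L, as.integer(gaps > max_gap_ms)))
  out <- empty
  for (g in unique(grp)) {
    sel <- spikes[grp == g, , drop = FALSE]
    if (nrow(sel) >= min_spikes) {
      out <- rbind(out, data.frame(
        start_s = min(sel$time_s), end_s = max(sel$time_s),
        n_spikes = nrow(sel),
        channels = paste(sort(unique(sel$channel)), collapse = ",")))
    }
  }
  out
}

#' Episode frequency over analysis windows
#'
#' @param episodes Episode data frame (\code{start_s} column).
#' @param windows Data frame of non-overlapping \code{start_s}/\code{end_s}
#'   windows (seconds).
#' @return Episodes per hour: episodes whose start falls in any window,
#'   divided by the total window duration.
#' @export
episode_rate <- function(episodes, windows) {
  total_h <- sum(windows$end_s - windows$start_s) / 3600
  if (total_h <= 0) stop("zero total window duration")
  if (nrow(episodes) == 0) return(0)
  inside <- vapply(episodes$start_s, function(t)
    any(t >= windows$start_s & t < windows$end_s), logical(1))
  sum(inside) / total_h
}

#' Detect poly-spike episodes in a recording
#'
#' Convenience chain: artifact mask, per-channel detrend + notch, spike
#' detection, episode clustering; episodes overlapping flagged artifact
#' windows are discarded.
#'
#' The artifact-exclusion threshold sits well above the spike-amplitude
#' regime: epileptiform transients and gross movement artifacts overlap in
#' amplitude, so amplitude-only flagging below ~20 z would swallow genuine
#' spikes; smooth high-amplitude bursts are instead rejected by the spike
#' width bounds.
#'
#' @param recording A raw \code{psg_recording}.
#' @param z_thresh Spike threshold, robust z-units.
#' @param artifact_z Artifact threshold, robust z-units.
#' @param notch Apply the 60 Hz notch before detection.
#' @param max_gap_ms,min_spikes Clustering parameters.
#' @return Episode data frame as from \code{\link{cluster_episodes}}.
#' @export
find_polyspikes <- function(recording, z_thresh = 6, artifact_z = 20,
                            notch = FALSE, max_gap_ms = 200, min_spikes = 3) {
  mask <- detect_artifacts(recording, window_s = 1, z_thresh = artifact_z)
  pre <- recording
  for (ch in eeg_channels(pre)) {
    x <- detrend_mean(pre$signals[[ch]])
    if (notch) x <- notch_filter(x, pre$sampling_rate)
    pre$signals[[ch]] <- x
  }
  spikes <- detect_spikes(pre, z_thresh = z_thresh, exclude_mask = mask)
  cluster_episodes(spikes, max_gap_ms = max_gap_ms, min_spikes = min_spikes)
}
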