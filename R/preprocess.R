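#' Preprocessing: artifact exclusion, detrending, notch filtering, and the
#' fixed analysis-hour schedule
#'
#' The pipeline order is fixed: artifact windows are excluded first, then
#' signals are detrended by mean subtraction, then an eighth-order
#' Butterworth band-stop around 60 Hz (+/-2 Hz) is applied bidirectionally
#' (zero phase).
#'
#' @name preprocess
NULL

#' Detect amplitude artifacts
#'
#' A window is flagged when any EEG channel's peak absolute amplitude
#' exceeds \code{z_thresh} robust z-units (median/MAD over the whole
#' recording, per channel). A flag on any channel excludes the window on
#' all channels. The detection parameters are recorded in the mask for
#' provenance.
#'
#' @param recording A \code{psg_recording}.
#' @param window_s Window length in seconds.
#' @param z_thresh Threshold in robust z-units.
#' @return Object of class \code{artifact_mask}: logical \code{flagged} per
#'   window (TRUE = artifact), \code{window_s}, and \code{params}.
#' @export
detect_artifacts <- function(recording, window_s = 1, z_thresh = 8) {
  if (window_s <= 0) stop("window_s must be > 0")
  fs <- recording$sampling_rate
  n <- n_samples(recording)
  wlen <- as.integer(round(window_s * fs))
  if (n < wlen) stop("recording shorter than one artifact window")
  n_win <- as.integer(ceiling(n / wlen))

  flagged <- rep(FALSE, n_win)
  for (ch in eeg_channels(recording)) {
    x <- recording$signals[[ch]]
    med <- stats::median(x)
    scale <- stats::mad(x)
    if (scale == 0) scale <- stats::sd(x)
    if (is.na(scale) || scale == 0) next       # flat channel: nothing to flag
    z <- abs(x - med) / scale
    for (w in which(!flagged)) {
      i0 <- (w - 1L) * wlen + 1L
      i1 <- min(n, w * wlen)
      if (max(z[i0:i1]) > z_thresh) flagged[w] <- TRUE
    }
  }
  structure(list(
    flagged = flagged, window_s = window_s, n_windows = n_win,
    params = list(z_thresh = z_thresh, window_s = window_s,
                  rule = "peak |robust z| on any EEG channel")
  ), class = "artifact_mask")
}

#' Logical mask at sample resolution
#' @param mask An \code{artifact_mask}.
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @return Logical vector of length \code{n}, TRUE where flagged.
#' @export
mask_samples <- function(mask, n, fs) {
  wlen <- as.integer(round(mask$window_s * fs))
  out <- rep(mask$flagged, each = wlen)
  length(out) <- n
  out[is.na(out)] <- TRUE                      # beyond-mask tail treated as unusable
  out
}

#' Detrend by mean subtraction
#' @param x Numeric signal (non-empty).
#' @return \code{x - mean(x)}.
#' @export
detrend_mean <- function(x) {
  if (length(x) == 0) stop("empty signal")
  x - mean(x)
}

# ---- Butterworth band-stop design (zero-pole-gain -> biquad cascade) ------

# Analog Butterworth lowpass prototype -> band-stop transform -> bilinear.
# Returns a list of biquads, each list(b = c(b0,b1,b2), a = c(1,a1,a2)).
butter_bandstop_sos <- function(order, lo_hz, hi_hz, fs) {
  if (fs <= 2 * hi_hz) stop("sampling rate too low for the requested stop band")
  n <- order
  k_idx <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k_idx + n - 1) / (2 * n))   # left-half-plane poles

  # prewarped band edges
  w1 <- 2 * fs * tan(pi * lo_hz / fs)
  w2 <- 2 * fs * tan(pi * hi_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1

  # lowpass -> bandstop: each prototype pole maps to two poles; 2n zeros at +/- i*w0
  p_inv <- (bw / 2) / p_lp
  p_bs <- c(p_inv + sqrt(p_inv^2 - w0^2), p_inv - sqrt(p_inv^2 - w0^2))
  z_bs <- rep(c(1i * w0, -1i * w0), n)
  k_bs <- Re(1 / prod(-p_lp))                  # H(0) = 1 for the prototype

  # bilinear transform
  fs2 <- 2 * fs
  k_d <- k_bs * Re(prod(fs2 - z_bs) / prod(fs2 - p_bs))
  z_d <- (fs2 + z_bs) / (fs2 - z_bs)
  p_d <- (fs2 + p_bs) / (fs2 - p_bs)

  # pair conjugate poles with conjugate zeros into biquads
  pu <- p_d[Im(p_d) > 0]
  pu <- pu[order(-Mod(pu))]
  zu <- z_d[Im(z_d) > 0]                       # all identical: e^(i*w0_d)
  gain_per <- abs(k_d)^(1 / length(pu))
  sign_k <- sign(k_d)
  sos <- vector("list", length(pu))
  for (s in seq_along(pu)) {
    g <- gain_per * if (s == 1) sign_k else 1
    sos[[s]] <- list(
      b = g * c(1, -2 * Re(zu[s]), Mod(zu[s])^2),
      a = c(1, -2 * Re(pu[s]), Mod(pu[s])^2)
    )
  }
  sos
}

# forward-backward filtering through a biquad cascade with odd-reflection
# padding; zero net phase
sos_filtfilt <- function(sos, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 3000L)
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - 1:pad])
  run <- function(v) {
    for (sec in sos) v <- signal::filter(filt = sec$b, a = sec$a, x = v)
    v
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Zero-phase Butterworth notch filter
#'
#' Eighth-order Butterworth band-stop around \code{center} Hz
#' (+/- \code{half_bw} Hz), designed as a cascade of second-order sections
#' and applied forward-backward so the net phase shift is zero. The design
#' order refers to the band-stop prototype; the forward-backward pass
#' squares the magnitude response.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz; must exceed \code{2*(center+half_bw)}.
#' @param center Notch center frequency, Hz.
#' @param half_bw Half bandwidth, Hz.
#' @param order Butterworth design order.
#' @return Filtered signal, same length.
#' @export
notch_filter <- function(x, fs, center = 60, half_bw = 2, order = 8) {
  if (fs <= 2 * (center + half_bw))
    stop("fs must be > 2*(center + half_bw)")
  sos <- butter_bandstop_sos(order, center - half_bw, center + half_bw, fs)
  # guard against an unstable design (all biquads must have poles inside |z|<1)
  for (sec in sos) {
    r <- Mod(polyroot(rev(sec$a)))
    if (any(r >= 1)) stop("unstable notch filter design at fs = ", fs)
  }
  pad <- min(length(x) - 1L, as.integer(round(fs)))
  sos_filtfilt(sos, x, pad = pad)
}

#' Analysis-hour schedule on the second recording day
#'
#' Returns the six one-hour windows used for spectral and poly-spike
#' analysis: 12 AM-1 AM, 4 AM-5 AM, 8 AM-9 AM, 12 PM-1 PM, 4 PM-5 PM, and
#' 8 PM-9 PM on the second calendar day of the recording, resolved against
#' the recording's start clock time.
#'
#' @param recording A \code{psg_recording} covering the full second day.
#' @return Data frame: \code{start_s}, \code{end_s} (seconds from recording
#'   start), \code{clock} label.
#' @export
select_analysis_hours <- function(recording) {
  start <- recording$start_time
  day2 <- as.POSIXct(format(as.Date(start, tz = "UTC") + 1), tz = "UTC")
  hours <- c(0, 4, 8, 12, 16, 20)
  win_start <- day2 + hours * 3600
  start_s <- as.numeric(difftime(win_start, start, units = "secs"))
  end_s <- start_s + 3600
  dur <- recording_duration(recording)
  labels <- c("12AM-1AM", "4AM-5AM", "8AM-9AM", "12PM-1PM", "4PM-5PM", "8PM-9PM")
  short <- which(end_s > dur + 1e-9)
  if (length(short) > 0)
    stop("recording too short: missing analysis window ", labels[short[1]],
         " of the second day")
  data.frame(start_s = start_s, end_s = end_s, clock = labels)
}
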