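#' Spectral analysis: Welch PSD, band powers, and the low/high power ratio
#'
#' The spectral phenotype of a recording is computed as: Welch power
#' spectral density (2 s Hann windows, 50% overlap, 0.5 Hz resolution) over
#' artifact-free segments; linear interpolation across the 58--62 Hz notch
#' band; integration into seven canonical bands (delta 1--4, theta 4--8,
#' alpha 8--13, low beta 13--18, high beta 18--25, low gamma 25--50, high
#' gamma 50--100 Hz); relative power as band/total over 1--100 Hz; and the
#' low/high-frequency biomarker (alpha + low beta + high beta) / high gamma,
#' which is invariant to any positive rescaling of the PSD and hence
#' identical whether computed from absolute or relative power.
#'
#' @name spectral
NULL

#' Canonical seven-band segmentation of 1--100 Hz
#'
#' @return Data frame with columns \code{name}, \code{lo}, \code{hi} (Hz);
#'   the bands tile 1--100 Hz contiguously.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "low_beta", "high_beta",
             "low_gamma", "high_gamma"),
    lo = c(1, 4, 8, 13, 18, 25, 50),
    hi = c(4, 8, 13, 18, 25, 50, 100)
  )
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Construct a PSD result object
#'
#' Container for a one-sided power spectral density on a uniform frequency
#' grid, as produced by \code{\link{welch_psd}} or built directly from a
#' tabulated spectrum.
#'
#' @param freqs Strictly increasing frequency grid, Hz.
#' @param psd Non-negative density values, signal-units^2/Hz.
#' @param n_segments Number of averaged segments behind the estimate.
#' @param interpolated_range Optional Hz interval replaced by interpolation.
#' @return An object of class \code{psd_result}.
#' @export
psd_result <- function(freqs, psd, n_segments, interpolated_range = NULL) {
  if (any(diff(freqs) <= 0)) stop("frequency grid must be strictly increasing")
  if (any(psd < 0)) stop("PSD must be non-negative")
  structure(list(freqs = freqs, psd = psd, n_segments = n_segments,
                 interpolated_range = interpolated_range),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d frequencies (%.3g-%.4g Hz, d=%g Hz), %d segments\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_segments))
  if (!is.null(x$interpolated_range))
    cat(sprintf("  interpolated: %g-%g Hz\n",
                x$interpolated_range[1], x$interpolated_range[2]))
  invisible(x)
}

#' Welch power spectral density
#'
#' Averaged Hann-tapered periodogram with density scaling, so band power is
#' the area under the curve. Segments are formed only inside maximal
#' artifact-free runs and never straddle masked samples. The frequency
#' spacing equals \code{1/window_s} (0.5 Hz for the default 2 s window).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param window_s Segment length in seconds.
#' @param overlap Fractional overlap between consecutive segments.
#' @param mask Optional logical vector, length of \code{x}; TRUE marks
#'   artifact samples to exclude.
#' @return A \code{psd_result} (one-sided, signal-units^2/Hz).
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5, mask = NULL) {
  nper <- as.integer(round(window_s * fs))
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  clean <- if (is.null(mask)) rep(TRUE, length(x)) else !mask
  if (length(clean) != length(x)) stop("mask length must match signal length")

  runs <- rle(clean)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  seg_starts <- integer(0)
  for (r in which(runs$values & runs$lengths >= nper)) {
    seg_starts <- c(seg_starts, seq.int(starts[r], ends[r] - nper + 1L, by = step))
  }
  if (length(seg_starts) == 0)
    stop("no artifact-free span of at least one Welch window")

  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nper) - 1) / nper))   # periodic Hann
  U <- sum(w^2)
  nfreq <- nper %/% 2 + 1L
  segs <- vapply(seg_starts, function(s) x[s:(s + nper - 1L)] * w,
                 numeric(nper))
  spec <- Mvfft_power(segs, nfreq)
  pxx <- rowMeans(spec) / (fs * U)
  pxx[2:(nfreq - 1L)] <- 2 * pxx[2:(nfreq - 1L)]   # one-sided doubling
  freqs <- (seq_len(nfreq) - 1) * fs / nper
  psd_result(freqs, pxx, n_segments = length(seg_starts))
}

Mvfft_power <- function(segs, nfreq) {
  ft <- stats::mvfft(segs)
  Mod(ft[seq_len(nfreq), , drop = FALSE])^2
}

#' Interpolate the PSD across the notch band
#'
#' Replaces PSD values on grid points in [lo, hi] by a straight line fitted
#' to the \code{n_points} grid points immediately below lo and immediately
#' above hi. \code{method = "least_squares"} fits one least-squares line
#' over the 2*n_points flanking values; \code{method = "flank_means"} draws
#' the line through the two flank mean points. All other values are
#' untouched.
#'
#' @param psdres A \code{psd_result}.
#' @param lo,hi Interpolation band edges, Hz.
#' @param n_points Flanking points per side.
#' @param method Interpolation variant.
#' @return A \code{psd_result} with the band replaced and
#'   \code{interpolated_range} recorded.
#' @export
interpolate_notch_band <- function(psdres, lo = 58, hi = 62, n_points = 10,
                                   method = c("least_squares", "flank_means")) {
  method <- match.arg(method)
  f <- psdres$freqs
  in_band <- which(f >= lo - 1e-9 & f <= hi + 1e-9)
  below <- which(f < lo - 1e-9)
  above <- which(f > hi + 1e-9)
  if (length(below) < n_points || length(above) < n_points)
    stop("insufficient flanking points for notch-band interpolation")
  flank <- c(utils::tail(below, n_points), utils::head(above, n_points))
  xf <- f[flank]; yf <- psdres$psd[flank]
  if (method == "least_squares") {
    fit <- stats::lm.fit(cbind(1, xf), yf)
    line <- fit$coefficients[1] + fit$coefficients[2] * f[in_band]
  } else {
    x1 <- mean(xf[seq_len(n_points)]); y1 <- mean(yf[seq_len(n_points)])
    x2 <- mean(xf[n_points + seq_len(n_points)]); y2 <- mean(yf[n_points + seq_len(n_points)])
    slope <- (y2 - y1) / (x2 - x1)
    line <- y1 + slope * (f[in_band] - x1)
  }
  out <- psdres
  out$psd[in_band] <- pmax(line, 0)
  out$interpolated_range <- c(lo, hi)
  out
}

#' Band powers and the low/high power ratio
#'
#' Absolute power per band is the trapezoidal area under the PSD between
#' the band edges (which must lie on the frequency grid); relative power is
#' band power over total 1--100 Hz power. Because the bands tile 1--100 Hz
#' with shared edges, the seven absolute powers sum exactly to the total.
#'
#' @param psdres A \code{psd_result} whose grid covers 1--100 Hz.
#' @param bands Band definition table as from \code{\link{eeg_bands}}.
#' @return Object of class \code{band_power_table}: data frame of
#'   name/lo/hi/absolute_power/relative_power plus attributes
#'   \code{total_power_1_100} and \code{ratio_low_high}.
#' @export
band_powers <- function(psdres, bands = eeg_bands()) {
  f <- psdres$freqs
  p <- psdres$psd
  tol <- 1e-9
  edge_idx <- function(hz) {
    i <- which(abs(f - hz) < tol)
    if (length(i) != 1) stop("band edge ", hz, " Hz is not on the frequency grid")
    i
  }
  if (min(f) > 1 + tol || max(f) < 100 - tol)
    stop("frequency grid must cover 1-100 Hz")
  absolute <- numeric(nrow(bands))
  for (b in seq_len(nrow(bands))) {
    i0 <- edge_idx(bands$lo[b]); i1 <- edge_idx(bands$hi[b])
    absolute[b] <- trapz(f[i0:i1], p[i0:i1])
  }
  i0 <- edge_idx(1); i1 <- edge_idx(100)
  total <- trapz(f[i0:i1], p[i0:i1])
  if (total <= 0) stop("zero total power in 1-100 Hz: relative power undefined")
  tab <- data.frame(name = bands$name, lo = bands$lo, hi = bands$hi,
                    absolute_power = absolute,
                    relative_power = absolute / total)
  structure(tab, class = c("band_power_table", "data.frame"),
            total_power_1_100 = total,
            ratio_low_high = power_ratio_from_powers(tab))
}

power_ratio_from_powers <- function(tab) {
  low <- sum(tab$absolute_power[tab$name %in% c("alpha", "low_beta", "high_beta")])
  g2 <- tab$absolute_power[tab$name == "high_gamma"]
  if (g2 == 0) stop("high-gamma power is zero: power ratio undefined")
  low / g2
}

#' Low/high-frequency power ratio (alpha + low beta + high beta) / high gamma
#'
#' The 8--25 Hz over 50--100 Hz power ratio. Because numerator and
#' denominator share the normalizing total, the value is identical whether
#' absolute or relative powers are used.
#'
#' @param band_table A \code{band_power_table}.
#' @return Non-negative scalar.
#' @export
power_ratio <- function(band_table) {
  stopifnot(inherits(band_table, "band_power_table"))
  power_ratio_from_powers(band_table)
}

#' Normalize a PSD by its total 1--100 Hz power
#'
#' @param psdres A \code{psd_result} with positive total power in 1--100 Hz.
#' @return A \code{psd_result} whose trapezoidal integral over 1--100 Hz is 1.
#' @export
relative_psd <- function(psdres) {
  f <- psdres$freqs
  sel <- f >= 1 - 1e-9 & f <= 100 + 1e-9
  total <- trapz(f[sel], psdres$psd[sel])
  if (total <= 0) stop("zero total power in 1-100 Hz")
  out <- psdres
  out$psd <- psdres$psd / total
  out
}

#' Full spectral phenotype of a recording
#'
#' Runs the fixed preprocessing and spectral chain per EEG channel:
#' artifact exclusion, mean detrend, zero-phase 60 Hz notch, Welch PSD over
#' clean segments (optionally restricted to the second-day analysis-hour
#' schedule), 58--62 Hz interpolation, band powers, and the power ratio.
#'
#' @param recording A \code{psg_recording}.
#' @param hours "schedule" to restrict to \code{\link{select_analysis_hours}}
#'   windows, or "all" for the whole recording.
#' @param artifact_z Robust-z threshold for artifact exclusion.
#' @param notch Apply the 60 Hz notch + interpolation (disable when the
#'   sampling rate cannot support it or no mains component exists).
#' @param window_s Welch window length, seconds.
#' @return List per EEG channel: \code{psd} (\code{psd_result}),
#'   \code{bands} (\code{band_power_table}), \code{ratio}.
#' @export
spectral_phenotype <- function(recording, hours = c("all", "schedule"),
                               artifact_z = 8, notch = TRUE, window_s = 2) {
  hours <- match.arg(hours)
  fs <- recording$sampling_rate
  mask <- detect_artifacts(recording, window_s = 1, z_thresh = artifact_z)
  smask <- mask_samples(mask, n_samples(recording), fs)

  windows <- if (hours == "schedule") {
    select_analysis_hours(recording)
  } else {
    data.frame(start_s = 0, end_s = recording_duration(recording))
  }

  out <- list()
  for (ch in eeg_channels(recording)) {
    acc_psd <- NULL; acc_n <- 0
    for (w in seq_len(nrow(windows))) {
      i0 <- as.integer(windows$start_s[w] * fs) + 1L
      i1 <- as.integer(windows$end_s[w] * fs)
      x <- recording$signals[[ch]][i0:i1]
      m <- smask[i0:i1]
      x <- detrend_mean(x)
      if (notch) x <- notch_filter(x, fs)
      pr <- welch_psd(x, fs, window_s = window_s, mask = m)
      if (is.null(acc_psd)) acc_psd <- pr$psd * pr$n_segments
      else acc_psd <- acc_psd + pr$psd * pr$n_segments
      acc_n <- acc_n + pr$n_segments
      freqs <- pr$freqs
    }
    pres <- psd_result(freqs, acc_psd / acc_n, n_segments = acc_n)
    if (notch) pres <- interpolate_notch_band(pres)
    bt <- band_powers(pres)
    out[[recording$channel_labels[ch]]] <-
      list(psd = pres, bands = bt, ratio = power_ratio(bt))
  }
  out
}
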