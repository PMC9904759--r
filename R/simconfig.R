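#' Simulation configuration for synthetic polysomnography
#'
#' Bundles every knob of the synthetic EEG/EMG generator. Defaults reproduce
#' the acquisition conditions of a chronic mouse video-EEG rig: 5000 Hz
#' sampling, 48 h recordings, three cortical EEG channels plus neck EMG, and
#' a 14/10 h light/dark cycle with lights on at 06:00.
#'
#' The genotype is encoded continuously through \code{protein_level}, the
#' UBE3A protein level as a fraction of wild type: 1 is wild type, 0 a full
#' maternal knockout, intermediate values model partial reinstatement (e.g.
#' after antisense-oligonucleotide treatment). The mutant electrographic
#' phenotype scales with \code{1 - protein_level}:
#' \itemize{
#'   \item EEG power in 8--25 Hz multiplied by
#'     \code{1 + band_effect_low * (1 - protein_level)},
#'   \item EEG power in 50--100 Hz multiplied by
#'     \code{1 - band_effect_high * (1 - protein_level)},
#'   \item light-phase REM occupancy scaled by
#'     \code{1 - rem_reduction_light * (1 - protein_level)}.
#' }
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param duration_h Recording duration in hours.
#' @param n_eeg_channels Number of cortical EEG channels.
#' @param lights_on_clock Clock time of lights-on, "HH:MM" string.
#' @param light_hours Length of the light phase in hours (dark = 24 - light).
#' @param state_dwell_means Named list \code{list(light=, dark=)} of named
#'   numeric vectors \code{c(WAKE=, NREM=, REM=)} giving mean bout lengths in
#'   seconds; bouts are gamma-distributed with shape 2.
#' @param p_nrem_to_rem Named numeric \code{c(light=, dark=)}: probability
#'   that a NREM bout is followed by REM rather than wake.
#' @param spectral_exponent Exponent chi of the 1/f^chi EEG background.
#' @param band_effect_low Fractional power gain applied to 8--25 Hz for a
#'   full mutant (protein_level 0); must be > -1.
#' @param band_effect_high Fractional power loss applied to 50--100 Hz for a
#'   full mutant; in [0, 1).
#' @param rem_reduction_light Fractional light-phase REM reduction for a full
#'   mutant; in [0, 1).
#' @param spike_rate Poly-spike episode rate, episodes/hour.
#' @param line_noise_amp Amplitude of the 60 Hz mains component, in signal
#'   units (microvolts).
#' @param artifact_rate Rate of gross movement-artifact bursts, events/hour.
#' @param eeg_rms Target RMS of the clean EEG background, microvolts.
#' @param emg_rms Named numeric \code{c(WAKE=, NREM=, REM=)}: EMG RMS per
#'   state in microvolts; must be strictly decreasing WAKE > NREM > REM.
#' @param protein_level UBE3A protein level as a fraction of WT, in [0, 1].
#' @param seed Integer seed driving all randomness.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(sampling_rate = 5000,
                       duration_h = 48,
                       n_eeg_channels = 3,
                       lights_on_clock = "06:00",
                       light_hours = 14,
                       state_dwell_means = list(
                         light = c(WAKE = 120, NREM = 170, REM = 65),
                         dark  = c(WAKE = 300, NREM = 150, REM = 55)
                       ),
                       p_nrem_to_rem = c(light = 0.40, dark = 0.25),
                       spectral_exponent = 1.8,
                       band_effect_low = 0.4,
                       band_effect_high = 0.3,
                       rem_reduction_light = 0.35,
                       spike_rate = 0,
                       line_noise_amp = 0,
                       artifact_rate = 0,
                       eeg_rms = 60,
                       emg_rms = c(WAKE = 120, NREM = 45, REM = 15),
                       protein_level = 1,
                       seed = 1L) {
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (duration_h <= 0) stop("duration_h must be > 0")
  if (n_eeg_channels < 1) stop("need at least one EEG channel")
  if (light_hours <= 0 || light_hours >= 24) stop("light_hours must be in (0, 24)")
  if (rem_reduction_light < 0 || rem_reduction_light >= 1)
    stop("rem_reduction_light must be in [0, 1)")
  if (protein_level < 0 || protein_level > 1)
    stop("protein_level must be in [0, 1]")
  if (spike_rate < 0) stop("spike_rate must be >= 0")
  if (artifact_rate < 0) stop("artifact_rate must be >= 0")
  if (band_effect_high < 0 || band_effect_high >= 1)
    stop("band_effect_high must be in [0, 1)")
  if (band_effect_low <= -1) stop("band_effect_low must be > -1")
  for (phase in c("light", "dark")) {
    dw <- state_dwell_means[[phase]]
    if (is.null(dw) || !all(c("WAKE", "NREM", "REM") %in% names(dw)))
      stop("state_dwell_means$", phase, " must name WAKE, NREM and REM")
    if (any(dw[c("WAKE", "NREM", "REM")] <= 0))
      stop("dwell-time means must be positive")
  }
  if (any(p_nrem_to_rem < 0) || any(p_nrem_to_rem > 1))
    stop("p_nrem_to_rem must be probabilities")
  if (!(emg_rms["WAKE"] > emg_rms["NREM"] && emg_rms["NREM"] > emg_rms["REM"]))
    stop("emg_rms must satisfy WAKE > NREM > REM")
  if (!grepl("^\\d{1,2}:\\d{2}$", lights_on_clock))
    stop("lights_on_clock must be 'HH:MM'")

  structure(list(
    sampling_rate = sampling_rate,
    duration_h = duration_h,
    n_eeg_channels = as.integer(n_eeg_channels),
    lights_on_clock = lights_on_clock,
    light_hours = light_hours,
    state_dwell_means = state_dwell_means,
    p_nrem_to_rem = p_nrem_to_rem,
    spectral_exponent = spectral_exponent,
    band_effect_low = band_effect_low,
    band_effect_high = band_effect_high,
    rem_reduction_light = rem_reduction_light,
    spike_rate = spike_rate,
    line_noise_amp = line_noise_amp,
    artifact_rate = artifact_rate,
    eeg_rms = eeg_rms,
    emg_rms = emg_rms,
    protein_level = protein_level,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %g Hz, %g h, %d EEG channels + EMG\n",
              x$sampling_rate, x$duration_h, x$n_eeg_channels))
  cat(sprintf("  lights on %s for %g h; protein_level %.2f; seed %d\n",
              x$lights_on_clock, x$light_hours, x$protein_level, x$seed))
  invisible(x)
}

# minutes past midnight of an "HH:MM" clock string
clock_to_min <- function(clock) {
  p <- as.integer(strsplit(clock, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}
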