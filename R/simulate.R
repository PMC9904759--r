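#' Synthetic polysomnography generation
#'
#' The generator produces EEG/EMG recordings with the statistical structure
#' the downstream analysis assumes: a semi-Markov wake/NREM/REM state
#' sequence modulated by the light/dark cycle, state-dependent EEG spectra
#' on a 1/f^chi background, EMG tone ordered WAKE > NREM > REM, optional
#' 60 Hz mains contamination, movement-artifact bursts, and Poisson
#' poly-spike episodes. A genotype gradient enters through
#' \code{protein_level}: low protein raises 8--25 Hz EEG power, lowers
#' 50--100 Hz power, and shrinks light-phase REM occupancy.
#'
#' @name synthetic_data
NULL

# ---- hypnogram ------------------------------------------------------------

#' Simulate a semi-Markov hypnogram
#'
#' States alternate WAKE -> NREM -> (REM | WAKE); REM is entered only from
#' NREM. Bout lengths are gamma-distributed (shape 2) with phase-dependent
#' means; the phase (light/dark) at bout onset selects the parameters. For
#' mutants (protein_level < 1) the NREM->REM entry probability in the light
#' phase is scaled by 1 - rem_reduction_light * (1 - protein_level), which
#' scales light-phase REM occupancy by approximately the same factor.
#'
#' @param config A \code{sim_config}.
#' @param start_clock Clock time "HH:MM" at which the recording starts.
#' @return A \code{hypnogram} with \code{floor(duration_h*3600/4)} epochs.
#' @export
simulate_hypnogram <- function(config, start_clock = "00:00") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  simulate_hypnogram_impl(config, start_clock)
}

simulate_hypnogram_impl <- function(config, start_clock = "00:00") {
  epoch_s <- 4
  n_ep <- floor(config$duration_h * 3600 / epoch_s)
  rem_scale <- 1 - config$rem_reduction_light * (1 - config$protein_level)

  start_min <- clock_to_min(start_clock)
  on_min <- clock_to_min(config$lights_on_clock)
  is_light_at <- function(elapsed_s) {
    clock_min <- (start_min + elapsed_s / 60) %% 1440
    since_on <- (clock_min - on_min) %% 1440
    since_on < config$light_hours * 60
  }

  labels <- character(n_ep)
  i <- 1L
  state <- "WAKE"
  while (i <= n_ep) {
    phase <- if (is_light_at((i - 1L) * epoch_s)) "light" else "dark"
    mu <- config$state_dwell_means[[phase]][[state]]
    dwell_s <- stats::rgamma(1, shape = 2, scale = mu / 2)
    k <- max(1L, as.integer(round(dwell_s / epoch_s)))
    j <- min(n_ep, i + k - 1L)
    labels[i:j] <- state
    i <- j + 1L
    p_rem <- config$p_nrem_to_rem[[phase]]
    if (phase == "light") p_rem <- p_rem * rem_scale
    state <- switch(state,
      WAKE = "NREM",
      NREM = if (stats::runif(1) < p_rem) "REM" else "WAKE",
      REM  = if (stats::runif(1) < 0.3) "NREM" else "WAKE"
    )
  }
  hypnogram(labels, epoch_s = epoch_s)
}

#' Light/dark phase per epoch
#'
#' @param n_epochs Number of 4 s epochs.
#' @param epoch_s Epoch length in seconds.
#' @param start_clock Recording start clock "HH:MM".
#' @param lights_on_clock Lights-on clock "HH:MM".
#' @param light_hours Light phase length in hours.
#' @return Character vector "light"/"dark" per epoch.
#' @export
epoch_phases <- function(n_epochs, epoch_s = 4, start_clock = "00:00",
                         lights_on_clock = "06:00", light_hours = 14) {
  start_min <- clock_to_min(start_clock)
  on_min <- clock_to_min(lights_on_clock)
  clock_min <- (start_min + (seq_len(n_epochs) - 1) * epoch_s / 60) %% 1440
  since_on <- (clock_min - on_min) %% 1440
  ifelse(since_on < light_hours * 60, "light", "dark")
}

# ---- spectral synthesis ---------------------------------------------------

gaussian_bump <- function(f, center, width) exp(-(f - center)^2 / (2 * width^2))

#' Target EEG power spectral shape for a sleep/wake state
#'
#' Relative (unnormalized) power spectrum used by the synthesizer:
#' a 1/(0.5+f)^chi background with a delta bump in NREM, a 6.5 Hz theta
#' peak in REM, and a flatter, mildly theta-tinged spectrum in wake. For
#' mutants the 8--25 Hz range is multiplied by
#' 1 + band_effect_low*(1-protein_level) and the 50--100 Hz range by
#' 1 - band_effect_high*(1-protein_level).
#'
#' @param f Frequencies in Hz (>= 0).
#' @param state One of "WAKE", "NREM", "REM".
#' @param config A \code{sim_config}.
#' @return Non-negative power shape, same length as \code{f}.
#' @export
state_spectrum <- function(f, state, config) {
  chi <- config$spectral_exponent
  base <- switch(state,
    WAKE = 1 / (0.5 + f)^(chi - 0.4) * (1 + 0.8 * gaussian_bump(f, 7, 2)),
    NREM = 1 / (0.5 + f)^chi * (1 + 6 * gaussian_bump(f, 2, 1.3)),
    REM  = 1 / (0.5 + f)^(chi - 0.2) * (1 + 5 * gaussian_bump(f, 6.5, 1.0)),
    stop("unknown state: ", state)
  )
  d <- 1 - config$protein_level
  mult <- rep(1, length(f))
  mult[f >= 8 & f < 25] <- 1 + config$band_effect_low * d
  mult[f >= 50 & f <= 100] <- 1 - config$band_effect_high * d
  base * mult
}

# shape white noise to a target spectrum via FFT multiplication, then scale
# to the requested RMS
shaped_noise <- function(n, fs, shape_fun, rms) {
  if (n == 0) return(numeric(0))
  w <- stats::rnorm(n)
  if (n < 8) return(w * rms)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  amp <- sqrt(shape_fun(f))
  amp[1] <- 0                       # no DC
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x * (rms / s)
}

#' Synthesize EEG/EMG signals from a hypnogram
#'
#' Each maximal run of one state is generated as white noise shaped in the
#' frequency domain to \code{\link{state_spectrum}} and scaled to the target
#' EEG RMS; EMG is white noise at the state's RMS. A 60 Hz sinusoid of
#' amplitude \code{line_noise_amp} is added to all EEG channels, and
#' movement-artifact bursts (0.5--2 s, ~10x background amplitude, one random
#' EEG channel each) occur at \code{artifact_rate} events/hour.
#'
#' @param hyp A \code{hypnogram} (ARTIFACT labels are synthesized as WAKE).
#' @param config A \code{sim_config}.
#' @param start_time Recording start \code{POSIXct}.
#' @return List with elements \code{recording} (a \code{psg_recording}) and
#'   \code{ground_truth} (state sequence, artifact intervals, covariates).
#' @export
synthesize_signals <- function(hyp, config,
                               start_time = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  synthesize_signals_impl(hyp, config, start_time)
}

synthesize_signals_impl <- function(hyp, config, start_time) {
  fs <- config$sampling_rate
  epoch_s <- hyp$epoch_s
  spe <- as.integer(round(epoch_s * fs))
  n_ep <- length(hyp$labels)
  n <- n_ep * spe
  states <- ifelse(hyp$labels == "ARTIFACT", "WAKE", hyp$labels)

  runs <- rle(states)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)

  eeg_scale <- c(WAKE = 0.85, NREM = 1.25, REM = 0.9)
  n_eeg <- config$n_eeg_channels
  signals <- vector("list", n_eeg + 1L)
  for (ch in seq_len(n_eeg)) signals[[ch]] <- numeric(n)
  emg <- numeric(n)

  for (r in seq_along(runs$values)) {
    st <- runs$values[r]
    i0 <- (starts[r] - 1L) * spe + 1L
    i1 <- ends[r] * spe
    len <- i1 - i0 + 1L
    for (ch in seq_len(n_eeg)) {
      signals[[ch]][i0:i1] <- shaped_noise(
        len, fs, function(f) state_spectrum(f, st, config),
        rms = config$eeg_rms * eeg_scale[[st]])
    }
    emg[i0:i1] <- stats::rnorm(len, sd = config$emg_rms[[st]])
  }

  if (config$line_noise_amp > 0) {
    t <- (seq_len(n) - 1) / fs
    line <- config$line_noise_amp * sin(2 * pi * 60 * t)
    for (ch in seq_len(n_eeg)) signals[[ch]] <- signals[[ch]] + line
  }

  artifact_intervals <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
  n_art <- stats::rpois(1, config$artifact_rate * config$duration_h)
  if (n_art > 0) {
    onsets <- sort(stats::runif(n_art, 0, n / fs - 3))
    durs <- stats::runif(n_art, 0.5, 2)
    for (a in seq_len(n_art)) {
      ch <- sample.int(n_eeg, 1)
      i0 <- as.integer(onsets[a] * fs) + 1L
      i1 <- min(n, i0 + as.integer(durs[a] * fs) - 1L)
      len <- i1 - i0 + 1L
      burst <- 10 * config$eeg_rms * sin(pi * seq_len(len) / len) *
        sin(2 * pi * 3 * seq_len(len) / fs)
      signals[[ch]][i0:i1] <- signals[[ch]][i0:i1] + burst
    }
    artifact_intervals <- merge_intervals(data.frame(onset_s = onsets, duration_s = durs))
  }

  signals[[n_eeg + 1L]] <- emg
  labels <- c(paste("EEG", c("FC-L", "SC-L", "VC-R", "X1", "X2", "X3")[seq_len(n_eeg)]),
              "EMG")
  rec <- psg_recording(signals, sampling_rate = fs, channel_labels = labels,
                       start_time = start_time)
  gt <- list(
    state_sequence = hyp,
    spike_episode_times = numeric(0),
    artifact_intervals = artifact_intervals,
    covariates = list(
      genotype = if (config$protein_level >= 0.999) "WT" else "mutant",
      protein_level = config$protein_level,
      ATS_level = ats_from_protein(config$protein_level)
    )
  )
  list(recording = rec, ground_truth = gt)
}

# non-overlapping union of (onset, duration) intervals
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$onset_s), , drop = FALSE]
  out_on <- iv$onset_s[1]; out_end <- iv$onset_s[1] + iv$duration_s[1]
  ons <- c(); ends <- c()
  for (k in seq_len(nrow(iv))[-1]) {
    s <- iv$onset_s[k]; e <- s + iv$duration_s[k]
    if (s <= out_end) out_end <- max(out_end, e)
    else { ons <- c(ons, out_on); ends <- c(ends, out_end); out_on <- s; out_end <- e }
  }
  ons <- c(ons, out_on); ends <- c(ends, out_end)
  data.frame(onset_s = ons, duration_s = ends - ons)
}

# deterministic antisense-transcript companion: protein = a*exp(-k*ATS) + b
# inverted so the association module's decay fit has a recoverable target
ATS_DECAY <- c(a = 0.9, k = 2.2, b = 0.08)

ats_from_protein <- function(p) {
  if (p >= 0.999) return(1.0)           # WT: full antisense, protein from maternal allele
  a <- ATS_DECAY[["a"]]; k <- ATS_DECAY[["k"]]; b <- ATS_DECAY[["b"]]
  frac <- min(max((p - b) / a, 1e-3), 1)
  -log(frac) / k
}

# ---- poly-spikes ----------------------------------------------------------

#' Inject stereotyped poly-spike episodes
#'
#' Episode onsets are Poisson with the given rate; each episode is a run of
#' three or more sharp Gaussian transients (half-amplitude width 20--70 ms,
#' inter-spike gap 80--150 ms) added to the first EEG channel at
#' \code{amp_z} robust z-units above background. All injected episode times
#' are returned for recovery testing.
#'
#' @param recording A \code{psg_recording}.
#' @param rate Episodes per hour (>= 0).
#' @param config A \code{sim_config} (supplies the seed).
#' @param amp_z Spike amplitude in robust z-units of the target channel.
#' @return List: \code{recording} (with spikes added) and \code{episodes},
#'   a data frame of onset_s, duration_s, n_spikes.
#' @export
inject_polyspikes <- function(recording, rate, config, amp_z = 10) {
  if (rate < 0) stop("spike rate must be >= 0")
  set.seed(config$seed + 2L)
  inject_polyspikes_impl(recording, rate, amp_z)
}

inject_polyspikes_impl <- function(recording, rate, amp_z) {
  fs <- recording$sampling_rate
  dur_h <- recording_duration(recording) / 3600
  episodes <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                         n_spikes = integer(0))
  n_epi <- stats::rpois(1, rate * dur_h)
  if (n_epi == 0) return(list(recording = recording, episodes = episodes))

  ch <- eeg_channels(recording)[1]
  x <- recording$signals[[ch]]
  rsd <- stats::mad(x)
  total_s <- length(x) / fs
  onsets <- sort(stats::runif(n_epi, 2, total_s - 5))

  for (e in seq_len(n_epi)) {
    ns <- 3L + stats::rpois(1, 1.2)
    gaps <- stats::runif(ns - 1, 0.08, 0.15)
    times <- onsets[e] + c(0, cumsum(gaps))
    for (tt in times) {
      sigma_s <- stats::runif(1, 0.012, 0.026)     # FWHM 28--61 ms
      half <- as.integer(round(3 * sigma_s * fs))
      idx <- as.integer(round(tt * fs)) + (-half:half)
      idx <- idx[idx >= 1 & idx <= length(x)]
      tsec <- (idx - round(tt * fs)) / fs
      x[idx] <- x[idx] - amp_z * rsd * exp(-tsec^2 / (2 * sigma_s^2))
    }
    episodes <- rbind(episodes, data.frame(
      onset_s = onsets[e], duration_s = max(times) - onsets[e] + 0.05,
      n_spikes = ns))
  }
  recording$signals[[ch]] <- x
  list(recording = recording, episodes = episodes)
}

# ---- full recordings and cohorts ------------------------------------------

#' Simulate one complete recording with ground truth
#'
#' Chains hypnogram simulation, spectral synthesis, and poly-spike
#' injection under the config's seed.
#'
#' @param config A \code{sim_config}.
#' @param start_time Recording start \code{POSIXct}.
#' @return List: \code{recording}, \code{hypnogram}, \code{ground_truth}.
#' @export
simulate_recording <- function(config,
                               start_time = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  start_clock <- format(start_time, "%H:%M")
  hyp <- simulate_hypnogram(config, start_clock = start_clock)
  syn <- synthesize_signals(hyp, config, start_time = start_time)
  spk <- inject_polyspikes(syn$recording, config$spike_rate, config)
  gt <- syn$ground_truth
  gt$spike_episodes <- spk$episodes
  gt$spike_episode_times <- spk$episodes$onset_s
  list(recording = spk$recording, hypnogram = hyp, ground_truth = gt)
}

#' Simulate a cohort and write it to disk
#'
#' One EDF plus sidecars (hypnogram CSV, events CSV, covariates JSON) per
#' animal, and a manifest CSV mapping files to covariates. Per-animal seeds
#' are derived deterministically from the master seed and animal index.
#'
#' @param group_specs Data frame with columns genotype, treatment, n,
#'   protein_level (one row per group).
#' @param config Base \code{sim_config}; per-animal protein_level and seed
#'   are substituted per group.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame, invisibly written to
#'   \code{out_dir/manifest.csv}.
#' @export
simulate_cohort <- function(group_specs, config, out_dir) {
  req <- c("genotype", "treatment", "n", "protein_level")
  stopifnot(all(req %in% names(group_specs)), all(group_specs$n >= 1))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- NULL
  idx <- 0L
  for (g in seq_len(nrow(group_specs))) {
    for (a in seq_len(group_specs$n[g])) {
      idx <- idx + 1L
      animal_id <- sprintf("m%03d", idx)
      cfg <- config
      cfg$protein_level <- group_specs$protein_level[g]
      cfg$seed <- as.integer((as.numeric(config$seed) * 1000 + idx) %% 2147483647)
      sim <- simulate_recording(cfg)
      edf_path <- file.path(out_dir, paste0(animal_id, ".edf"))
      if (file.exists(edf_path))
        stop("output path collision: ", edf_path)
      write_edf(sim$recording, edf_path)
      write_hypnogram(sim$hypnogram,
                      file.path(out_dir, paste0(animal_id, "_hypnogram.csv")))
      ev <- rbind(
        if (nrow(sim$ground_truth$spike_episodes) > 0)
          data.frame(onset_s = sim$ground_truth$spike_episodes$onset_s,
                     duration_s = sim$ground_truth$spike_episodes$duration_s,
                     type = "polyspike", channel = "EEG FC-L"),
        if (nrow(sim$ground_truth$artifact_intervals) > 0)
          data.frame(onset_s = sim$ground_truth$artifact_intervals$onset_s,
                     duration_s = sim$ground_truth$artifact_intervals$duration_s,
                     type = "artifact", channel = "any")
      )
      if (is.null(ev)) ev <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                                        type = character(0), channel = character(0))
      write_events(ev, file.path(out_dir, paste0(animal_id, "_events.csv")))
      cov <- sim$ground_truth$covariates
      set.seed(cfg$seed + 3L)                 # per-animal ATS measurement noise
      cov$ATS_level <- cov$ATS_level * exp(stats::rnorm(1, 0, 0.08))
      cov$animal_id <- animal_id
      cov$treatment <- group_specs$treatment[g]
      cov$genotype <- group_specs$genotype[g]
      jsonlite::write_json(cov, file.path(out_dir, paste0(animal_id, "_covariates.json")),
                           auto_unbox = TRUE, digits = NA)
      manifest <- rbind(manifest, data.frame(
        animal_id = animal_id,
        edf = basename(edf_path),
        genotype = group_specs$genotype[g],
        treatment = group_specs$treatment[g],
        protein_level = group_specs$protein_level[g],
        ATS_level = cov$ATS_level,
        seed = cfg$seed
      ))
    }
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
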