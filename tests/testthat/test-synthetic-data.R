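# Synthetic polysomnography generator

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(duration_h = 0), "duration")
  expect_error(sim_config(rem_reduction_light = 1), "rem_reduction_light")
  expect_error(sim_config(protein_level = 1.2), "protein_level")
  expect_error(sim_config(spike_rate = -1), "spike_rate")
  expect_error(sim_config(light_hours = 24), "light_hours")
  expect_error(sim_config(state_dwell_means = list(
    light = c(WAKE = -5, NREM = 100, REM = 50),
    dark = c(WAKE = 100, NREM = 100, REM = 50))), "positive")
  expect_error(sim_config(emg_rms = c(WAKE = 10, NREM = 45, REM = 15)),
               "WAKE > NREM > REM")
})

test_that("hypnogram simulation is deterministic under the seed and REM is entered only from NREM", {
  cfg <- sim_config(duration_h = 6, seed = 21)
  h1 <- simulate_hypnogram(cfg)
  h2 <- simulate_hypnogram(cfg)
  expect_identical(h1$labels, h2$labels)
  expect_length(h1, floor(6 * 3600 / 4))
  prev <- h1$labels[-length(h1$labels)]
  nxt <- h1$labels[-1]
  expect_false(any(prev == "WAKE" & nxt == "REM"))
})

test_that("empirical REM fraction matches a brute-force long-run oracle", {
  # phase-homogeneous config so the oracle can ignore the light cycle
  dw <- list(light = c(WAKE = 120, NREM = 170, REM = 65),
             dark = c(WAKE = 120, NREM = 170, REM = 65))
  cfg <- sim_config(duration_h = 24, seed = 31, state_dwell_means = dw,
                    p_nrem_to_rem = c(light = 0.4, dark = 0.4))
  hyp <- simulate_hypnogram(cfg)
  frac <- mean(hyp$labels == "REM")

  # stationary fraction from a 10x-duration independent simulation, and the
  # spread of a single 24 h run from oracle replicates
  long <- oracle_state_seconds(cfg, 240 * 3600, seed = 1)
  p_stat <- long[["REM"]] / sum(long)
  reps <- vapply(1:10, function(s) {
    v <- oracle_state_seconds(cfg, 24 * 3600, seed = 100 + s)
    v[["REM"]] / sum(v)
  }, numeric(1))
  expect_lt(abs(frac - p_stat), 2 * sd(reps) + 1e-12)
})

test_that("mutants lose light-phase REM time relative to wild type", {
  rem_min <- function(protein, seed) {
    cfg <- sim_config(duration_h = 24, protein_level = protein, seed = seed)
    tb <- time_budget(simulate_hypnogram(cfg))
    tb$seconds[tb$phase == "light" & tb$state == "REM"] / 60
  }
  wt <- vapply(1:20, function(s) rem_min(1, 1000 + s), numeric(1))
  mut <- vapply(1:20, function(s) rem_min(0, 2000 + s),  numeric(1))
  expect_lt(mean(mut), mean(wt))
})

test_that("wake spectra match the configured spectral shape (periodogram oracle)", {
  cfg <- sim_config(sampling_rate = 250, duration_h = 1 / 60, seed = 1)
  n <- 250 * 60
  acc <- NULL
  for (s in 1:50) {
    cfg$seed <- s
    hyp <- hypnogram(rep("WAKE", 15), epoch_s = 4)
    syn <- synthesize_signals(hyp, cfg)
    pr <- welch_psd(syn$recording$signals[[1]], 250)
    acc <- if (is.null(acc)) pr$psd else acc + pr$psd
  }
  avg <- acc / 50
  f <- pr$freqs
  sel <- f >= 2 & f <= 80
  target <- state_spectrum(f[sel], "WAKE", cfg)
  # compare shapes after normalization on the common support
  a <- avg[sel] / sum(avg[sel]); b <- target / sum(target)
  expect_lt(max(abs(a - b) / b), 0.15)
})

test_that("mutant effect raises 8-25 Hz and lowers 50-100 Hz relative power; null effect is indistinguishable", {
  cfg <- sim_config(sampling_rate = 500, duration_h = 0.1, seed = 5)
  hyp <- simulate_hypnogram(cfg)
  wt <- synthesize_signals(hyp, cfg)
  cfg_m <- cfg; cfg_m$protein_level <- 0
  mut <- synthesize_signals(hyp, cfg_m)
  bp <- function(rec) {
    pr <- welch_psd(rec$signals[[1]], 500)
    band_powers(pr)
  }
  bw <- bp(wt$recording); bm <- bp(mut$recording)
  low <- function(b) sum(b$relative_power[b$name %in% c("alpha", "low_beta", "high_beta")])
  expect_gt(low(bm), low(bw))
  expect_lt(bm$relative_power[bm$name == "high_gamma"],
            bw$relative_power[bw$name == "high_gamma"])

  # zero effect sizes: WT vs "mutant" ratios statistically indistinguishable
  rat <- function(protein, seed) {
    c0 <- sim_config(sampling_rate = 500, duration_h = 0.05, seed = seed,
                     band_effect_low = 0, band_effect_high = 0,
                     protein_level = protein)
    syn <- synthesize_signals(simulate_hypnogram(c0), c0)
    power_ratio(band_powers(welch_psd(syn$recording$signals[[1]], 500)))
  }
  r_wt <- vapply(1:10, function(s) rat(1, 300 + s), numeric(1))
  r_mut <- vapply(1:10, function(s) rat(0, 400 + s), numeric(1))
  expect_gt(t.test(r_wt, r_mut)$p.value, 0.05)
})

test_that("EMG RMS ordering wake > NREM > REM holds per recording", {
  cfg <- sim_config(sampling_rate = 250, duration_h = 0.5, seed = 8)
  sim <- simulate_recording(cfg)
  feats <- extract_epoch_features(sim$recording)
  m <- tapply(feats$emg_rms, sim$hypnogram$labels, mean)
  expect_true(m[["WAKE"]] > m[["NREM"]])
  expect_true(m[["NREM"]] > m[["REM"]])
})

test_that("poly-spike injection is Poisson with every episode containing >= 3 transients", {
  cfg <- sim_config(sampling_rate = 250, duration_h = 6, seed = 9)
  # rate 0: nothing injected
  rec <- flat_recording(secs = 60)
  out0 <- inject_polyspikes(rec, 0, cfg)
  expect_equal(nrow(out0$episodes), 0)
  expect_error(inject_polyspikes(rec, -1, cfg), "rate")

  # Poisson(60) episode counts over 6 h at 10/h: mean within 3 s.e.
  counts <- vapply(1:50, function(s) {
    cfg2 <- sim_config(sampling_rate = 50, duration_h = 6, seed = s)
    base <- psg_recording(list(rnorm(50 * 21600, sd = 50)), 50, "EEG FC-L")
    nrow(inject_polyspikes(base, 10, cfg2)$episodes)
  }, numeric(1))
  lambda <- 60
  se <- sqrt(lambda / 50)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  expect_true(all(vapply(1:5, function(s) {
    cfg3 <- sim_config(sampling_rate = 250, duration_h = 1, seed = 50 + s)
    base <- psg_recording(list(rnorm(250 * 3600, sd = 50)), 250, "EEG FC-L")
    all(inject_polyspikes(base, 10, cfg3)$episodes$n_spikes >= 3)
  }, logical(1))))
})

test_that("protein level monotonically shrinks the power-ratio excess and REM deficit", {
  grid <- c(0, 0.5, 1)
  ratio_avg <- rem_avg <- numeric(3)
  for (g in seq_along(grid)) {
    r <- v <- numeric(4)
    for (s in 1:4) {
      cfg <- sim_config(sampling_rate = 500, duration_h = 0.05,
                        protein_level = grid[g], seed = 600 + s)
      syn <- synthesize_signals(simulate_hypnogram(cfg), cfg)
      r[s] <- power_ratio(band_powers(welch_psd(syn$recording$signals[[1]], 500)))
      cfgH <- sim_config(duration_h = 24, protein_level = grid[g], seed = 700 + s)
      tb <- time_budget(simulate_hypnogram(cfgH))
      v[s] <- tb$seconds[tb$phase == "light" & tb$state == "REM"]
    }
    ratio_avg[g] <- mean(r); rem_avg[g] <- mean(v)
  }
  expect_true(all(diff(ratio_avg) < 0))   # ratio falls as protein rises
  expect_true(all(diff(rem_avg) > 0))     # REM recovers as protein rises
})

test_that("cohort writer produces one EDF + sidecars per animal, deterministically", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- sim_config(sampling_rate = 250, duration_h = 1 / 30, seed = 77)
  gs <- data.frame(genotype = c("WT", "mut", "mut", "mut"),
                   treatment = c("control", "control", "aso_a", "aso_b"),
                   n = 3, protein_level = c(1, 0.1, 0.7, 0.4))
  man1 <- simulate_cohort(gs, cfg, out1)
  man2 <- simulate_cohort(gs, cfg, out2)
  expect_equal(nrow(man1), 12)
  expect_length(list.files(out1, pattern = "\\.edf$"), 12)
  expect_length(list.files(out1, pattern = "_hypnogram\\.csv$"), 12)
  expect_length(list.files(out1, pattern = "_covariates\\.json$"), 12)
  expect_equal(man1$protein_level, rep(gs$protein_level, each = 3))
  # same master seed: byte-identical sidecars
  f <- "m005_hypnogram.csv"
  expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  expect_identical(readBin(file.path(out1, "m005.edf"), "raw", 1e6),
                   readBin(file.path(out2, "m005.edf"), "raw", 1e6))
})
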