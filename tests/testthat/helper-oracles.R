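# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately re-derive quantities by the most literal route
# available (direct loops, pairwise reachability, permutation nulls) and
# never call the implementation paths they check.

# small, fast simulation config for tests
tiny_config <- function(...) {
  sim_config(sampling_rate = 250, duration_h = 0.1, ...)
}

# --- brute-force semi-Markov simulator (independent of simulate_hypnogram):
# samples bouts directly in continuous time and accumulates per-state
# seconds; phase-free (uses the light parameters throughout)
oracle_state_seconds <- function(config, total_s, seed) {
  set.seed(seed)
  dw <- config$state_dwell_means$light
  p_rem <- config$p_nrem_to_rem[["light"]] *
    (1 - config$rem_reduction_light * (1 - config$protein_level))
  secs <- c(WAKE = 0, NREM = 0, REM = 0)
  state <- "WAKE"; t <- 0
  while (t < total_s) {
    d <- rgamma(1, shape = 2, scale = dw[[state]] / 2)
    d <- max(4, round(d / 4) * 4)          # same 4 s quantization
    d <- min(d, total_s - t)
    secs[state] <- secs[state] + d
    t <- t + d
    state <- switch(state,
      WAKE = "NREM",
      NREM = if (runif(1) < p_rem) "REM" else "WAKE",
      REM  = if (runif(1) < 0.3) "NREM" else "WAKE")
  }
  secs
}

# --- brute-force episode clustering via pairwise reachability: adjacency if
# |t_i - t_j| <= gap, transitive closure, count components of size >= k
oracle_cluster_count <- function(times, max_gap_s, min_spikes = 3) {
  n <- length(times)
  if (n == 0) return(0)
  adj <- abs(outer(times, times, "-")) <= max_gap_s
  reach <- adj
  for (i in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  comp <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { nxt <- nxt + 1L; comp[which(reach[i, ])] <- nxt }
  }
  sum(table(comp) >= min_spikes)
}

# --- brute-force one-vs-rest confusion counts, epoch by epoch
oracle_confusion <- function(a, b, state) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(a)) {
    if (a[i] == state && b[i] == state) tp <- tp + 1L
    else if (a[i] != state && b[i] == state) fp <- fp + 1L
    else if (a[i] == state && b[i] != state) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# --- permutation null for the regression slope (two-sided)
oracle_perm_slope_p <- function(x, y, n_perm = 10000, seed = 1) {
  set.seed(seed)
  obs <- abs(cov(x, y))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (abs(cov(x, sample(y))) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# --- match detected episodes against injected onsets with a tolerance
match_episodes <- function(injected_onsets, detected_starts, tol_s = 0.5) {
  sens_hits <- vapply(injected_onsets, function(o)
    any(abs(detected_starts - o) < tol_s), logical(1))
  spurious <- vapply(detected_starts, function(s)
    !any(abs(injected_onsets - s) < tol_s), logical(1))
  list(sensitivity = if (length(injected_onsets) == 0) NA else mean(sens_hits),
       n_spurious = sum(spurious), n_detected = length(detected_starts))
}

# flat unit recording of given seconds for plumbing tests
flat_recording <- function(secs = 10, fs = 250, n_ch = 3,
                           start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  n <- secs * fs
  sig <- c(replicate(n_ch, numeric(n), simplify = FALSE), list(numeric(n)))
  psg_recording(sig, fs, c(paste("EEG", c("FC-L", "SC-L", "VC-R")[seq_len(n_ch)]), "EMG"),
                start_time = start)
}
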