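# Epoch features, staging stand-in, time budgets, agreement metrics

test_that("feature extraction yields one row per complete epoch with sane zeros", {
  rec <- flat_recording(secs = 62, fs = 250)       # 15 complete epochs + remainder
  feats <- extract_epoch_features(rec)
  expect_equal(nrow(feats), 15)
  expect_true(all(feats$delta == 0) && all(feats$emg_rms == 0))
  expect_error(extract_epoch_features(flat_recording(secs = 2)), "shorter")
  # 24 h at 4 s epochs = 21,600 rows (checked at a coarse rate for speed)
  n <- 24 * 3600 * 10
  rec24 <- psg_recording(list(numeric(n), numeric(n)), 10, c("EEG FC-L", "EMG"))
  expect_equal(nrow(extract_epoch_features(rec24)), 21600)
})

test_that("REM epochs show higher theta/delta than NREM epochs", {
  cfg <- sim_config(sampling_rate = 250, duration_h = 0.5, seed = 17)
  sim <- simulate_recording(cfg)
  feats <- extract_epoch_features(sim$recording)
  labs <- sim$hypnogram$labels
  skip_if(!all(c("REM", "NREM") %in% labs))
  expect_gt(mean(feats$theta_delta[labs == "REM"]),
            mean(feats$theta_delta[labs == "NREM"]))
})

test_that("unsupervised staging reaches 0.90 accuracy with per-state recall >= 0.80", {
  cfg <- sim_config(sampling_rate = 250, duration_h = 2, seed = 19)
  sim <- simulate_recording(cfg)
  feats <- extract_epoch_features(sim$recording)
  hyp_hat <- classify_epochs(feats)
  truth <- sim$hypnogram$labels
  expect_gte(mean(hyp_hat$labels == truth), 0.90)
  for (s in c("WAKE", "NREM", "REM"))
    expect_gte(agreement_metrics(truth, hyp_hat$labels, s)$recall, 0.80)
})

test_that("a trained model labels an all-wake recording as wake", {
  cfg <- sim_config(sampling_rate = 250, duration_h = 1, seed = 23)
  sim <- simulate_recording(cfg)
  feats <- extract_epoch_features(sim$recording)
  model <- fit_sleep_model(feats, sim$hypnogram$labels)
  # fresh recording that is wake throughout
  cfg2 <- sim_config(sampling_rate = 250, duration_h = 0.25, seed = 29)
  hyp_w <- hypnogram(rep("WAKE", 225))
  syn <- synthesize_signals(hyp_w, cfg2)
  feats_w <- extract_epoch_features(syn$recording)
  out <- classify_epochs(feats_w, model)
  expect_gte(mean(out$labels == "WAKE"), 0.95)
})

test_that("Viterbi smoothing removes isolated single-epoch REM flips", {
  cfg <- sim_config(sampling_rate = 250, duration_h = 1.5, seed = 31)
  sim <- simulate_recording(cfg)
  feats <- extract_epoch_features(sim$recording)
  model <- fit_sleep_model(feats, sim$hypnogram$labels)
  # raw argmax labels (no temporal smoothing)
  X <- psgpheno:::feature_matrix(feats)
  states <- rownames(model$mu)
  ll <- vapply(seq_along(states), function(k)
    rowSums(dnorm(X, mean = rep(model$mu[k, ], each = nrow(X)),
                  sd = rep(model$sd[k, ], each = nrow(X)), log = TRUE)),
    numeric(nrow(X)))
  raw <- states[max.col(ll)]
  dec <- classify_epochs(feats, model)$labels
  isolated <- function(l) sum(l[-c(1, length(l))] == "REM" &
                                l[-c(length(l) - 1, length(l))] == "NREM" &
                                l[-c(1, 2)] == "NREM")
  expect_lte(isolated(dec), isolated(raw))
  expect_error(classify_epochs(data.frame(delta = rep(1, 50), theta = 1,
                                          theta_delta = 1, broadband = 1,
                                          emg_rms = 1)),
               "degenerate")
})

test_that("time budget conserves the 24 h day and splits phases 14/10", {
  hyp <- hypnogram(rep("WAKE", 21600))
  tb <- time_budget(hyp, start_clock = "00:00", lights_on = "06:00")
  expect_equal(sum(tb$seconds), 86400)
  expect_equal(tb$seconds[tb$phase == "light" & tb$state == "WAKE"], 14 * 3600)
  expect_equal(tb$seconds[tb$phase == "dark" & tb$state == "WAKE"], 10 * 3600)
  expect_equal(sum(tb$seconds[tb$state == "REM"]), 0)
  expect_error(time_budget(hypnogram(rep("WAKE", 100))), "24 h")
  # phase totals are exact regardless of composition
  set.seed(33)
  hyp2 <- hypnogram(sample(c("WAKE", "NREM", "REM"), 21600, replace = TRUE))
  tb2 <- time_budget(hyp2)
  expect_equal(sum(tb2$seconds[tb2$phase == "light"]), 14 * 3600)
  expect_equal(sum(tb2$seconds[tb2$phase == "dark"]), 10 * 3600)
})

test_that("agreement metrics reproduce the printed formulas and handle edge cases", {
  # TP=8 FP=2 FN=2 TN=88 built directly
  a <- c(rep("REM", 10), rep("NREM", 90))
  b <- c(rep("REM", 8), "NREM", "NREM", rep("REM", 2), rep("NREM", 88))
  m <- agreement_metrics(a, b, "REM")
  expect_equal(unname(m$counts), c(8, 2, 2, 88))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 0.96)

  ident <- agreement_metrics(a, a, "REM")
  expect_equal(ident$f1, 1)
  expect_equal(ident$accuracy, 1)

  # state absent from both: precision/recall undefined (NA + reason), accuracy 1
  none <- agreement_metrics(rep("WAKE", 50), rep("WAKE", 50), "REM")
  expect_true(is.na(none$precision) && is.na(none$recall))
  expect_gt(length(none$undefined), 0)
  expect_equal(none$accuracy, 1)
  expect_error(agreement_metrics(a, b[-1], "REM"), "equal length")
})

test_that("agreement metrics match a brute-force confusion oracle on random label pairs", {
  set.seed(37)
  for (i in 1:200) {
    n <- sample(10:80, 1)
    a <- sample(c("WAKE", "NREM", "REM"), n, replace = TRUE)
    b <- sample(c("WAKE", "NREM", "REM"), n, replace = TRUE)
    s <- sample(c("WAKE", "NREM", "REM"), 1)
    expect_identical(agreement_metrics(a, b, s)$counts,
                     oracle_confusion(a, b, s))
  }
})

test_that("artifact epochs are excluded from confusion counts", {
  a <- c("REM", "ARTIFACT", "NREM", "REM")
  b <- c("REM", "REM", "ARTIFACT", "REM")
  m <- agreement_metrics(a, b, "REM")
  expect_equal(sum(m$counts), 2)           # only epochs scored by both
})

test_that("REM-deficit effect from classified hypnograms is within 15% of the ground-truth effect", {
  # 24 h days at a coarse sampling rate (features need only <= 30 Hz);
  # 2 animals per group, same animals scored both ways
  rem_min <- function(hyp) {
    tb <- time_budget(hyp)
    tb$seconds[tb$phase == "light" & tb$state == "REM"] / 60
  }
  truth_rem <- hat_rem <- list(wt = numeric(2), mut = numeric(2))
  for (g in c("wt", "mut")) {
    for (i in 1:2) {
      cfg <- sim_config(sampling_rate = 100, duration_h = 24,
                        protein_level = if (g == "wt") 1 else 0,
                        seed = 4000 + i + 100 * (g == "mut"))
      sim <- simulate_recording(cfg)
      feats <- extract_epoch_features(sim$recording)
      hyp_hat <- classify_epochs(feats)
      truth_rem[[g]][i] <- rem_min(sim$hypnogram)
      hat_rem[[g]][i] <- rem_min(hyp_hat)
    }
  }
  eff_truth <- mean(truth_rem$mut) - mean(truth_rem$wt)
  eff_hat <- mean(hat_rem$mut) - mean(hat_rem$wt)
  expect_lt(eff_truth, 0)
  expect_lt(abs(eff_hat - eff_truth), 0.15 * abs(eff_truth))
})
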