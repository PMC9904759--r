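#' Sleep staging, time budgets, and scorer agreement
#'
#' A transparent stand-in for CNN-based automated scorers: per-epoch
#' spectral/EMG features feed a 3-component Gaussian model whose most
#' probable state path is decoded under a transition matrix that forbids
#' direct WAKE -> REM transitions (REM is entered only through NREM). The
#' downstream time-budget and agreement computations are independent of how
#' the hypnogram was produced, so externally scored hypnograms (CSV) drop
#' in unchanged.
#'
#' @name sleep
NULL

#' Per-epoch features for sleep staging
#'
#' For each complete 4 s epoch: EEG delta (1--4 Hz) power, theta (6--9 Hz)
#' power, their ratio, broadband 1--30 Hz power (all averaged over EEG
#' channels, raw periodogram), and EMG RMS. The trailing partial epoch is
#' dropped.
#'
#' @param recording A preprocessed \code{psg_recording} containing an "EMG"
#'   channel.
#' @param epoch_s Epoch length, seconds.
#' @return Data frame, one row per epoch: \code{delta}, \code{theta},
#'   \code{theta_delta}, \code{broadband}, \code{emg_rms}.
#' @export
extract_epoch_features <- function(recording, epoch_s = 4) {
  fs <- recording$sampling_rate
  spe <- as.integer(round(epoch_s * fs))
  n <- n_samples(recording)
  n_ep <- n %/% spe
  if (n_ep < 1) stop("recording shorter than one epoch")

  eeg_idx <- eeg_channels(recording)
  emg_idx <- which(recording$channel_labels == "EMG")
  if (length(emg_idx) == 0) stop("no EMG channel in recording")

  freqs <- (seq_len(spe %/% 2 + 1L) - 1) * fs / spe
  in_delta <- freqs >= 1 & freqs <= 4
  in_theta <- freqs >= 6 & freqs <= 9
  in_broad <- freqs >= 1 & freqs <= 30

  delta <- theta <- broad <- numeric(n_ep)
  for (ch in eeg_idx) {
    m <- matrix(recording$signals[[ch]][seq_len(n_ep * spe)], nrow = spe)
    pw <- Mod(stats::mvfft(m)[seq_len(spe %/% 2 + 1L), , drop = FALSE])^2
    delta <- delta + colSums(pw[in_delta, , drop = FALSE])
    theta <- theta + colSums(pw[in_theta, , drop = FALSE])
    broad <- broad + colSums(pw[in_broad, , drop = FALSE])
  }
  delta <- delta / length(eeg_idx)
  theta <- theta / length(eeg_idx)
  broad <- broad / length(eeg_idx)
  memg <- matrix(recording$signals[[emg_idx]][seq_len(n_ep * spe)], nrow = spe)
  emg_rms <- sqrt(colMeans(memg^2))

  data.frame(delta = delta, theta = theta,
             theta_delta = theta / pmax(delta, .Machine$double.eps),
             broadband = broad, emg_rms = emg_rms)
}

feature_matrix <- function(features) {
  cbind(log(pmax(features$emg_rms, 1e-12)),
        log(pmax(features$theta_delta, 1e-12)),
        log(pmax(features$delta, 1e-12)))
}

#' Train the Gaussian sleep-scoring model from labelled epochs
#'
#' Fits one diagonal-covariance Gaussian per state on (log EMG RMS,
#' log theta/delta, log delta) and estimates the state transition matrix
#' from the label sequence, forcing the WAKE -> REM entry to zero.
#'
#' @param features Epoch feature table from
#'   \code{\link{extract_epoch_features}}.
#' @param labels Character vector of true labels (WAKE/NREM/REM), same
#'   length.
#' @return A \code{sleep_model} list: per-state means, sds, transition
#'   matrix, initial distribution.
#' @export
fit_sleep_model <- function(features, labels) {
  stopifnot(nrow(features) == length(labels))
  X <- feature_matrix(features)
  states <- c("WAKE", "NREM", "REM")
  mu <- sd_ <- matrix(NA_real_, 3, ncol(X), dimnames = list(states, NULL))
  for (s in states) {
    sel <- labels == s
    if (sum(sel) < 2) stop("need at least 2 epochs of state ", s, " to train")
    mu[s, ] <- colMeans(X[sel, , drop = FALSE])
    sd_[s, ] <- pmax(apply(X[sel, , drop = FALSE], 2, stats::sd), 1e-3)
  }
  trans <- matrix(0.5, 3, 3, dimnames = list(states, states))
  from <- labels[-length(labels)]; to <- labels[-1]
  for (a in states) for (b in states)
    trans[a, b] <- sum(from == a & to == b) + 0.5
  trans["WAKE", "REM"] <- 0
  trans <- trans / rowSums(trans)
  structure(list(mu = mu, sd = sd_, trans = trans,
                 init = rep(1 / 3, 3)), class = "sleep_model")
}

# unsupervised: kmeans init + EM on diagonal Gaussians, components mapped to
# states by physiology (highest EMG -> WAKE; of the rest, higher theta/delta
# -> REM)
fit_sleep_model_unsupervised <- function(features, n_iter = 25) {
  X <- feature_matrix(features)
  if (all(apply(X, 2, stats::sd) < 1e-9))
    stop("degenerate features: all epochs identical")
  Z <- scale(X)
  km <- stats::kmeans(Z, centers = 3, nstart = 10, iter.max = 50)
  resp <- matrix(0, nrow(X), 3)
  resp[cbind(seq_len(nrow(X)), km$cluster)] <- 1
  for (it in seq_len(n_iter)) {
    w <- colSums(resp) / nrow(X)
    mu <- t(vapply(1:3, function(k)
      colSums(X * resp[, k]) / sum(resp[, k]), numeric(ncol(X))))
    sd_ <- t(vapply(1:3, function(k) {
      v <- colSums(resp[, k] * sweep(X, 2, mu[k, ])^2) / sum(resp[, k])
      pmax(sqrt(v), 1e-3)
    }, numeric(ncol(X))))
    logd <- vapply(1:3, function(k)
      rowSums(stats::dnorm(X, mean = rep(mu[k, ], each = nrow(X)),
                           sd = rep(sd_[k, ], each = nrow(X)), log = TRUE)) +
        log(w[k]), numeric(nrow(X)))
    m <- apply(logd, 1, max)
    resp <- exp(logd - m)
    resp <- resp / rowSums(resp)
  }
  # map components to states
  wake_k <- which.max(mu[, 1])                 # highest EMG
  rest <- setdiff(1:3, wake_k)
  rem_k <- rest[which.max(mu[rest, 2])]        # higher theta/delta
  nrem_k <- setdiff(rest, rem_k)
  ord <- c(wake_k, nrem_k, rem_k)
  states <- c("WAKE", "NREM", "REM")
  mu <- mu[ord, , drop = FALSE]; sd_ <- sd_[ord, , drop = FALSE]
  rownames(mu) <- rownames(sd_) <- states
  trans <- matrix(c(0.96, 0.04, 0,
                    0.03, 0.94, 0.03,
                    0.05, 0.05, 0.90), 3, 3, byrow = TRUE,
                  dimnames = list(states, states))
  structure(list(mu = mu, sd = sd_, trans = trans, init = rep(1 / 3, 3)),
            class = "sleep_model")
}

# log-space Viterbi over the 3 states
viterbi_decode <- function(loglik, trans, init) {
  n <- nrow(loglik); k <- ncol(loglik)
  lt <- log(trans)
  delta <- matrix(-Inf, n, k)
  back <- matrix(0L, n, k)
  delta[1, ] <- log(init) + loglik[1, ]
  for (t in 2:n) {
    for (j in seq_len(k)) {
      cand <- delta[t - 1, ] + lt[, j]
      back[t, j] <- which.max(cand)
      delta[t, j] <- cand[back[t, j]] + loglik[t, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

#' Classify epochs into WAKE/NREM/REM
#'
#' Emission log-likelihoods from the per-state Gaussians are decoded with
#' the most probable path (Viterbi) under the model's transition matrix, in
#' which WAKE -> REM has probability zero. With no model supplied, a
#' 3-component Gaussian mixture is fitted to the features by EM and its
#' components are mapped to states by physiology (highest EMG tone = WAKE,
#' then higher theta/delta = REM); this self-calibrating route assumes the
#' recording actually contains all three states.
#'
#' @param features Epoch feature table.
#' @param model Optional \code{sleep_model} from
#'   \code{\link{fit_sleep_model}}.
#' @return A \code{hypnogram} (4 s epochs).
#' @export
classify_epochs <- function(features, model = NULL) {
  if (is.null(model)) model <- fit_sleep_model_unsupervised(features)
  X <- feature_matrix(features)
  states <- rownames(model$mu)
  loglik <- vapply(seq_along(states), function(k)
    rowSums(stats::dnorm(X, mean = rep(model$mu[k, ], each = nrow(X)),
                         sd = rep(model$sd[k, ], each = nrow(X)), log = TRUE)),
    numeric(nrow(X)))
  path <- viterbi_decode(loglik, model$trans, model$init)
  hypnogram(states[path], epoch_s = 4)
}

#' Sleep time budget by light/dark phase
#'
#' Cumulative seconds per state per phase over the scored span. Phases are
#' resolved from clock time: an epoch is "light" if its start falls within
#' \code{light_hours} hours after \code{lights_on}.
#'
#' @param hyp A \code{hypnogram} spanning at least 24 h.
#' @param start_clock Clock "HH:MM" of the first epoch.
#' @param lights_on Lights-on clock "HH:MM".
#' @param light_hours Light phase length, hours.
#' @param require_24h Error if the hypnogram spans less than 24 h.
#' @return Data frame: \code{phase}, \code{state}, \code{seconds}.
#' @export
time_budget <- function(hyp, start_clock = "00:00", lights_on = "06:00",
                        light_hours = 14, require_24h = TRUE) {
  span_s <- length(hyp$labels) * hyp$epoch_s
  if (require_24h && span_s < 24 * 3600 - 1e-9)
    stop("hypnogram spans ", round(span_s / 3600, 2), " h; 24 h required")
  phases <- epoch_phases(length(hyp$labels), hyp$epoch_s, start_clock,
                         lights_on, light_hours)
  out <- expand.grid(phase = c("light", "dark"),
                     state = HYPNOGRAM_STATES,
                     stringsAsFactors = FALSE)
  out$seconds <- mapply(function(ph, st)
    sum(phases == ph & hyp$labels == st) * hyp$epoch_s,
    out$phase, out$state)
  out
}

#' Pairwise scorer-agreement metrics for one state
#'
#' One-vs-rest confusion counts for the named state, with
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2*precision*recall/(precision+recall), and
#' accuracy = (TP+TN)/(TP+TN+FP+FN). Epochs labelled ARTIFACT by either
#' scorer are excluded. Metrics with zero denominators are returned as NA
#' with a reason, never silently 0.
#'
#' @param labels_a,labels_b Hypnograms (or label vectors) of equal length;
#'   \code{labels_a} is the reference.
#' @param state State to score one-vs-rest.
#' @return List: \code{counts} (TP/FP/FN/TN), \code{precision},
#'   \code{recall}, \code{f1}, \code{accuracy}, \code{undefined} (character
#'   reasons, possibly empty).
#' @export
agreement_metrics <- function(labels_a, labels_b, state = "REM") {
  a <- if (inherits(labels_a, "hypnogram")) labels_a$labels else as.character(labels_a)
  b <- if (inherits(labels_b, "hypnogram")) labels_b$labels else as.character(labels_b)
  if (length(a) != length(b)) stop("label sequences must have equal length")
  keep <- a != "ARTIFACT" & b != "ARTIFACT"
  a <- a[keep]; b <- b[keep]
  tp <- sum(a == state & b == state)
  fp <- sum(a != state & b == state)
  fn <- sum(a == state & b != state)
  tn <- sum(a != state & b != state)
  undefined <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision: no positive predictions"); NA_real_ }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall: state absent from reference"); NA_real_ }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else { undefined <- c(undefined, "f1: undefined"); NA_real_ }
  accuracy <- if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn) else {
    undefined <- c(undefined, "accuracy: no scored epochs"); NA_real_ }
  list(counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
       precision = precision, recall = recall, f1 = f1, accuracy = accuracy,
       undefined = undefined)
}
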