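#' Minimal European Data Format (EDF) input/output
#'
#' Plain EDF (not EDF+): fixed-layout ASCII header followed by 16-bit
#' little-endian samples in data records. Annotations are deliberately kept
#' out of the signal file and carried in sidecar CSVs, so the on-disk
#' contract is bit-exact and simple. Physical range defaults to +/-2000
#' microvolts; samples outside the range are clipped at quantization.
#'
#' @name edf_io
NULL

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' @param recording A \code{psg_recording}. The sampling rate must yield an
#'   integer number of samples per 1 s data record.
#' @param path Output path.
#' @param physical_range Symmetric physical amplitude range in signal units;
#'   the 16-bit quantization grid spans \code{[-physical_range, physical_range]}.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(recording, path, physical_range = 2000) {
  stopifnot(inherits(recording, "psg_recording"))
  fs <- recording$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- length(recording$signals)
  if (ns == 0) stop("recording has no channels")
  n <- n_samples(recording)
  n_rec <- n %/% fs
  if (n_rec * fs != n)
    stop("recording length must be a whole number of 1 s data records")
  if (n_rec < 1) stop("recording shorter than one data record")

  dmin <- -32768L; dmax <- 32767L
  pmin <- -physical_range; pmax <- physical_range
  gain <- (dmax - dmin) / (pmax - pmin)

  con <- file(path, "wb")
  on.exit(close(con))
  st <- recording$start_time
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad(format(st, "%d.%m.%y"), 8),
    edf_pad(format(st, "%H.%M.%S"), 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  per_sig <- paste0(
    paste(vapply(recording$channel_labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_pad(pmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(pmax, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, per_sig), con, eos = NULL, useBytes = TRUE)

  # digitize all channels once, then interleave by record
  dig <- lapply(recording$signals, function(x) {
    d <- round((pmin(pmax(x, pmin), pmax) - pmin) * gain) + dmin
    as.integer(pmin(pmax(d, dmin), dmax))
  })
  blk <- matrix(0L, nrow = fs * ns, ncol = n_rec)
  for (s in seq_len(ns)) {
    rows <- (s - 1L) * fs + seq_len(fs)
    blk[rows, ] <- matrix(dig[[s]], nrow = fs, ncol = n_rec)
  }
  writeBin(as.integer(blk), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @return A \code{psg_recording} in physical units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  version <- rd_str(8)
  if (version != "0") stop("malformed EDF header: bad version field")
  rd_str(80); rd_str(80)                       # patient / recording ids
  startdate <- rd_str(8); starttime <- rd_str(8)
  hdr_bytes <- suppressWarnings(as.integer(rd_str(8)))
  rd_str(44)
  n_rec <- suppressWarnings(as.integer(rd_str(8)))
  rec_dur <- suppressWarnings(as.numeric(rd_str(8)))
  ns <- suppressWarnings(as.integer(rd_str(4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1)
    stop("malformed EDF header: bad numeric field")

  labels <- vapply(seq_len(ns), function(i) rd_str(16), "")
  for (i in seq_len(ns)) rd_str(80)            # transducer
  for (i in seq_len(ns)) rd_str(8)             # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  for (i in seq_len(ns)) rd_str(80)            # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd_str(8)), 0L)
  for (i in seq_len(ns)) rd_str(32)
  if (length(unique(spr / rec_dur)) != 1)
    stop("channels with differing sampling rates are not supported")

  total <- sum(spr) * n_rec
  raw <- readBin(con, integer(), n = total, size = 2, endian = "little",
                 signed = TRUE)
  if (length(raw) != total) stop("malformed EDF: truncated data section")

  blk <- matrix(raw, nrow = sum(spr), ncol = n_rec)
  offs <- cumsum(c(0L, spr))
  signals <- vector("list", ns)
  for (s in seq_len(ns)) {
    d <- as.numeric(blk[offs[s] + seq_len(spr[s]), , drop = FALSE])
    gain <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
    signals[[s]] <- (d - dmin[s]) * gain + pmin[s]
  }

  dt <- strsplit(startdate, ".", fixed = TRUE)[[1]]
  tm <- strsplit(starttime, ".", fixed = TRUE)[[1]]
  yy <- as.integer(dt[3]); yyyy <- if (yy >= 85) 1900 + yy else 2000 + yy
  start <- as.POSIXct(sprintf("%04d-%s-%s %s:%s:%s",
                              yyyy, dt[2], dt[1], tm[1], tm[2], tm[3]),
                      tz = "UTC")
  psg_recording(signals, sampling_rate = spr[1] / rec_dur,
                channel_labels = labels, start_time = start)
}
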