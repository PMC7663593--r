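STANDARD_BLOCKS <- c("RS1", "MIST_TRAIN", "MIST_TASK", "RELAX", "RS2")
STANDARD_1020 <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3", "C4",
                   "Cz", "P3", "P4", "Pz", "T3", "T4", "T5", "T6",
                   "O1", "O2", "A1", "A2")

#' Load a recorded session from disk
#'
#' Reads an EDF+C file with block annotations or a long-format CSV
#' (`time_s, channel, value_uV, block`) and returns the session with blocks
#' ordered RS1, MIST_TRAIN, MIST_TASK, RELAX, RS2. A missing block is a
#' format error; channel labels outside the 10-20 nomenclature are retained
#' with a warning.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param sampling_rate Required for CSV input when the file does not allow
#'   rate inference from time stamps (default: inferred).
#' @return An [eeg_session()].
#' @export
load_session <- function(path, format = c("auto", "edf", "csv"),
                         sampling_rate = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "edf"
  if (format == "edf") {
    raw <- read_edf(path)
    ann <- raw$annotations
    missing <- setdiff(STANDARD_BLOCKS, ann$label)
    if (length(missing) > 0)
      stop_rg("missing block annotation(s): %s", paste(missing, collapse = ", "))
    ann <- ann[match(STANDARD_BLOCKS, ann$label), ]
    fs <- raw$sampling_rate
    blocks <- lapply(seq_len(nrow(ann)), function(i) {
      i0 <- round(ann$onset[i] * fs)
      len <- round(ann$duration[i] * fs)
      raw$data[, (i0 + 1L):(i0 + len), drop = FALSE]
    })
    names(blocks) <- ann$label
    labels <- raw$channel_labels
    group <- raw$group
    subject_id <- raw$subject_id
  } else {
    dt <- data.table::fread(path, showProgress = FALSE)
    need <- c("time_s", "channel", "value_uV", "block")
    if (!all(need %in% names(dt)))
      stop_rg("CSV must have columns %s", paste(need, collapse = ", "))
    missing <- setdiff(STANDARD_BLOCKS, unique(dt$block))
    if (length(missing) > 0)
      stop_rg("missing block annotation(s): %s", paste(missing, collapse = ", "))
    labels <- unique(dt$channel)
    ts <- sort(unique(dt$time_s[dt$channel == labels[1]]))
    fs <- sampling_rate %||% round(1 / stats::median(diff(ts)))
    blocks <- lapply(STANDARD_BLOCKS, function(bl) {
      sub <- dt[dt$block == bl, ]
      m <- do.call(rbind, lapply(labels, function(chn) {
        s <- sub[sub$channel == chn, ]
        s$value_uV[order(s$time_s)]
      }))
      rownames(m) <- labels
      m
    })
    names(blocks) <- STANDARD_BLOCKS
    subject_id <- sub("\\.[a-zA-Z]+$", "", basename(path))
    group <- NA_character_
  }
  unknown <- setdiff(labels, STANDARD_1020)
  if (length(unknown) > 0)
    warning(sprintf("unknown channel label(s) retained: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  eeg_session(subject_id = subject_id, group = group, sampling_rate = fs,
              channel_labels = labels, blocks = blocks)
}

#' Write a session as a long-format CSV
#'
#' Columns `time_s` (session-relative), `channel`, `value_uV`, `block`.
#'
#' @param session An [eeg_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path) {
  fs <- session$sampling_rate
  pos <- 0
  pieces <- vector("list", length(session$blocks))
  for (i in seq_along(session$blocks)) {
    bl <- names(session$blocks)[i]
    m <- session$blocks[[i]]
    nt <- ncol(m)
    pieces[[i]] <- data.table::data.table(
      time_s = rep((pos + seq_len(nt) - 1) / fs, each = nrow(m)),
      channel = rep(session$channel_labels, times = nt),
      value_uV = as.vector(m),
      block = bl)
    pos <- pos + nt
  }
  data.table::fwrite(data.table::rbindlist(pieces), path)
  invisible(path)
}

#' Select the central minute of a resting-state block
#'
#' @param block Channels-by-samples matrix.
#' @param rate Sampling rate in Hz.
#' @return Channels-by-samples matrix of exactly `60 * rate` samples
#'   centered on the block midpoint (0-based half-open sample convention:
#'   a 120 s block at 250 Hz yields samples `[7500, 22500)`).
#' @export
select_central_minute <- function(block, rate) {
  n <- ncol(block)
  n60 <- round(60 * rate)
  if (n < n60) stop_rg("block shorter than 60 s (%.1f s)", n / rate)
  if (n == n60) return(block)
  start <- floor((n - n60) / 2)             # 0-based
  block[, (start + 1L):(start + n60), drop = FALSE]
}

#' Concatenate protocol blocks into the analysis signal
#'
#' Assembles the analysis window in order RS1-central-minute, MIST_TRAIN,
#' MIST_TASK, RELAX, RS2-central-minute, and records the block boundary map
#' (0-based half-open sample ranges). The standard protocol yields a 16-min
#' signal (`16 * 60 * rate` samples).
#'
#' @param session An [eeg_session()] with all five standard blocks.
#' @return An object of class `analysis_signal`: `data` (channels x
#'   samples, uV), `sampling_rate`, `boundaries` (block -> c(start, end)),
#'   plus subject metadata.
#' @export
concatenate_blocks <- function(session) {
  missing <- setdiff(STANDARD_BLOCKS, names(session$blocks))
  if (length(missing) > 0)
    stop_rg("missing block(s): %s", paste(missing, collapse = ", "))
  fs <- session$sampling_rate
  parts <- list(
    RS1 = select_central_minute(session$blocks$RS1, fs),
    MIST_TRAIN = session$blocks$MIST_TRAIN,
    MIST_TASK = session$blocks$MIST_TASK,
    RELAX = session$blocks$RELAX,
    RS2 = select_central_minute(session$blocks$RS2, fs))
  lens <- vapply(parts, ncol, integer(1))
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  boundaries <- Map(function(s, e) c(s, e), starts, ends)
  names(boundaries) <- names(parts)
  structure(list(data = do.call(cbind, parts),
                 sampling_rate = fs,
                 boundaries = boundaries,
                 subject_id = session$subject_id,
                 group = session$group,
                 channel_labels = session$channel_labels),
            class = "analysis_signal")
}

#' @export
print.analysis_signal <- function(x, ...) {
  cat(sprintf("Analysis signal %s: %d channels x %d samples (%.1f min at %g Hz)\n",
              x$subject_id %||% "?", nrow(x$data), ncol(x$data),
              ncol(x$data) / x$sampling_rate / 60, x$sampling_rate))
  invisible(x)
}

apply_zero_phase <- function(signal, b, a) {
  if (inherits(signal, "analysis_signal")) {
    signal$data <- t(apply(signal$data, 1, function(ch) zero_phase_filter(b, a, ch)))
    signal
  } else if (is.matrix(signal)) {
    t(apply(signal, 1, function(ch) zero_phase_filter(b, a, ch)))
  } else {
    zero_phase_filter(b, a, signal)
  }
}

#' Zero-phase Butterworth band-pass filter
#'
#' Second-order (prototype) Butterworth band-pass applied forward and
#' backward per channel, giving zero net phase shift and an effective
#' fourth-order magnitude response. Length-preserving.
#'
#' @param signal An `analysis_signal`, channels-by-samples matrix, or
#'   numeric vector.
#' @param low,high Band edges in Hz (default 1-50).
#' @param order Prototype filter order before the forward-backward pass
#'   (default 2).
#' @param rate Sampling rate in Hz; taken from the `analysis_signal` if
#'   not given.
#' @return Filtered signal of the same shape and class.
#' @export
bandpass_filter <- function(signal, low = 1, high = 50, order = 2, rate = NULL) {
  rate <- rate %||% if (inherits(signal, "analysis_signal")) signal$sampling_rate else
    stop_rg("rate is required for matrix/vector input")
  if (high >= rate / 2)
    stop_rg("band-pass high edge (%g Hz) must be below the Nyquist frequency (%g Hz)",
            high, rate / 2)
  if (low <= 0 || low >= high) stop_rg("need 0 < low < high")
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  apply_zero_phase(signal, bf$b, bf$a)
}

#' Zero-phase 50 Hz notch filter
#'
#' Narrow IIR notch (biquad, quality factor `q`) applied forward-backward
#' per channel to remove power-line coupling.
#'
#' @inheritParams bandpass_filter
#' @param freq Notch frequency in Hz (default 50).
#' @param q Quality factor (center frequency / -3 dB bandwidth; default 30).
#' @return Filtered signal of the same shape and class.
#' @export
notch_filter <- function(signal, freq = 50, q = 30, rate = NULL) {
  rate <- rate %||% if (inherits(signal, "analysis_signal")) signal$sampling_rate else
    stop_rg("rate is required for matrix/vector input")
  if (freq >= rate / 2)
    stop_rg("notch frequency (%g Hz) must be below the Nyquist frequency (%g Hz)",
            freq, rate / 2)
  w0 <- 2 * pi * freq / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  apply_zero_phase(signal, b, a)
}
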