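# Minimal EDF+C I/O (16-bit European Data Format with one annotation
# channel carrying block-onset markers). Only the subset needed for
# session round-trips is implemented: continuous recordings, one-second
# data records, integer sampling rates.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop_rg("EDF header field too long: '%s'", x)
  formatC(x, width = -width)
}

EDF_PHYS_RANGE <- c(-400, 400)  # uV; generous for EEG plus transients

#' Write an EEG session as an EDF+C file
#'
#' The five protocol blocks are concatenated into one continuous recording
#' and marked with one annotation per block (onset + duration + label).
#' Samples are quantized to 16 bits over a +/-400 uV physical range.
#'
#' @param session An [eeg_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_edf <- function(session, path) {
  fs <- session$sampling_rate
  if (fs != round(fs))
    stop_rg("EDF writer requires an integer sampling rate (got %g)", fs)
  fs <- as.integer(fs)
  data <- do.call(cbind, session$blocks)     # channels x samples
  n_ch <- nrow(data)
  n <- ncol(data)
  if (n %% fs != 0)
    stop_rg("total sample count must be a whole number of seconds")
  n_rec <- n %/% fs
  durs <- vapply(session$blocks, ncol, integer(1)) / fs
  onsets <- cumsum(c(0, durs))[seq_along(durs)]

  pmin_ <- EDF_PHYS_RANGE[1]; pmax_ <- EDF_PHYS_RANGE[2]
  dmin <- -32768L; dmax <- 32767L
  dig <- round((pmin(pmax(data, pmin_), pmax_) - pmin_) /
                 (pmax_ - pmin_) * (dmax - dmin)) + dmin
  storage.mode(dig) <- "integer"

  ann_samples <- 60L  # 120 bytes of annotation payload per record
  ns <- n_ch + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(edf_pad(s, w)), con)
  wr("0", 8)
  wr(sprintf("X X X %s", session$subject_id), 80)
  wr(sprintf("Startdate 01-JAN-2000 X X X group=%s", session$group), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr("EDF+C", 44)
  wr(n_rec, 8)
  wr("1", 8)          # record duration, seconds
  wr(ns, 4)
  labels <- c(session$channel_labels, "EDF Annotations")
  for (lb in labels) wr(if (lb == "EDF Annotations") lb else paste("EEG", lb), 16)
  for (i in seq_len(ns)) wr("", 80)                        # transducer
  for (i in seq_len(ns)) wr(if (i <= n_ch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) pmin_ else -1, 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) pmax_ else 1, 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                        # prefilter
  for (i in seq_len(ns)) wr(if (i <= n_ch) fs else ann_samples, 8)
  for (i in seq_len(ns)) wr("", 32)

  # a time-stamped annotation list: text terminated by an ASCII NUL
  tal <- function(onset, duration = NULL, label = NULL) {
    out <- paste0("+", format(onset, trim = TRUE, scientific = FALSE))
    if (!is.null(duration))
      out <- paste0(out, "\x15", format(duration, trim = TRUE, scientific = FALSE))
    out <- paste0(out, "\x14", if (!is.null(label)) paste0(label, "\x14") else "\x14")
    c(charToRaw(out), as.raw(0))
  }
  block_tals <- do.call(c, mapply(tal, onsets, durs, names(session$blocks),
                                  SIMPLIFY = FALSE))
  for (r in seq_len(n_rec) - 1L) {
    seg <- dig[, (r * fs + 1L):((r + 1L) * fs), drop = FALSE]
    writeBin(as.integer(t(seg)), con, size = 2L, endian = "little")
    ann <- c(tal(r), if (r == 0L) block_tals)
    if (length(ann) > 2L * ann_samples) stop_rg("annotation payload overflow")
    writeBin(c(ann, raw(2L * ann_samples - length(ann))), con)
  }
  invisible(path)
}

#' Read an EDF+C file written by [write_session_edf()]
#'
#' @param path EDF file path.
#' @return A list with `sampling_rate`, `channel_labels`, `data`
#'   (channels x samples matrix, uV), `annotations` (data.frame with
#'   `onset`, `duration`, `label`), `subject_id`, `group`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_rg("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  version <- rd(8)
  patient <- rd(80)
  recording <- rd(80)
  rd(8); rd(8)                          # start date / time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); dims <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)

  ann_idx <- which(labels == "EDF Annotations")
  sig_idx <- setdiff(seq_len(ns), ann_idx)
  data <- matrix(0, nrow = length(sig_idx), ncol = n_rec * spr[sig_idx[1]])
  ann_raw <- raw(0)
  for (r in seq_len(n_rec) - 1L) {
    for (i in seq_len(ns)) {
      if (i %in% ann_idx) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2L * spr[i]))
      } else {
        v <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                     endian = "little")
        row <- match(i, sig_idx)
        data[row, (r * spr[i] + 1L):((r + 1L) * spr[i])] <-
          pmin_[i] + (v - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      }
    }
  }
  rownames(data) <- labels_clean <- sub("^EEG ", "", labels[sig_idx])

  ann <- parse_edf_annotations(ann_raw)
  subject_id <- utils::tail(strsplit(patient, " ")[[1]], 1)
  group <- sub(".*group=([a-z]+).*", "\\1", recording)
  if (identical(group, recording)) group <- NA_character_
  list(sampling_rate = spr[sig_idx[1]] / rec_dur,
       channel_labels = labels_clean,
       data = data, annotations = ann,
       subject_id = subject_id, group = group)
}

parse_edf_annotations <- function(ann_raw) {
  txt <- rawToChar(ann_raw[ann_raw != as.raw(0)] )
  tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
  onset <- numeric(0); duration <- numeric(0); label <- character(0)
  # after splitting on the record-timestamp terminator, annotation TALs look
  # like "+<onset>\x15<duration>\x14<label>\x14+<next record stamp>"
  for (piece in tals) {
    m <- gregexpr("\\+?(-?[0-9.]+)\x15([0-9.]+)\x14([^\x14+]+)", piece)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      sub <- substring(piece, m[k], m[k] + attr(m, "match.length")[k] - 1L)
      parts <- strsplit(sub, "[\x14\x15]")[[1]]
      onset <- c(onset, as.numeric(sub("^\\+", "", parts[1])))
      duration <- c(duration, as.numeric(parts[2]))
      label <- c(label, parts[3])
    }
  }
  data.frame(onset = onset, duration = duration, label = label,
             stringsAsFactors = FALSE)
}
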