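#' Default EEG frequency band table
#'
#' The five classical bands used for band power estimation. Bins are
#' assigned to bands by `low <= f < high`, so shared edges (4, 8, 13,
#' 25 Hz) are not double-counted.
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz): delta
#'   1-4, theta 4-8, alpha 8-13, beta 13-25, gamma 25-45.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 4, 8, 13, 25),
             high = c(4, 8, 13, 25, 45),
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("name", "low", "high") %in% names(bands)))
  if (any(bands$low <= 0) || any(bands$low >= bands$high) || any(bands$high > 50))
    stop_rg("bands must satisfy 0 < low < high <= 50 Hz")
  if (anyDuplicated(bands$name)) stop_rg("band names must be unique")
  bands
}

#' Cut the analysis signal into non-overlapping epochs
#'
#' Epoch i covers samples `[i * L, (i+1) * L)` with `L = epoch_s * rate`
#' (0-based half-open). A trailing remainder shorter than one epoch is
#' dropped with a warning. The standard 16-min signal yields 480 epochs of
#' 2 s.
#'
#' @param signal An `analysis_signal` (or channels-by-samples matrix with
#'   `rate` supplied).
#' @param epoch_s Epoch length in seconds (default 2).
#' @param rate Sampling rate for matrix input.
#' @return An object of class `epoch_matrix`: `data` (epochs x channels x
#'   samples array), all-false `mask`, `rejected` flags, epoch-unit block
#'   boundaries, and metadata.
#' @export
epoch_signal <- function(signal, epoch_s = 2, rate = NULL) {
  if (inherits(signal, "analysis_signal")) {
    m <- signal$data
    rate <- signal$sampling_rate
    boundaries <- signal$boundaries
    meta <- signal[c("subject_id", "group", "channel_labels")]
  } else {
    m <- signal
    if (is.null(rate)) stop_rg("rate is required for matrix input")
    boundaries <- NULL
    meta <- list(subject_id = NULL, group = NULL, channel_labels = rownames(m))
  }
  spe <- round(epoch_s * rate)
  n <- ncol(m)
  n_epochs <- n %/% spe
  if (n_epochs < 1L) stop_rg("signal shorter than one epoch (%g s)", epoch_s)
  rem <- n - n_epochs * spe
  if (rem > 0)
    warning(sprintf("dropping trailing %.3g s (not a whole epoch)", rem / rate),
            call. = FALSE)
  n_ch <- nrow(m)
  used <- m[, seq_len(n_epochs * spe), drop = FALSE]
  arr <- aperm(array(used, dim = c(n_ch, spe, n_epochs)), c(3, 1, 2))
  b_ep <- if (!is.null(boundaries))
    lapply(boundaries, function(se) as.integer(pmin(se %/% spe, n_epochs))) else NULL
  structure(list(data = arr,
                 mask = matrix(FALSE, n_epochs, n_ch),
                 rejected = rep(FALSE, n_epochs),
                 sampling_rate = rate, epoch_s = epoch_s,
                 boundaries_epochs = b_ep,
                 channel_labels = meta$channel_labels,
                 subject_id = meta$subject_id, group = meta$group,
                 normalized = FALSE),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch matrix: %d epochs x %d channels x %d samples (%g s at %g Hz)\n",
              d[1], d[2], d[3], x$epoch_s, x$sampling_rate))
  cat(sprintf("  masked epoch-channels: %d; rejected epochs: %d\n",
              sum(x$mask), sum(x$rejected)))
  invisible(x)
}

#' Zero epoch-channels exceeding an amplitude threshold
#'
#' Any epoch-channel whose peak absolute amplitude exceeds `threshold`
#' (evaluated on the raw uV scale, before normalization) is set to all
#' zeros and masked. An epoch with every channel masked is flagged
#' rejected and yields missing band powers downstream.
#'
#' @param epochs An `epoch_matrix`.
#' @param threshold Amplitude threshold in uV (default 100).
#' @return The updated `epoch_matrix`, with `masked_fraction` (fraction of
#'   epoch-channel cells zeroed) and `rejected_fraction` fields.
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  if (threshold <= 0) stop_rg("threshold must be > 0")
  peak <- apply(abs(epochs$data), c(1, 2), max)
  mask <- peak > threshold
  if (any(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      epochs$data[idx[r, 1], idx[r, 2], ] <- 0
  }
  epochs$mask <- epochs$mask | mask
  epochs$rejected <- apply(epochs$mask, 1, all)
  epochs$masked_fraction <- mean(epochs$mask)
  epochs$rejected_fraction <- mean(epochs$rejected)
  epochs
}

#' Detrend and z-score each epoch-channel
#'
#' Removes the per-epoch-channel linear trend (least squares) and scales
#' the residual to zero mean and unit variance, making the signal
#' dimensionless. Masked epoch-channels stay exactly zero; an unmasked
#' zero-variance epoch-channel is left at zeros and reported.
#'
#' @param epochs An `epoch_matrix`.
#' @return The normalized `epoch_matrix`.
#' @export
detrend_zscore <- function(epochs) {
  d <- dim(epochs$data)
  spe <- d[3]
  m <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = spe)  # spe x (epochs*channels)
  rms0 <- sqrt(colMeans(m^2))
  tc <- seq_len(spe) - (spe + 1) / 2
  denom <- sum(tc^2)
  means <- colMeans(m)
  slopes <- as.vector(crossprod(tc, m)) / denom
  m <- m - rep(means, each = spe) - outer(tc, slopes)
  sds <- sqrt(colSums(m^2) / (spe - 1))
  masked <- as.vector(epochs$mask)
  # degenerate: residual variance at (or numerically indistinguishable
  # from) zero relative to the epoch's own scale, e.g. a pure linear ramp
  degenerate <- !masked & sds <= 1e-8 * pmax(rms0, .Machine$double.eps)
  if (any(degenerate))
    message(sprintf("%d zero-variance epoch-channel(s) left at zero", sum(degenerate)))
  sds[sds == 0] <- 1
  m <- m / rep(sds, each = spe)
  m[, masked | degenerate] <- 0
  epochs$data <- aperm(array(m, dim = c(spe, d[1], d[2])), c(2, 3, 1))
  epochs$normalized <- TRUE
  epochs
}

#' Per-epoch, channel-averaged band power
#'
#' For each epoch-channel the power spectral density of the 2-s segment is
#' estimated with a raw rectangular-window periodogram; band power is the
#' sum of PSD bins with `low <= f < high`, and the per-epoch value is the
#' mean over unmasked channels. Rejected epochs yield `NA`. With the
#' one-sided periodogram normalized so its total equals the mean square of
#' the segment, band powers are additive and Parseval-consistent.
#'
#' @param epochs An `epoch_matrix`.
#' @param bands Band table as from [default_bands()].
#' @return An object of class `band_power_series`: `power` (epochs x bands
#'   matrix), `bands`, `rejected`, metadata.
#' @export
band_power <- function(epochs, bands = default_bands()) {
  bands <- validate_bands(bands)
  rate <- epochs$sampling_rate
  if (any(bands$high > rate / 2))
    stop_rg("band above the Nyquist frequency (%g Hz)", rate / 2)
  d <- dim(epochs$data)
  n_ep <- d[1]; n_ch <- d[2]; spe <- d[3]
  m <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = spe)
  ft <- stats::mvfft(m)
  nyq_bin <- spe %/% 2
  p2 <- Mod(ft)^2 / spe^2                       # two-sided
  # one-sided: double everything but DC (and Nyquist for even lengths)
  ps <- p2[seq_len(nyq_bin + 1L), , drop = FALSE]
  if (nyq_bin >= 1) {
    dbl <- 2:(nyq_bin + 1L)
    if (spe %% 2 == 0) dbl <- dbl[-length(dbl)]
    ps[dbl, ] <- 2 * ps[dbl, ]
  }
  freqs <- (0:nyq_bin) * rate / spe
  power <- matrix(NA_real_, n_ep, nrow(bands),
                  dimnames = list(NULL, bands$name))
  w <- !epochs$mask                             # unmasked channels
  n_unmasked <- rowSums(w)
  for (bi in seq_len(nrow(bands))) {
    sel <- freqs >= bands$low[bi] & freqs < bands$high[bi]
    bp_cell <- matrix(colSums(ps[sel, , drop = FALSE]), n_ep, n_ch)
    bp_cell[!w] <- 0
    tot <- rowSums(bp_cell)
    power[, bi] <- ifelse(n_unmasked > 0, tot / n_unmasked, NA_real_)
  }
  structure(list(power = power, bands = bands,
                 rejected = epochs$rejected,
                 epoch_s = epochs$epoch_s,
                 boundaries_epochs = epochs$boundaries_epochs,
                 subject_id = epochs$subject_id, group = epochs$group),
            class = "band_power_series")
}

#' Relative gamma per epoch
#'
#' The stress biomarker: the ratio of gamma-band power to the summed
#' alpha- and theta-band power, computed per epoch. Rejected epochs and
#' zero denominators yield missing values (reported, not errors).
#'
#' @param bp A `band_power_series` containing alpha, theta and gamma.
#' @return An object of class `rg_series` with `values`, epoch-unit block
#'   boundaries, polarity slot and smoothing/resampling state.
#' @export
relative_gamma <- function(bp) {
  need <- c("alpha", "theta", "gamma")
  if (!all(need %in% colnames(bp$power)))
    stop_rg("band power series must contain %s", paste(need, collapse = ", "))
  denom <- bp$power[, "alpha"] + bp$power[, "theta"]
  rg <- bp$power[, "gamma"] / denom
  rg[!is.na(denom) & denom == 0] <- NA_real_
  n_missing <- sum(is.na(rg))
  if (n_missing > 0)
    message(sprintf("%d epoch(s) with missing relative gamma", n_missing))
  rg_series(values = unname(rg),
            boundaries_epochs = bp$boundaries_epochs,
            subject_id = bp$subject_id, group = bp$group)
}

#' Relative gamma series container
#'
#' @param values Numeric per-epoch relative gamma values.
#' @param boundaries_epochs Block boundary map in epoch units (0-based
#'   half-open), or NULL.
#' @param subject_id,group Optional metadata.
#' @param polarity Responder polarity (`"direct"`, `"inverse"` or NA).
#' @param smoothing_span,resampled_length Processing state.
#' @return An object of class `rg_series`.
#' @export
rg_series <- function(values, boundaries_epochs = NULL, subject_id = NULL,
                      group = NULL, polarity = NA_character_,
                      smoothing_span = NA_integer_,
                      resampled_length = NA_integer_) {
  structure(list(values = values, boundaries_epochs = boundaries_epochs,
                 subject_id = subject_id, group = group, polarity = polarity,
                 smoothing_span = smoothing_span,
                 resampled_length = resampled_length),
            class = "rg_series")
}

#' @export
print.rg_series <- function(x, ...) {
  cat(sprintf("Relative gamma series%s: %d epochs, mean %.3g",
              if (!is.null(x$subject_id)) paste0(" [", x$subject_id, "]") else "",
              length(x$values), mean(x$values, na.rm = TRUE)))
  if (!is.na(x$polarity)) cat(", polarity", x$polarity)
  cat("\n")
  invisible(x)
}

#' Fill missing relative gamma values by linear interpolation
#'
#' Missing epochs (rejected or degenerate denominators) are linearly
#' interpolated from their neighbors; leading/trailing runs take the
#' nearest observed value.
#'
#' @param rg An `rg_series`.
#' @return The `rg_series` without missing values.
#' @export
interpolate_missing <- function(rg) {
  v <- rg$values
  if (anyNA(v)) {
    ok <- !is.na(v)
    if (sum(ok) < 2) stop_rg("fewer than two observed values to interpolate from")
    message(sprintf("interpolating %d missing value(s)", sum(!ok)))
    rg$values <- stats::approx(which(ok), v[ok], xout = seq_along(v),
                               rule = 2)$y
  }
  rg
}
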