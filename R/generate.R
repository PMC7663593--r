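#' Generate one synthetic EEG session
#'
#' Each channel is a sum of five band-limited Gaussian noise components
#' (white noise filtered into each classical band with a 4th-order
#' Butterworth band-pass), whose amplitudes follow the latent stress
#' trajectory: for direct responders the gamma component is scaled by
#' `(1 + depth * s(t))` and the alpha and theta components by
#' `(1 - depth * s(t))`; the dependence is sign-flipped for inverse
#' responders. Optional 50 Hz line coupling and Poisson-placed 200 ms
#' raised-cosine transients of 150-300 uV (on 1-3 random channels) are
#' added on top. The output is bit-reproducible given the subject seed.
#'
#' @param protocol A [protocol_spec()].
#' @param subject A [subject_spec()].
#' @param profile A [stress_profile()]; defaults to the standard trajectory
#'   over `protocol`.
#' @param bands Band definition table (see [default_bands()]) used for the
#'   noise components.
#' @return An object of class `eeg_session`: subject metadata plus a named
#'   list of channels-by-samples matrices (uV), one per protocol block.
#' @export
generate_session <- function(protocol, subject,
                             profile = stress_profile(protocol),
                             bands = default_bands()) {
  fs <- protocol$sampling_rate
  gamma_high <- bands$high[bands$name == "gamma"]
  if (fs < 2 * gamma_high)
    stop_rg("sampling rate %g Hz cannot represent the gamma band (need >= %g Hz)",
            fs, 2 * gamma_high)
  ch <- protocol$channel_labels
  n_ch <- length(ch)
  total_s <- protocol_duration(protocol)
  n <- round(total_s * fs)
  tt <- (seq_len(n) - 1) / fs
  s <- stress_profile_eval(profile, tt)
  depth <- subject$modulation_depth
  dir_sign <- if (subject$responder_polarity == "direct") 1 else -1

  # Band components are white noise filtered forward-backward with a
  # 4th-order Butterworth band-pass (|H|^4 magnitude: sharp enough that a
  # quiet band is not swamped by a loud neighbor's skirts). Component
  # powers are calibrated jointly: the in-band gain matrix A (power each
  # component delivers into each band) is solved against the per-band
  # variance targets asd^2 * bandwidth, so every band's in-band variance is
  # on target in expectation despite cross-band leakage.
  active <- which(vapply(bands$name, function(b)
    !is.null(subject$band_amplitudes[[b]]) && subject$band_amplitudes[[b]] > 0,
    logical(1)))
  filters <- lapply(active, function(bi)
    signal::butter(4, c(bands$low[bi], bands$high[bi]) / (fs / 2), type = "pass"))
  A <- outer(seq_along(active), seq_along(active),
             Vectorize(function(i, j) {
               bi <- active[i]
               filter_variance_gain(filters[[j]]$b, filters[[j]]$a,
                                    low = bands$low[bi], high = bands$high[bi],
                                    fs = fs, power = 4)
             }))
  targets <- vapply(active, function(bi)
    subject$band_amplitudes[[bands$name[bi]]]^2 * (bands$high[bi] - bands$low[bi]),
    numeric(1))
  c2 <- solve(A, targets)
  if (any(c2 < 0)) stop_rg("band calibration failed (non-physical amplitudes)")

  data <- with_seed(subject$seed, {
    x <- matrix(0, nrow = n, ncol = n_ch)
    for (i in seq_along(active)) {
      bname <- bands$name[active[i]]
      bf <- filters[[i]]
      scale <- sqrt(c2[i])
      gain <- if (bname == "gamma") {
        1 + dir_sign * depth * s
      } else if (bname %in% c("alpha", "theta")) {
        1 - dir_sign * depth * s
      } else {
        1
      }
      for (c_i in seq_len(n_ch)) {
        comp <- zero_phase_filter(bf$b, bf$a, stats::rnorm(n)) * scale
        x[, c_i] <- x[, c_i] + comp * gain
      }
    }
    if (subject$line_noise_uv > 0) {
      for (c_i in seq_len(n_ch)) {
        phase <- stats::runif(1, 0, 2 * pi)
        x[, c_i] <- x[, c_i] + subject$line_noise_uv * sin(2 * pi * 50 * tt + phase)
      }
    }
    if (subject$artifact_rate > 0) {
      n_ev <- stats::rpois(1, subject$artifact_rate * total_s / 60)
      pulse_len <- max(2L, round(0.2 * fs))
      pulse <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = pulse_len)))
      for (ev in seq_len(n_ev)) {
        start <- sample.int(n - pulse_len, 1)
        chans <- sample.int(n_ch, sample(1:3, 1))
        amp <- stats::runif(1, 150, 300) * sample(c(-1, 1), 1)
        idx <- start:(start + pulse_len - 1L)
        x[idx, chans] <- x[idx, chans] + amp * pulse
      }
    }
    x
  })

  # split continuous recording into annotated blocks (channels x samples)
  blocks <- list()
  pos <- 0L
  for (bl in names(protocol$durations)) {
    len <- round(protocol$durations[[bl]] * fs)
    blocks[[bl]] <- t(data[(pos + 1L):(pos + len), , drop = FALSE])
    rownames(blocks[[bl]]) <- ch
    pos <- pos + len
  }
  eeg_session(subject_id = subject$subject_id, group = subject$group,
              sampling_rate = fs, channel_labels = ch, blocks = blocks)
}

#' EEG session container
#'
#' @param subject_id Subject identifier.
#' @param group Group label.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Channel labels.
#' @param blocks Named list of channels-by-samples matrices (uV), in
#'   protocol order.
#' @return An object of class `eeg_session`.
#' @export
eeg_session <- function(subject_id, group, sampling_rate, channel_labels, blocks) {
  ncs <- vapply(blocks, nrow, integer(1))
  if (length(unique(ncs)) != 1L)
    stop_rg("all blocks must share the same channel count")
  structure(list(subject_id = subject_id, group = group,
                 sampling_rate = sampling_rate,
                 channel_labels = channel_labels, blocks = blocks),
            class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("EEG session %s (%s), %g Hz, %d channels\n",
              x$subject_id, x$group, x$sampling_rate, length(x$channel_labels)))
  for (bl in names(x$blocks))
    cat(sprintf("  %-11s %6.1f s\n", bl, ncol(x$blocks[[bl]]) / x$sampling_rate))
  invisible(x)
}

#' Generate self-perceived stress level (SPSL) survey responses
#'
#' Integer 1-5 responses at the four survey instants (T1 before RS1, T2
#' after the MIST, T3 during relaxation, T4 before RS2), drawn as rounded,
#' clipped Gaussians around phase means. The means must encode the
#' protocol's stress arc: T2 above T1 and T3 below T2.
#'
#' @param cohort List of [subject_spec()] objects.
#' @param means Length-4 vector of phase means at T1..T4, each in `[1, 5]`.
#' @param sd Response noise standard deviation (>= 0).
#' @param seed Seed for the draws.
#' @return A data.frame with columns `subject_id`, `group`, `T1`..`T4`
#'   (integers in 1..5).
#' @export
generate_spsl <- function(cohort, means = c(2, 4, 2.5, 2), sd = 0.7, seed = 1L) {
  if (length(means) != 4) stop_rg("means must have length 4 (T1..T4)")
  if (any(means < 1 | means > 5)) stop_rg("phase means must lie within [1, 5]")
  if (!(means[2] > means[1]) || !(means[3] < means[2]))
    stop_rg("means must satisfy T2 > T1 and T3 < T2 (the protocol's stress arc)")
  if (sd < 0) stop_rg("noise sd must be >= 0")
  n <- length(cohort)
  resp <- with_seed(seed, {
    m <- matrix(stats::rnorm(4L * n, mean = rep(means, each = n), sd = sd),
                nrow = n)
    pmin(pmax(round(m), 1L), 5L)
  })
  out <- data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
                    group = vapply(cohort, `[[`, "", "group"),
                    T1 = as.integer(resp[, 1]), T2 = as.integer(resp[, 2]),
                    T3 = as.integer(resp[, 3]), T4 = as.integer(resp[, 4]),
                    stringsAsFactors = FALSE)
  out
}

#' Write a complete fixture set to disk
#'
#' Generates each subject's session and writes one signal file per subject
#' (EDF with block annotations, or long CSV), a surveys CSV
#' (`subject_id, group, T1..T4`) and a ground-truth JSON echoing each
#' subject's specification (polarity, depth, seed, ...).
#'
#' @param cohort List of [subject_spec()] objects (may be empty).
#' @param out_dir Writable output directory (created if absent).
#' @param protocol A [protocol_spec()].
#' @param profile A [stress_profile()].
#' @param format `"edf"` or `"csv"` for the signal files.
#' @param spsl_means,spsl_sd,spsl_seed Passed to [generate_spsl()].
#' @return Character vector of all written paths (the manifest); empty for
#'   an empty cohort.
#' @export
write_fixture_set <- function(cohort, out_dir,
                              protocol = protocol_spec(),
                              profile = stress_profile(protocol),
                              format = c("edf", "csv"),
                              spsl_means = c(2, 4, 2.5, 2), spsl_sd = 0.7,
                              spsl_seed = 1L) {
  format <- match.arg(format)
  if (length(cohort) == 0L) return(character(0))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop_rg("cannot create directory '%s'", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop_rg("directory '%s' is not writable", out_dir)
  paths <- character(0)
  for (subj in cohort) {
    sess <- generate_session(protocol, subj, profile)
    p <- file.path(out_dir, paste0(subj$subject_id, ".", format))
    if (format == "edf") write_session_edf(sess, p) else write_session_csv(sess, p)
    paths <- c(paths, p)
  }
  surveys <- generate_spsl(cohort, means = spsl_means, sd = spsl_sd, seed = spsl_seed)
  sp <- file.path(out_dir, "surveys.csv")
  utils::write.csv(surveys, sp, row.names = FALSE)
  truth <- lapply(cohort, function(s) unclass(s))
  names(truth) <- vapply(cohort, `[[`, "", "subject_id")
  tp <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  c(paths, sp, tp)
}
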