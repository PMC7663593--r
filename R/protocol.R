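#' Protocol specification for a stress-relaxation EEG session
#'
#' Describes the block structure of the experiment: an eyes-closed resting
#' state (RS1), stress induction with the Montreal Imaging Stress Task split
#' into a training and a task block, a relaxation block, and a closing
#' resting state (RS2), together with the sampling rate and electrode
#' montage.
#'
#' @param durations Named numeric vector of block durations in seconds, in
#'   protocol order. Defaults to the standard 18-minute session:
#'   RS1 120 s, MIST_TRAIN 180 s, MIST_TASK 360 s, RELAX 300 s, RS2 120 s.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param channel_labels Electrode labels (10-20 system); default the
#'   eight-channel frontal/central/occipital montage.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(durations = c(RS1 = 120, MIST_TRAIN = 180, MIST_TASK = 360,
                                        RELAX = 300, RS2 = 120),
                          sampling_rate = 250,
                          channel_labels = c("Fp1", "Fp2", "F7", "F8",
                                             "Fz", "Cz", "O1", "O2")) {
  if (is.null(names(durations)) || any(!nzchar(names(durations))))
    stop_rg("protocol durations must be a named vector")
  if (any(durations <= 0)) stop_rg("all block durations must be strictly positive")
  rs <- grep("^RS", names(durations), value = TRUE)
  if (any(durations[rs] < 60))
    stop_rg("resting-state blocks must last at least 60 s (a central minute must exist)")
  if (length(channel_labels) == 0L || anyDuplicated(channel_labels))
    stop_rg("channel labels must be non-empty and unique")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_rg("sampling_rate must be a positive number")
  structure(list(durations = durations,
                 sampling_rate = sampling_rate,
                 channel_labels = channel_labels),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("EEG protocol:", paste(names(x$durations), collapse = " | "), "\n")
  cat("  durations (s):", paste(x$durations, collapse = ", "),
      sprintf(" (total %.1f min)\n", sum(x$durations) / 60))
  cat("  sampling rate:", x$sampling_rate, "Hz;",
      length(x$channel_labels), "channels\n")
  invisible(x)
}

# Cumulative block onsets in seconds (named, same order as durations).
block_onsets <- function(protocol) {
  on <- cumsum(c(0, protocol$durations))
  stats::setNames(on[-length(on)], names(protocol$durations))
}

protocol_duration <- function(protocol) sum(protocol$durations)

#' Latent stress trajectory over the session
#'
#' A deterministic, piecewise-smooth stress level s(t) in [0, 1] that the
#' synthetic generator modulates band amplitudes with. Rest is zero stress;
#' stress rises exponentially during the MIST (onset time constant
#' `tau_onset`), peaks (exactly 1) at the end of the task block, decays
#' during relaxation toward a slightly negative asymptote (time constant
#' `tau_relax`, undershoot `relax_undershoot`, clipped at 0) so the level
#' crosses zero in the third minute of the relaxation block, then rebounds
#' gently (a mild re-engagement, e.g. boredom) and fades through the final
#' resting state.
#'
#' @param protocol A [protocol_spec()].
#' @param tau_onset Stress onset time constant in seconds (default 30).
#' @param tau_relax Relaxation decay time constant in seconds (default 60).
#' @param relax_undershoot Magnitude of the (clipped) negative decay
#'   asymptote; controls when the level reaches zero (default 0.12).
#' @param rebound_level Asymptotic level of the late-relaxation rebound
#'   (default 0.12).
#' @param tau_rebound Rebound time constant in seconds (default 60).
#' @param train_level Asymptotic stress level during MIST training
#'   (default 0.4).
#' @param tau_rs2 Decay time constant during the closing resting state
#'   (default 120).
#' @return An object of class `stress_profile`.
#' @export
stress_profile <- function(protocol = protocol_spec(),
                           tau_onset = 30, tau_relax = 60,
                           relax_undershoot = 0.12,
                           rebound_level = 0.12, tau_rebound = 60,
                           train_level = 0.4, tau_rs2 = 120) {
  stopifnot(tau_onset > 0, tau_relax > 0, tau_rebound > 0, tau_rs2 > 0,
            relax_undershoot >= 0, rebound_level >= 0 && rebound_level < 1,
            train_level >= 0 && train_level < 1)
  structure(list(protocol = protocol,
                 tau_onset = tau_onset, tau_relax = tau_relax,
                 relax_undershoot = relax_undershoot,
                 rebound_level = rebound_level, tau_rebound = tau_rebound,
                 train_level = train_level, tau_rs2 = tau_rs2),
            class = "stress_profile")
}

#' Evaluate the stress trajectory
#'
#' @param profile A [stress_profile()].
#' @param t Time(s) in seconds from the start of the session; must lie in
#'   `[0, session duration]`.
#' @return Stress level(s) in `[0, 1]`; vectorized over `t`.
#' @export
stress_profile_eval <- function(profile, t) {
  pr <- profile$protocol
  total <- protocol_duration(pr)
  if (any(t < 0 | t > total))
    stop_rg("t outside the session: must be in [0, %g] s", total)
  on <- block_onsets(pr)
  dur <- pr$durations
  need <- c("RS1", "MIST_TRAIN", "MIST_TASK", "RELAX", "RS2")
  if (!all(need %in% names(dur)))
    stop_rg("stress profile requires the standard blocks: %s",
            paste(setdiff(need, names(dur)), collapse = ", "))

  # Raw (unnormalized) piecewise trajectory; continuous at every boundary.
  s_train_end <- profile$train_level *
    (1 - exp(-dur[["MIST_TRAIN"]] / profile$tau_onset))
  peak_raw <- s_train_end + (1 - s_train_end) *
    (1 - exp(-dur[["MIST_TASK"]] / profile$tau_onset))

  q <- profile$relax_undershoot
  # time (s into RELAX) at which the clipped decay reaches zero
  t_zero <- if (q > 0) profile$tau_relax * log((1 + q) / q) else Inf
  relax_end_dt <- dur[["RELAX"]]
  relax_val <- function(dt) {
    decay <- pmax((1 + q) * exp(-dt / profile$tau_relax) - q, 0)
    reb <- ifelse(dt > t_zero,
                  profile$rebound_level *
                    (1 - exp(-(dt - t_zero) / profile$tau_rebound)),
                  0)
    decay + reb
  }
  s_relax_end <- relax_val(relax_end_dt)

  s <- numeric(length(t))
  in_block <- function(lab) t >= on[[lab]] & t <= on[[lab]] + dur[[lab]]
  # later blocks overwrite boundary points; value is continuous there anyway
  idx <- in_block("RS1"); s[idx] <- 0
  idx <- in_block("MIST_TRAIN")
  s[idx] <- profile$train_level * (1 - exp(-(t[idx] - on[["MIST_TRAIN"]]) / profile$tau_onset))
  idx <- in_block("MIST_TASK")
  s[idx] <- s_train_end + (1 - s_train_end) *
    (1 - exp(-(t[idx] - on[["MIST_TASK"]]) / profile$tau_onset))
  s <- s / peak_raw  # end of MIST task is exactly 1
  idx <- in_block("RELAX")
  s[idx] <- relax_val(t[idx] - on[["RELAX"]])
  idx <- in_block("RS2")
  s[idx] <- s_relax_end * exp(-(t[idx] - on[["RS2"]]) / profile$tau_rs2)
  pmin(pmax(s, 0), 1)
}
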