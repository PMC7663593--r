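#' Centered moving-average smoothing
#'
#' Smooths the relative gamma series with an odd, centered moving-average
#' window (default 19 points: the center sample plus the 9 preceding and 9
#' following epochs, i.e. 18 s of smear at 2 s per epoch). Near the edges
#' the window shrinks symmetrically so the output keeps the input length.
#'
#' @param rg An `rg_series` or numeric vector.
#' @param span Odd window length >= 1 (default 19).
#' @return Smoothed series of the same class and length.
#' @export
smooth_moving_average <- function(rg, span = 19) {
  if (!is_count(span) || span < 1 || span %% 2 == 0)
    stop_rg("span must be an odd positive integer (e.g. 19 or 21)")
  x <- if (inherits(rg, "rg_series")) rg$values else rg
  if (anyNA(x)) stop_rg("series contains missing values; interpolate first")
  n <- length(x)
  h <- pmin((span - 1) / 2, seq_len(n) - 1, n - seq_len(n))
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  out <- (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
  if (inherits(rg, "rg_series")) {
    rg$values <- out
    rg$smoothing_span <- as.integer(span)
    rg
  } else out
}

#' Resample a series to a fixed length
#'
#' Linear interpolation onto `target` equally spaced points spanning the
#' original index range, so all subjects' series become comparable
#' (default 480 points = 16 min at 2 s per epoch). Endpoints are
#' preserved; affine inputs are reproduced exactly.
#'
#' @param rg An `rg_series` or numeric vector of length >= 2.
#' @param target Output length >= 2 (default 480).
#' @return Resampled series of the same class, length exactly `target`.
#' @export
resample_to_length <- function(rg, target = 480) {
  if (!is_count(target) || target < 2) stop_rg("target length must be >= 2")
  x <- if (inherits(rg, "rg_series")) rg$values else rg
  n <- length(x)
  if (n < 2) stop_rg("need at least 2 points to resample")
  out <- stats::approx(seq_len(n), x, xout = seq(1, n, length.out = target))$y
  if (inherits(rg, "rg_series")) {
    scale <- (target) / n
    if (!is.null(rg$boundaries_epochs))
      rg$boundaries_epochs <- lapply(rg$boundaries_epochs,
                                     function(se) as.integer(round(se * scale)))
    rg$values <- out
    rg$resampled_length <- as.integer(target)
    rg
  } else out
}

#' Classify responder polarity
#'
#' Automated surrogate for visual inspection: the decision statistic is
#' the mean relative gamma over the MIST task minus the mean over the
#' relaxation block. Non-negative values are classified direct (relative
#' gamma rises with stress), negative values inverse; ties go to direct.
#'
#' @param rg An `rg_series` with a block boundary map.
#' @param boundaries Optional boundary map overriding the one in `rg`
#'   (block -> c(start, end), 0-based half-open epoch indices).
#' @return An object of class `responder_label` with `polarity` and
#'   `statistic`.
#' @export
classify_responder <- function(rg, boundaries = rg$boundaries_epochs) {
  if (is.null(boundaries) || !all(c("MIST_TASK", "RELAX") %in% names(boundaries)))
    stop_rg("boundary map with MIST_TASK and RELAX is required")
  seg <- function(lab) {
    se <- boundaries[[lab]]
    if (se[2] <= se[1]) stop_rg("empty phase: %s", lab)
    rg$values[(se[1] + 1L):se[2]]
  }
  delta <- mean(seg("MIST_TASK"), na.rm = TRUE) - mean(seg("RELAX"), na.rm = TRUE)
  structure(list(polarity = if (delta >= 0) "direct" else "inverse",
                 statistic = delta),
            class = "responder_label")
}

#' @export
print.responder_label <- function(x, ...) {
  cat(sprintf("responder polarity: %s (MIST - Relax contrast %.4g)\n",
              x$polarity, x$statistic))
  invisible(x)
}

#' Orient a series by responder polarity
#'
#' Inverse responders' series are reflected about their own mean
#' (`x -> 2 * mean(x) - x`), which preserves location and scale so direct
#' and inverted series can be averaged together; direct series pass
#' through unchanged. Applying the orientation twice restores the input.
#'
#' @param rg An `rg_series`.
#' @param label A `responder_label` (or the polarity string).
#' @return The oriented `rg_series` with its polarity recorded.
#' @export
orient_rg <- function(rg, label) {
  polarity <- if (inherits(label, "responder_label")) label$polarity else label
  if (!polarity %in% c("direct", "inverse"))
    stop_rg("polarity must be 'direct' or 'inverse'")
  if (polarity == "inverse")
    rg$values <- 2 * mean(rg$values) - rg$values
  rg$polarity <- polarity
  rg
}

#' Grand average and standard error of the mean across subjects
#'
#' @param series List of `rg_series` (or numeric vectors) of equal length.
#' @param group Optional group label.
#' @return An object of class `group_curve`: pointwise `mean`, `sem`
#'   (sd / sqrt(n)), `n` and the label.
#' @export
grand_average_sem <- function(series, group = NULL) {
  vals <- lapply(series, function(s) if (inherits(s, "rg_series")) s$values else s)
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L)
    stop_rg("all series must have the same length (got %s)",
            paste(unique(lens), collapse = ", "))
  n <- length(vals)
  if (n < 2) stop_rg("need at least 2 subjects for a SEM")
  m <- do.call(rbind, vals)
  structure(list(mean = colMeans(m),
                 sem = apply(m, 2, stats::sd) / sqrt(n),
                 n = n, group = group %||% NA_character_),
            class = "group_curve")
}

#' @export
print.group_curve <- function(x, ...) {
  cat(sprintf("Group curve%s: n = %d, %d points, mean RG %.3g (mean SEM %.3g)\n",
              if (!is.na(x$group)) paste0(" [", x$group, "]") else "",
              x$n, length(x$mean), mean(x$mean), mean(x$sem)))
  invisible(x)
}

#' @export
plot.group_curve <- function(x, col = "steelblue", add = FALSE, ...) {
  i <- seq_along(x$mean)
  if (!add) {
    graphics::plot(i, x$mean, type = "n",
                   xlab = "epoch (2 s)", ylab = "relative gamma", ...)
  }
  graphics::polygon(c(i, rev(i)), c(x$mean + x$sem, rev(x$mean - x$sem)),
                    col = grDevices::adjustcolor(col, alpha.f = 0.3), border = NA)
  graphics::lines(i, x$mean, col = col, lwd = 2)
  invisible(x)
}

#' Sixth-degree polynomial fit of a group curve
#'
#' Least-squares polynomial fit (default degree 6) of the mean relative
#' gamma, used to suppress statistical fluctuation before comparing the
#' groups. The abscissa is rescaled to `[-1, 1]` for numerical
#' conditioning; coefficients refer to that scale.
#'
#' @param curve A `group_curve` or numeric vector.
#' @param degree Polynomial degree (default 6).
#' @return An object of class `poly_fit` with `coefficients`, `fitted`
#'   and `degree`.
#' @export
fit_poly6 <- function(curve, degree = 6) {
  y <- if (inherits(curve, "group_curve")) curve$mean else curve
  n <- length(y)
  if (n < degree + 1) stop_rg("need at least %d points for degree %d", degree + 1, degree)
  xs <- seq(-1, 1, length.out = n)
  fit <- stats::lm(y ~ stats::poly(xs, degree, raw = TRUE))
  structure(list(coefficients = unname(stats::coef(fit)),
                 fitted = unname(stats::fitted(fit)),
                 degree = degree),
            class = "poly_fit")
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("Degree-%d polynomial fit (%d points); coefficients on [-1, 1]:\n",
              x$degree, length(x$fitted)))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' @param r Sample Pearson correlation.
#' @param n Number of paired observations (> 3).
#' @param level Confidence level (default 0.95).
#' @return `c(low, high)`: `tanh(atanh(r) +/- z_crit / sqrt(n - 3))`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3) stop_rg("Fisher CI requires n > 3")
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param a,b Numeric vectors of equal length (n >= 4) with nonzero
#'   variance; `group_curve` and `poly_fit` objects are accepted.
#' @param level Confidence level (default 0.95).
#' @return An object of class `correlation_result` with `estimate`,
#'   `ci_low`, `ci_high`, `level`, `n`.
#' @export
pcc_with_ci <- function(a, b, level = 0.95) {
  get_vals <- function(v) {
    if (inherits(v, "group_curve")) v$mean
    else if (inherits(v, "poly_fit")) v$fitted
    else v
  }
  a <- get_vals(a); b <- get_vals(b)
  if (length(a) != length(b)) stop_rg("curves must have equal length")
  n <- length(a)
  if (n < 4) stop_rg("need at least 4 paired points")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop_rg("zero-variance input")
  r <- stats::cor(a, b)
  ci <- fisher_ci(r, n, level)
  structure(list(estimate = r, ci_low = ci[1], ci_high = ci[2],
                 level = level, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (is.na(x$ci_low)) {
    cat(sprintf("PCC = %.3f (n = %d; no CI reported at this n)\n", x$estimate, x$n))
  } else {
    cat(sprintf("PCC = %.3f, %g%% CI [%.3f, %.3f] (n = %d)\n",
                x$estimate, 100 * x$level, x$ci_low, x$ci_high, x$n))
  }
  invisible(x)
}
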