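#' Hypothesis test result container
#'
#' @param method Test name.
#' @param statistic Test statistic.
#' @param p_value P-value in `[0, 1]`.
#' @param alpha Significance level (default 0.05); `significant` is
#'   `p_value < alpha`.
#' @param n Effective sample size used.
#' @param notes Character notes (dropped zeros, ties, approximation used).
#' @return An object of class `test_result`.
#' @export
test_result <- function(method, statistic, p_value, alpha = 0.05, n = NA_integer_,
                        notes = character(0)) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop_rg("p-value outside [0, 1]")
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 alpha = alpha, significant = isTRUE(p_value < alpha),
                 n = n, notes = notes),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s (alpha = %g, n = %s)\n",
              x$method, x$statistic, x$p_value,
              if (x$significant) " *" else "", x$alpha, x$n))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Kolmogorov-Smirnov distance between a sample and a normal with the
# sample's own mean and sd.
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

#' Null distribution of the Lilliefors statistic
#'
#' Monte-Carlo draws of the Lilliefors KS statistic for standard-normal
#' samples of size `n` (the statistic is location-scale invariant, so
#' standard normals suffice). Computed once per `n`, it can be reused
#' across many tests.
#'
#' @param n Sample size.
#' @param reps Number of Monte-Carlo draws (default 10000).
#' @param seed Seed making the draws reproducible.
#' @return Numeric vector of `reps` null statistics.
#' @export
lilliefors_null_stats <- function(n, reps = 10000, seed = NULL) {
  with_seed(seed, vapply(seq_len(reps),
                         function(i) lilliefors_stat(stats::rnorm(n)),
                         numeric(1)))
}

#' Lilliefors normality test with a Monte-Carlo null
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with
#' estimated mean and standard deviation; the p-value is computed from a
#' seeded Monte-Carlo null distribution (at least 10000 draws by default),
#' making it reproducible bit-for-bit given the seed.
#'
#' @param x Numeric sample (n >= 4, nonconstant).
#' @param mc_reps Monte-Carlo draws for the null (default 10000).
#' @param seed Seed for the null draws.
#' @param null_stats Optional precomputed null statistics from
#'   [lilliefors_null_stats()] (must match `length(x)`).
#' @param alpha Significance level.
#' @return A [test_result()].
#' @export
lilliefors_test <- function(x, mc_reps = 10000, seed = NULL, null_stats = NULL,
                            alpha = 0.05) {
  n <- length(x)
  if (n < 4) stop_rg("Lilliefors test requires n >= 4")
  if (stats::sd(x) == 0) stop_rg("constant sample: sd is zero")
  d <- lilliefors_stat(x)
  if (is.null(null_stats)) null_stats <- lilliefors_null_stats(n, mc_reps, seed)
  p <- (1 + sum(null_stats >= d)) / (length(null_stats) + 1)
  test_result("Lilliefors (Monte-Carlo)", d, p, alpha = alpha, n = n,
              notes = sprintf("%d null draws", length(null_stats)))
}

# Exact null CDF of the signed-rank statistic for rank vector r (midranks
# allowed): dynamic program over doubled ranks, so all sums are integers.
signed_rank_exact_cdf <- function(r) {
  dr <- as.integer(round(2 * r))
  S <- sum(dr)
  f <- numeric(S + 1L)
  f[1L] <- 1
  for (d in dr) {
    shifted <- c(numeric(d), f[seq_len(S + 1L - d)])
    f <- f + shifted
  }
  f / 2^length(dr)   # P(2V = 0..S)
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired test on the signed ranks of the differences. Zero
#' differences are dropped (Wilcoxon's original rule; the reduction is
#' noted), tied absolute differences receive midranks. For effective
#' n <= `exact_max_n` the null distribution of the rank sum is computed
#' exactly over all sign assignments (midranks included); above that, a
#' normal approximation with tie correction and continuity correction is
#' used. If every difference is zero the test is degenerate and returns
#' p = 1 with a note.
#'
#' @param x,y Paired numeric samples of equal length (n >= 1).
#' @param alpha Significance level (default 0.05).
#' @param exact_max_n Largest effective n for the exact null (default 25).
#' @return A [test_result()] whose statistic is the positive-rank sum V.
#' @export
wilcoxon_signed_rank <- function(x, y, alpha = 0.05, exact_max_n = 25) {
  if (length(x) != length(y)) stop_rg("x and y must have equal length")
  if (length(x) < 1) stop_rg("need at least one pair")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  notes <- if (n_zero > 0) sprintf("%d zero difference(s) dropped", n_zero) else character(0)
  if (n == 0) {
    return(test_result("Wilcoxon signed-rank (exact)", 0, 1, alpha = alpha,
                       n = 0L, notes = c(notes, "all differences zero")))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- anyDuplicated(r) > 0
  if (has_ties) notes <- c(notes, "tied ranks midranked")
  if (n <= exact_max_n) {
    pmf <- signed_rank_exact_cdf(r)
    v2 <- round(2 * v)
    p_le <- sum(pmf[seq_len(v2 + 1L)])
    p_ge <- sum(pmf[(v2 + 1L):length(pmf)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "Wilcoxon signed-rank (normal approximation)"
    notes <- c(notes, "normal approximation with tie correction")
  }
  test_result(method, v, p, alpha = alpha, n = n, notes = notes)
}

#' Summarize SPSL surveys and run the test battery
#'
#' Per-group means and standard deviations of the self-perceived stress
#' level at the four survey instants, within-group Wilcoxon signed-rank
#' tests for the consecutive phase contrasts (T1 vs T2, T2 vs T3, T3 vs
#' T4), between-group tests at each instant (subjects paired positionally,
#' requiring equal group sizes), and a Lilliefors normality check of each
#' comparison's differences (reported; the Wilcoxon test is used for the
#' ordinal survey data regardless). No multiple-testing correction is
#' applied (noted in the output).
#'
#' @param records Data frame with columns `subject_id`, `group` and
#'   integer `T1`..`T4` in 1..5.
#' @param alpha Significance level (default 0.05).
#' @param lilliefors_reps,seed Monte-Carlo settings for the normality
#'   checks.
#' @return An object of class `spsl_summary`: `summary` (group x instant
#'   means/sds), `within` and `between` test tables, `normality` notes.
#' @export
summarize_spsl <- function(records, alpha = 0.05, lilliefors_reps = 2000,
                           seed = 1L) {
  instants <- c("T1", "T2", "T3", "T4")
  need <- c("subject_id", "group", instants)
  if (!all(need %in% names(records)))
    stop_rg("records must have columns %s", paste(need, collapse = ", "))
  vals <- as.matrix(records[, instants])
  if (any(vals != round(vals)) || any(vals < 1 | vals > 5))
    stop_rg("survey responses must be integers in [1, 5]")
  groups <- sort(unique(records$group))
  if (length(groups) != 2)
    stop_rg("exactly two groups are required (got: %s)",
            paste(groups, collapse = ", "))
  by_group <- split(records, records$group)
  if (any(vapply(by_group, nrow, 0L) < 2))
    stop_rg("need at least 2 records per group")

  summary <- do.call(rbind, lapply(groups, function(g) {
    m <- as.matrix(by_group[[g]][, instants])
    data.frame(group = g, instant = instants,
               mean = colMeans(m), sd = apply(m, 2, stats::sd),
               row.names = NULL)
  }))

  gate <- function(d, s) {
    out <- tryCatch(lilliefors_test(d, mc_reps = lilliefors_reps, seed = s)$p_value,
                    error = function(e) NA_real_)
    out
  }
  pairs <- list(c("T1", "T2"), c("T2", "T3"), c("T3", "T4"))
  within <- list()
  k <- 0L
  for (g in groups) for (pr in pairs) {
    k <- k + 1L
    a <- by_group[[g]][[pr[1]]]; b <- by_group[[g]][[pr[2]]]
    tr <- wilcoxon_signed_rank(a, b, alpha = alpha)
    within[[k]] <- data.frame(group = g, comparison = paste(pr, collapse = "-"),
                              statistic = tr$statistic, p_value = tr$p_value,
                              significant = tr$significant, n = tr$n,
                              lilliefors_p = gate(a - b, seed + k),
                              row.names = NULL)
  }
  within <- do.call(rbind, within)

  n1 <- nrow(by_group[[groups[1]]]); n2 <- nrow(by_group[[groups[2]]])
  if (n1 != n2)
    stop_rg("between-group comparison needs equal group sizes (%d vs %d)", n1, n2)
  between <- do.call(rbind, lapply(seq_along(instants), function(i) {
    ti <- instants[i]
    a <- by_group[[groups[1]]][[ti]]; b <- by_group[[groups[2]]][[ti]]
    tr <- wilcoxon_signed_rank(a, b, alpha = alpha)
    data.frame(instant = ti, statistic = tr$statistic, p_value = tr$p_value,
               significant = tr$significant, n = tr$n,
               lilliefors_p = gate(a - b, seed + 100L + i), row.names = NULL)
  }))

  structure(list(summary = summary, within = within, between = between,
                 groups = groups, alpha = alpha,
                 notes = "no multiple-testing correction applied"),
            class = "spsl_summary")
}

#' @export
print.spsl_summary <- function(x, ...) {
  cat("SPSL summary (mean (sd) per instant):\n")
  for (g in x$groups) {
    s <- x$summary[x$summary$group == g, ]
    cat(sprintf("  %-8s %s\n", g,
                paste(sprintf("%s %.2f (%.2f)", s$instant, s$mean, s$sd),
                      collapse = "  ")))
  }
  cat("Within-group phase contrasts (Wilcoxon signed-rank):\n")
  for (g in x$groups) {
    w <- x$within[x$within$group == g, ]
    cat(sprintf("  %-8s %s\n", g,
                paste(sprintf("%s p=%.4f%s", w$comparison, w$p_value,
                              ifelse(w$significant, "*", "")), collapse = "  ")))
  }
  cat("Between-group tests per instant:\n  ")
  cat(paste(sprintf("%s p=%.4f%s", x$between$instant, x$between$p_value,
                    ifelse(x$between$significant, "*", "")), collapse = "  "), "\n")
  cat(" ", x$notes, "\n")
  invisible(x)
}

#' Relative gamma at the survey instants
#'
#' The biomarker value attached to each survey moment: the mean relative
#' gamma over a one-minute window (30 epochs at 2 s) centered on each
#' instant's epoch index, clipped at the series edges (clipping is
#' reported).
#'
#' @param rg An `rg_series` or numeric vector.
#' @param instants Epoch indices (1-based) of the instants (e.g. T1..T4).
#' @param half_window Half window in epochs (default 15, i.e. +/- 30 s).
#' @return Numeric vector of per-instant means.
#' @export
rg_at_instants <- function(rg, instants, half_window = 15) {
  v <- if (inherits(rg, "rg_series")) rg$values else rg
  n <- length(v)
  vapply(instants, function(k) {
    if (k < 1 || k > n) stop_rg("instant %d outside the series (1..%d)", k, n)
    lo <- k - half_window
    hi <- k + half_window - 1
    if (lo < 1 || hi > n) {
      message(sprintf("window for instant %d clipped at the series edge", k))
      lo <- max(1, lo); hi <- min(n, hi)
    }
    mean(v[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

#' Default epoch indices of the survey instants on the standard timeline
#'
#' T1 mid-RS1, T2 at the end of the MIST task, T3 90 s after relaxation
#' onset, T4 at the end of the relaxation block, on the 480-epoch
#' concatenated timeline.
#'
#' @param boundaries Epoch-unit boundary map (block -> c(start, end)).
#' @return Named integer vector T1..T4 (1-based epoch indices).
#' @export
default_instants <- function(boundaries) {
  rs1 <- boundaries$RS1; task <- boundaries$MIST_TASK; rel <- boundaries$RELAX
  c(T1 = as.integer((rs1[1] + rs1[2]) %/% 2 + 1L),
    T2 = as.integer(task[2]),
    T3 = as.integer(rel[1] + 45L + 1L),
    T4 = as.integer(rel[2]))
}

#' Correlate mean SPSL with mean relative gamma over the survey instants
#'
#' Pearson correlation between the four instant means of the
#' self-perceived stress level and of the relative gamma. With only four
#' points no confidence interval is reported.
#'
#' @param spsl_means,rg_means Numeric vectors of equal length (the four
#'   instants) with nonzero variance.
#' @return A `correlation_result` with `ci_low`/`ci_high` set to `NA`.
#' @export
correlate_spsl_rg <- function(spsl_means, rg_means) {
  if (length(spsl_means) != length(rg_means))
    stop_rg("instant means must have equal length")
  if (stats::sd(spsl_means) == 0 || stats::sd(rg_means) == 0)
    stop_rg("zero-variance input")
  structure(list(estimate = stats::cor(spsl_means, rg_means),
                 ci_low = NA_real_, ci_high = NA_real_,
                 level = NA_real_, n = length(spsl_means)),
            class = "correlation_result")
}
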