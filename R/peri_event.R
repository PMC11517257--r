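# Event-aligned analyses: trial-aligned counts in sliding bins, PSTH with
# mean +/- s.e.m. across trials, and bin-wise two-condition comparison with
# the Wilcoxon rank-sum (Mann-Whitney) test at uncorrected alpha.

#' Peri-event analysis configuration
#'
#' The default bin geometry is 150 ms bins slid in 50 ms steps over a
#' window of 5 s on either side of the event. Bin centers form an
#' arithmetic sequence with step `step_ms`; each bin is the half-open
#' interval `[center - bin/2, center + bin/2)` in event-relative time, so a
#' point exactly on a boundary belongs to the bin whose left edge it is.
#'
#' @param window_pre_ms,window_post_ms Window extent before/after the event
#'   (ms, > 0). Defaults 5000.
#' @param bin_ms Bin width in ms; default 150.
#' @param step_ms Slide step in ms (<= `bin_ms`); default 50.
#' @param alpha Per-bin significance level for condition comparison,
#'   uncorrected; default 0.05.
#' @return Object of class `peri_event_config`.
#' @export
peri_event_config <- function(window_pre_ms = 5000, window_post_ms = 5000,
                              bin_ms = 150, step_ms = 50, alpha = 0.05) {
  stopifnot_scalar_num(window_pre_ms, "window_pre_ms", lower = 0,
                       open_lower = TRUE)
  stopifnot_scalar_num(window_post_ms, "window_post_ms", lower = 0,
                       open_lower = TRUE)
  stopifnot_scalar_num(bin_ms, "bin_ms", lower = 0, open_lower = TRUE)
  stopifnot_scalar_num(step_ms, "step_ms", lower = 0, open_lower = TRUE)
  stopifnot_scalar_num(alpha, "alpha", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  if (step_ms > bin_ms)
    validation_error("step_ms must be <= bin_ms (sliding bins)")
  if (window_pre_ms + window_post_ms < bin_ms)
    validation_error("window must cover at least one bin")
  structure(list(window_pre_ms = window_pre_ms,
                 window_post_ms = window_post_ms,
                 bin_ms = bin_ms, step_ms = step_ms, alpha = alpha),
            class = "peri_event_config")
}

#' Bin centers of a peri-event configuration
#' @param cfg A [peri_event_config()].
#' @return Numeric vector of bin centers in event-relative ms.
#' @export
bin_centers <- function(cfg) {
  seq(-cfg$window_pre_ms + cfg$bin_ms / 2,
      cfg$window_post_ms - cfg$bin_ms / 2, by = cfg$step_ms)
}

#' Align a point process on events: trial x bin count matrix
#'
#' For each event (one trial per event) and each sliding bin, counts the
#' points whose event-relative time falls in `[center - bin/2,
#' center + bin/2)`. Trials whose window extends past the recording bounds
#' are kept (partial coverage); use `drop_partial = TRUE` to drop trials
#' whose window is not fully inside `[0, duration_ms]`.
#'
#' @param times_ms Point times (integer ms), e.g. one call type's times or
#'   one unit's spike times.
#' @param events_ms Event times to align on (one trial each).
#' @param cfg A [peri_event_config()].
#' @param duration_ms Recording length, required for `drop_partial`.
#' @param drop_partial Drop trials with partial window coverage (default
#'   `FALSE`: kept, flagged in the `"partial_trials"` attribute).
#' @return Integer matrix `n_trials x n_bins` with bin centers as column
#'   names; attribute `"partial_trials"` flags trials with partial
#'   coverage. Zero events give a 0-row matrix.
#' @export
align_events <- function(times_ms, events_ms, cfg, duration_ms = NULL,
                         drop_partial = FALSE) {
  centers <- bin_centers(cfg)
  half <- cfg$bin_ms / 2
  t <- sort(as.numeric(times_ms))
  partial <- rep(FALSE, length(events_ms))
  if (!is.null(duration_ms))
    partial <- events_ms - cfg$window_pre_ms < 0 |
      events_ms + cfg$window_post_ms > duration_ms
  if (drop_partial) {
    if (is.null(duration_ms))
      validation_error("drop_partial requires duration_ms")
    events_ms <- events_ms[!partial]
    partial <- partial[!partial]
  }
  n_ev <- length(events_ms)
  m <- matrix(0L, n_ev, length(centers),
              dimnames = list(NULL, format(centers, trim = TRUE,
                                           scientific = FALSE)))
  for (i in seq_len(n_ev)) {
    rel <- t - events_ms[i]
    # count rel in [lo, hi): cumulative counts just below each edge
    lo <- centers - half
    hi <- centers + half
    m[i, ] <- findInterval(hi - 1e-9, rel) - findInterval(lo - 1e-9, rel)
  }
  attr(m, "partial_trials") <- partial
  attr(m, "cfg") <- cfg
  m
}

#' Peri-event time histogram: mean rate +/- s.e.m. across trials
#'
#' Converts a trial x bin count matrix into rates (events/s, counts divided
#' by the bin width) and summarizes across trials: mean and standard error
#' of the mean (trial SD / sqrt(n)). With a single trial the s.e.m. is 0 by
#' convention.
#'
#' @param count_matrix Output of [align_events()].
#' @param cfg The [peri_event_config()] used for alignment (defaults to the
#'   one stored on the matrix).
#' @return Object of class `peri_event_result`: `data.frame`-like list with
#'   `bin_centers_ms`, `mean_rate`, `sem`, `n_trials`, `trial_counts`.
#' @export
psth <- function(count_matrix, cfg = attr(count_matrix, "cfg")) {
  if (is.null(cfg)) validation_error("cfg required")
  n <- nrow(count_matrix)
  if (n < 1L) validation_error("psth needs at least one trial")
  rates <- count_matrix / (cfg$bin_ms / 1000)
  mean_rate <- colMeans(rates)
  sem <- if (n > 1L) apply(rates, 2, stats::sd) / sqrt(n) else
    rep(0, ncol(rates))
  structure(list(bin_centers_ms = bin_centers(cfg),
                 mean_rate = unname(mean_rate), sem = unname(sem),
                 n_trials = n, trial_counts = count_matrix, cfg = cfg),
            class = "peri_event_result")
}

#' @export
print.peri_event_result <- function(x, ...) {
  cat("<peri_event_result>", x$n_trials, "trials,",
      length(x$bin_centers_ms), "bins of", x$cfg$bin_ms, "ms (step",
      x$cfg$step_ms, "ms)\n")
  cat(sprintf("  peak rate %.3g ev/s at %g ms\n",
              max(x$mean_rate), x$bin_centers_ms[which.max(x$mean_rate)]))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test, tie-aware
#'
#' Two-sided test of whether two samples come from the same distribution,
#' used bin-wise on per-trial counts. For small samples the p-value is
#' computed by exhaustive permutation of the rank-sum statistic (exact even
#' under ties); for larger samples the tie-corrected normal approximation
#' is used. Degenerate all-equal samples give p = 1 by convention.
#'
#' @param x,y Numeric samples (per-trial counts of one bin).
#' @param method `"auto"` (exact when both groups have <= 10 observations
#'   and the total is <= 20, else normal), `"exact"`, or `"normal"`.
#' @return The two-sided p-value.
#' @export
rank_sum_test <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) validation_error("both samples must be non-empty")
  all_v <- c(x, y)
  if (max(all_v) == min(all_v)) return(1)
  r <- rank(all_v)
  W <- sum(r[seq_len(n1)])
  N <- n1 + n2
  mu <- n1 * (N + 1) / 2
  if (method == "auto")
    method <- if (n1 <= 10L && n2 <= 10L && N <= 20L) "exact" else "normal"
  if (method == "exact") {
    combos <- utils::combn(N, n1)
    stats_all <- colSums(matrix(r[combos], nrow = n1))
    obs_dev <- abs(W - mu)
    return(mean(abs(stats_all - mu) >= obs_dev - 1e-9))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Bin-wise comparison of two conditions
#'
#' Per sliding bin, compares the per-trial counts of the two conditions
#' with the two-sided rank-sum test and marks bins with `p < alpha`.
#' No correction for multiple comparisons across bins is applied by
#' default (the conventional uncorrected p < 0.05 marking of PSTH bins); a
#' Benjamini-Hochberg option is available.
#'
#' @param matrix_a,matrix_b Trial x bin count matrices from
#'   [align_events()] with identical bin geometry; >= 2 trials each.
#' @param cfg The shared [peri_event_config()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param method Passed to [rank_sum_test()].
#' @return Object of class `bin_comparison`: `data.frame` with
#'   `bin_center_ms`, `p_value`, `significant`.
#' @export
compare_conditions <- function(matrix_a, matrix_b,
                               cfg = attr(matrix_a, "cfg"),
                               p_adjust = c("none", "BH"),
                               method = "auto") {
  p_adjust <- match.arg(p_adjust)
  if (is.null(cfg)) validation_error("cfg required")
  if (ncol(matrix_a) != ncol(matrix_b))
    validation_error("count matrices have different bin geometry")
  if (nrow(matrix_a) < 2L || nrow(matrix_b) < 2L)
    validation_error("need >= 2 trials per condition")
  p <- vapply(seq_len(ncol(matrix_a)), function(j)
    rank_sum_test(matrix_a[, j], matrix_b[, j], method = method), numeric(1))
  if (p_adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  out <- data.frame(bin_center_ms = bin_centers(cfg), p_value = p,
                    significant = p < cfg$alpha)
  class(out) <- c("bin_comparison", "data.frame")
  out
}

#' Write a PSTH (optionally with a comparison) as tidy CSV
#'
#' Columns: `bin_center_ms, mean_rate, sem[, p_value, significant]`.
#' @param result A `peri_event_result`.
#' @param path Output path.
#' @param comparison Optional `bin_comparison` on the same geometry.
#' @return `path`, invisibly.
#' @export
write_psth_csv <- function(result, path, comparison = NULL) {
  df <- data.frame(bin_center_ms = result$bin_centers_ms,
                   mean_rate = result$mean_rate, sem = result$sem)
  header <- "bin_center_ms,mean_rate,sem"
  lines <- paste(fmt_num(df$bin_center_ms), fmt_num(df$mean_rate),
                 fmt_num(df$sem), sep = ",")
  if (!is.null(comparison)) {
    if (nrow(comparison) != nrow(df))
      validation_error("comparison does not match the PSTH geometry")
    header <- paste0(header, ",p_value,significant")
    lines <- paste(lines, fmt_num(comparison$p_value),
                   tolower(comparison$significant), sep = ",")
  }
  write_lines_utf8(c(header, lines), path)
}
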