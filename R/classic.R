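#' N1/P1 peak features of a single SEP trace
#'
#' The rat sciatic-nerve SEP consists of a low-amplitude negative
#' deflection (N1) followed by a high-amplitude positive wave (P1).  N1 is
#' located as the minimum inside the N1 search window and P1 as the maximum
#' between N1 and the end of the P1 window; latencies are reported in ms
#' after stimulus onset and the N1-P1 amplitude is the peak-to-trough
#' difference in microvolts.
#'
#' A trace with no SEP morphology (e.g. monotone drift, where the extrema
#' land on the search-window edges, or a P1 not exceeding N1) raises a
#' `morphology_error`; callers processing many channels should catch it per
#' channel (see [sep_features()]).
#'
#' Default windows (N1: 3-15 ms, P1: 10-40 ms) bracket typical rat
#' sciatic-nerve latencies (N1 ~7.5-9.5 ms, P1 ~18.5-21 ms) with margin
#' and are configurable for other protocols.
#'
#' @param trace numeric vector of one channel (microvolts).
#' @param fs sampling rate (Hz).
#' @param stim_onset_index 1-based sample index of the stimulus.
#' @param n1_window_ms,p1_window_ms numeric length-2 search windows in ms
#'   post-stimulus.
#' @return list: `n1_latency_ms`, `p1_latency_ms`, `n1p1_amplitude_uV`,
#'   `n1p1_interval_ms`.
#' @export
detect_n1_p1 <- function(trace, fs, stim_onset_index = 1L,
                         n1_window_ms = c(3, 15), p1_window_ms = c(10, 40)) {
  stopifnot(length(n1_window_ms) == 2L, length(p1_window_ms) == 2L,
            n1_window_ms[1] < n1_window_ms[2],
            p1_window_ms[1] < p1_window_ms[2],
            n1_window_ms[1] < p1_window_ms[2])
  spm <- fs / 1000
  idx <- function(ms) stim_onset_index + as.integer(round(ms * spm))
  T_ <- length(trace)
  n1_rng <- idx(n1_window_ms[1]):min(idx(n1_window_ms[2]), T_)
  if (max(n1_rng) > T_ || min(n1_rng) < 1L)
    stop("N1 window outside the trace")
  n1_i <- n1_rng[which.min(trace[n1_rng])]
  p1_lo <- max(n1_i + 1L, idx(p1_window_ms[1]))
  p1_hi <- min(idx(p1_window_ms[2]), T_)
  if (p1_lo > p1_hi) morphology_stop("P1 window collapses at or before N1")
  p1_rng <- p1_lo:p1_hi
  p1_i <- p1_rng[which.max(trace[p1_rng])]
  # extrema stuck on a search-window edge indicate drift, not SEP peaks
  if (n1_i == min(n1_rng) || n1_i == max(n1_rng))
    morphology_stop("no N1 trough inside the search window")
  if (p1_i == max(p1_rng))
    morphology_stop("no P1 peak inside the search window")
  amp <- trace[p1_i] - trace[n1_i]
  if (p1_i <= n1_i || amp < 0)
    morphology_stop("P1 does not follow and exceed N1")
  n1_ms <- (n1_i - stim_onset_index) / spm
  p1_ms <- (p1_i - stim_onset_index) / spm
  list(n1_latency_ms = n1_ms, p1_latency_ms = p1_ms,
       n1p1_amplitude_uV = amp, n1p1_interval_ms = p1_ms - n1_ms)
}

morphology_stop <- function(msg) {
  e <- simpleError(paste0("morphology error: ", msg))
  class(e) <- c("morphology_error", class(e))
  stop(e)
}

#' N1/P1 features for every channel of a trace set
#'
#' Applies [detect_n1_p1()] per channel; channels without SEP morphology
#' are reported with `NA` features and `ok = FALSE` rather than aborting
#' the run.
#'
#' @param ts a [traceset()].
#' @inheritParams detect_n1_p1
#' @return data.frame: `channel_id`, `n1_latency_ms`, `p1_latency_ms`,
#'   `n1p1_amplitude_uV`, `n1p1_interval_ms`, `ok`.
#' @export
sep_features <- function(ts, n1_window_ms = c(3, 15),
                         p1_window_ms = c(10, 40)) {
  stopifnot(inherits(ts, "traceset"))
  rows <- lapply(seq_len(nrow(ts$data)), function(i) {
    f <- tryCatch(detect_n1_p1(ts$data[i, ], ts$fs, ts$stim_onset_index,
                               n1_window_ms, p1_window_ms),
                  morphology_error = function(e) NULL)
    if (is.null(f))
      data.frame(channel_id = ts$channel_ids[i], n1_latency_ms = NA_real_,
                 p1_latency_ms = NA_real_, n1p1_amplitude_uV = NA_real_,
                 n1p1_interval_ms = NA_real_, ok = FALSE,
                 stringsAsFactors = FALSE)
    else
      data.frame(channel_id = ts$channel_ids[i],
                 n1_latency_ms = f$n1_latency_ms,
                 p1_latency_ms = f$p1_latency_ms,
                 n1p1_amplitude_uV = f$n1p1_amplitude_uV,
                 n1p1_interval_ms = f$n1p1_interval_ms, ok = TRUE,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Traditional amplitude-based SEP representation area
#'
#' The classic topography rule: a channel belongs to the representation
#' area when its N1-P1 amplitude is at least `fraction` (default 60%) of
#' the maximum amplitude across channels.  The threshold is inclusive
#' (`>=`), so a channel at exactly the fraction is a member.  Membership is
#' invariant under a common positive rescaling of all amplitudes.
#'
#' @param features a [sep_features()] data.frame.
#' @param grid the [electrode_grid()] (provides the pitch for the area).
#' @param fraction amplitude fraction in `[0, 1]` (default 0.6).
#' @return list: `member_channels`, `area_mm2`, `max_amplitude_uV`,
#'   `fraction`.
#' @export
amplitude_topography <- function(features, grid, fraction = 0.6) {
  stopifnot(inherits(grid, "electrode_grid"),
            fraction >= 0, fraction <= 1)
  ok <- features[features$ok & is.finite(features$n1p1_amplitude_uV), ]
  if (!nrow(ok))
    stop("no channel has valid N1/P1 features")
  amax <- max(ok$n1p1_amplitude_uV)
  members <- ok$channel_id[ok$n1p1_amplitude_uV >= fraction * amax]
  list(member_channels = members,
       area_mm2 = length(members) * grid$pitch_mm^2,
       max_amplitude_uV = amax, fraction = fraction)
}

#' Two-group comparison of a scalar SEP measure
#'
#' Pooled-variance (Student) two-tailed independent t-test, the standard
#' reporting test for group differences in latency, amplitude or network
#' area; a Welch variant is available.  Degenerate inputs with zero pooled
#' variance return `t = 0, p = 1` when the means are equal and a flagged
#' infinite t otherwise.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) test instead (default
#'   `FALSE`).
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @return list: `t`, `p`, `df`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `n_a`, `n_b`, `significant`.
#' @export
compare_groups <- function(values_a, values_b, welch = FALSE, alpha = 0.05) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      t <- 0; p <- 1; df <- length(a) + length(b) - 2
    } else {
      warning("zero pooled variance with unequal means: t is infinite")
      t <- sign(mean(a) - mean(b)) * Inf; p <- 0
      df <- length(a) + length(b) - 2
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    t <- unname(ht$statistic); p <- ht$p.value; df <- unname(ht$parameter)
  }
  list(t = t, p = p, df = df,
       mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b),
       n_a = length(a), n_b = length(b),
       significant = p < alpha)
}
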