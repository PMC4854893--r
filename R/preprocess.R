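#' Extract a post-stimulus analysis window
#'
#' Returns the sub-matrix of samples in the half-open interval
#' `[stim_onset + t_start_ms, stim_onset + t_end_ms)`.  The default window
#' used by the pipeline is 0-50 ms post-stimulus, wide enough to cover the
#' N1 (~9.5 ms) and P1 (~21 ms) components of a rat sciatic-nerve SEP with
#' margin.
#'
#' @param ts a [traceset()].
#' @param t_start_ms,t_end_ms window edges in ms after stimulus onset;
#'   `0 <= t_start_ms < t_end_ms` and the window must lie inside the
#'   recording.
#' @return a [traceset()] with the windowed samples; `stim_onset_index` is
#'   reset to 1 and the window offset recorded in attribute
#'   `window_start_ms`.
#' @export
window_traces <- function(ts, t_start_ms, t_end_ms) {
  stopifnot(inherits(ts, "traceset"))
  if (!is.finite(t_start_ms) || !is.finite(t_end_ms) ||
      t_start_ms < 0 || t_start_ms >= t_end_ms)
    stop("invalid window: need 0 <= t_start_ms < t_end_ms, got [",
         t_start_ms, ", ", t_end_ms, ")")
  spm <- ts$fs / 1000                      # samples per ms
  i0 <- ts$stim_onset_index + as.integer(round(t_start_ms * spm))
  i1 <- ts$stim_onset_index + as.integer(round(t_end_ms * spm)) - 1L
  T_ <- ncol(ts$data)
  if (i0 > T_ || i1 > T_)
    stop("window [", t_start_ms, ", ", t_end_ms,
         ") ms extends past the end of the recording")
  if (i1 < i0) stop("empty analysis window")
  out <- traceset(ts$data[, i0:i1, drop = FALSE], ts$fs, ts$channel_ids,
                  stim_onset_index = 1L)
  attr(out, "window_start_ms") <- t_start_ms
  attr(out, "window_end_ms") <- t_end_ms
  out
}

#' Z-normalize each channel
#'
#' Subtracts each channel's mean and divides by its *population* standard
#' deviation (the divide-by-T form), so that the equal-time correlation
#' matrix computed downstream has an exactly unit diagonal.  The per-channel
#' mean and SD are kept as provenance attributes.
#'
#' @param ts a [traceset()] or a plain numeric matrix (channels x samples).
#' @return object of class `zscored_traces`: `data` (M x T, each row mean 0
#'   and population SD 1), `channel_ids`, `fs`, plus `channel_means` /
#'   `channel_sds` provenance.
#' @export
znormalize <- function(ts) {
  if (inherits(ts, "zscored_traces")) return(ts)
  if (inherits(ts, "traceset")) {
    m <- ts$data; ids <- ts$channel_ids; fs <- ts$fs
  } else {
    if (!is.matrix(ts) || !is.numeric(ts)) stop("need a traceset or matrix")
    m <- ts
    ids <- rownames(m); if (is.null(ids)) ids <- paste0("ch", seq_len(nrow(m)))
    fs <- NA_real_
  }
  mu <- rowMeans(m)
  sds <- sqrt(rowMeans((m - mu)^2))
  if (any(sds == 0))
    stop("degenerate channel(s) with zero variance: ",
         paste(ids[sds == 0], collapse = ", "))
  z <- (m - mu) / sds
  rownames(z) <- ids
  structure(
    list(data = z, channel_ids = ids, fs = fs,
         channel_means = mu, channel_sds = sds),
    class = "zscored_traces")
}
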