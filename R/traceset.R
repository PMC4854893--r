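#' Build and validate a multichannel evoked-potential trace set
#'
#' A `traceset` holds averaged evoked-potential traces as an M x T numeric
#' matrix (channels in rows, time samples in columns, amplitudes in
#' microvolts) together with the sampling rate, ordered channel labels and
#' the sample index of stimulus onset.  All downstream stages (windowing,
#' normalization, correlation analysis, peak detection) consume this type.
#'
#' Validation is strict: non-finite values, duplicate channel labels or a
#' flat (zero-variance) channel are errors, because a zero-variance channel
#' makes the z-score undefined and silent dropping would desynchronize the
#' matrix rows from the electrode layout.  When there are fewer time samples
#' than channels the correlation matrix is rank deficient; this is legal but
#' flagged with a warning.
#'
#' @param data numeric matrix, M channels x T time samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_ids character vector of M unique channel labels; defaults
#'   to `rownames(data)`, or `"ch1".."chM"` when unnamed.
#' @param stim_onset_index 1-based sample index of stimulus time zero
#'   (default 1: the recording starts at the stimulus).
#' @return an object of class `traceset` with fields `data`, `fs`,
#'   `channel_ids`, `stim_onset_index`.
#' @examples
#' ts <- traceset(matrix(rnorm(16), 2, 8), fs = 20000, channel_ids = c("a", "b"))
#' ts$fs
#' @export
traceset <- function(data, fs, channel_ids = NULL, stim_onset_index = 1L) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x time samples)")
  M <- nrow(data); T_ <- ncol(data)
  if (M < 2L) stop("need at least 2 channels, got ", M)
  if (T_ < 4L) stop("need at least 4 time samples, got ", T_)
  if (!all(is.finite(data)))
    stop("trace data contain non-finite values (NaN/Inf/NA)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.null(channel_ids)) {
    channel_ids <- rownames(data)
    if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(M))
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != M)
    stop("`channel_ids` length (", length(channel_ids),
         ") does not match the number of channels (", M, ")")
  if (anyDuplicated(channel_ids))
    stop("duplicate channel_ids: ",
         paste(unique(channel_ids[duplicated(channel_ids)]), collapse = ", "))
  stim_onset_index <- as.integer(stim_onset_index)
  if (is.na(stim_onset_index) || stim_onset_index < 1L || stim_onset_index > T_)
    stop("`stim_onset_index` must lie in [1, ", T_, "]")
  sds <- row_pop_sd(data)
  if (any(sds == 0)) {
    bad <- channel_ids[sds == 0]
    stop("degenerate channel(s) with zero variance: ",
         paste(bad, collapse = ", "))
  }
  if (T_ < M)
    warning("fewer time samples (", T_, ") than channels (", M,
            "): the correlation matrix will be rank deficient")
  rownames(data) <- channel_ids
  structure(
    list(data = data, fs = fs, channel_ids = channel_ids,
         stim_onset_index = stim_onset_index),
    class = "traceset")
}

#' @rdname traceset
#' @param raw numeric matrix passed through to [traceset()].
#' @export
validate_traceset <- function(raw, fs, channel_ids = NULL,
                              stim_onset_index = 1L) {
  if (inherits(raw, "traceset"))
    return(traceset(raw$data, raw$fs, raw$channel_ids, raw$stim_onset_index))
  traceset(raw, fs, channel_ids, stim_onset_index)
}

#' @export
print.traceset <- function(x, ...) {
  cat("traceset: ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (",
      round(ncol(x$data) / x$fs * 1000, 3), " ms), stimulus at sample ",
      x$stim_onset_index, "\n", sep = "")
  invisible(x)
}

# population (divide-by-T) standard deviation of each matrix row
row_pop_sd <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}
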