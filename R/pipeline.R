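#' Read a trace CSV
#'
#' Expects a first column of time (sample index or seconds; it is dropped)
#' and one column per channel with channel ids as headers.  The sampling
#' rate is supplied by the caller because the file does not carry it.
#'
#' @param path CSV file path.
#' @param fs sampling rate (Hz), default 20000.
#' @param stim_onset_index 1-based sample index of the stimulus.
#' @return a [traceset()].
#' @export
read_traces_csv <- function(path, fs = 20000, stim_onset_index = 1L) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 3L) stop("trace CSV needs a time column plus >= 2 channels")
  m <- t(as.matrix(d[, -1, drop = FALSE]))
  traceset(m, fs = fs, channel_ids = colnames(d)[-1],
           stim_onset_index = stim_onset_index)
}

#' Write a trace set to CSV
#'
#' Inverse of [read_traces_csv()]: first column `time_s`, one column per
#' channel.
#'
#' @param ts a [traceset()].
#' @param path output file.
#' @export
write_traces_csv <- function(ts, path) {
  d <- data.frame(time_s = (seq_len(ncol(ts$data)) - ts$stim_onset_index) /
                    ts$fs)
  for (i in seq_along(ts$channel_ids)) d[[ts$channel_ids[i]]] <- ts$data[i, ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @return named list of the tunable parameters of [run_pipeline()]:
#'   analysis window (ms post-stimulus), surrogate settings, significance
#'   multiplier `K`, peak-search windows, amplitude fraction, weak-network
#'   PI ceiling and RNG seed.
#' @export
default_config <- function() {
  list(window_start_ms = 0, window_end_ms = 50,
       n_surrogates = 100L, surrogate_method = "ft", K = 3,
       seed = 1L,
       n1_window_ms = c(3, 15), p1_window_ms = c(10, 40),
       amplitude_fraction = 0.6, weak_pi_max = 0.2)
}

#' Run the full synchronization-topography pipeline
#'
#' Executes, in order: post-stimulus windowing, per-channel z-normalization,
#' equal-time correlation matrix, eigendecomposition, phase-randomized
#' surrogate null, significant-cluster count, participation indices,
#' knee-point threshold, boundary demarcation and network area — and, in
#' parallel, the traditional amplitude-based topography (N1/P1 features and
#' the 60%-of-maximum representation area).  Returns one self-describing
#' report that [write_report()] serializes to JSON.
#'
#' @param traces a [traceset()] or path to a trace CSV.
#' @param layout an [electrode_grid()] or path to a layout file.
#' @param config named list; unspecified entries fall back to
#'   [default_config()].
#' @param fs sampling rate, used only when `traces` is a CSV path.
#' @return object of class `sep_report` (a named list): config echo,
#'   eigenvalues, surrogate null band, cluster count (total and with weak
#'   networks excluded), per-cluster PI map / knee threshold / members /
#'   area / weak flag, and the classic amplitude topography.
#' @export
run_pipeline <- function(traces, layout, config = list(), fs = 20000) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.character(traces)) traces <- read_traces_csv(traces, fs = fs)
  stopifnot(inherits(traces, "traceset"))
  grid <- if (is.character(layout)) read_layout(layout) else layout
  stopifnot(inherits(grid, "electrode_grid"))
  if (!setequal(traces$channel_ids, grid$positions$channel_id))
    stop("trace channels and electrode layout do not match")

  win <- window_traces(traces, cfg$window_start_ms, cfg$window_end_ms)
  z <- znormalize(win)
  cm <- correlation_matrix(z)
  es <- eigendecompose(cm)
  null <- surrogate_eigen_null(z, n = cfg$n_surrogates,
                               method = cfg$surrogate_method,
                               seed = cfg$seed)
  dec <- count_clusters(es, null, K = cfg$K)

  clusters <- list()
  if (dec$n_clusters > 0) {
    pm <- participation_index(es, dec$significant_indices)
    for (rank in dec$significant_indices) {
      curve <- pi_curve(pm, rank)
      knee <- tryCatch(knee_point(curve),
                       degenerate_curve_error = function(e) NULL)
      bd <- demarcate_boundary(pm, rank, grid, knee,
                               weak_pi_max = cfg$weak_pi_max)
      col <- match(rank, pm$cluster_ranks)
      clusters[[length(clusters) + 1L]] <- list(
        rank = rank,
        eigenvalue = es$values[rank],
        pi = stats::setNames(as.numeric(pm$PI[, col]), pm$channel_ids),
        pi_threshold = bd$pi_threshold,
        member_channels = bd$member_channels,
        area_mm2 = bd$area_mm2,
        is_weak = bd$is_weak,
        max_pi = bd$max_pi)
    }
  }

  feats <- sep_features(traces, cfg$n1_window_ms, cfg$p1_window_ms)
  classic <- tryCatch(
    amplitude_topography(feats, grid, cfg$amplitude_fraction),
    error = function(e) list(member_channels = character(0),
                             area_mm2 = NA_real_,
                             max_amplitude_uV = NA_real_,
                             fraction = cfg$amplitude_fraction,
                             error = conditionMessage(e)))

  structure(
    list(version = as.character(utils::packageVersion("sepsync")),
         config = cfg,
         n_channels = length(traces$channel_ids),
         n_samples_analyzed = ncol(win$data),
         eigenvalues = es$values,
         eigenvalues_ascending = rev(es$values),
         null = list(mean_eigs = null$mean_eigs, sd_eigs = null$sd_eigs,
                     n = null$n, method = null$method, seed = null$seed),
         n_clusters = dec$n_clusters,
         n_clusters_strong = sum(!vapply(clusters, `[[`, TRUE, "is_weak")),
         significant_indices = dec$significant_indices,
         clusters = clusters,
         classic = list(features = feats,
                        member_channels = classic$member_channels,
                        area_mm2 = classic$area_mm2,
                        max_amplitude_uV = classic$max_amplitude_uV,
                        fraction = classic$fraction)),
    class = "sep_report")
}

#' @export
print.sep_report <- function(x, ...) {
  cat("sep_report: ", x$n_channels, " channels, ",
      x$n_clusters, " synchronized cluster(s) (",
      x$n_clusters_strong, " strong)\n", sep = "")
  for (cl in x$clusters)
    cat(sprintf("  cluster %d: eigenvalue %.3f, %d members, %.2f mm^2%s\n",
                cl$rank, cl$eigenvalue, length(cl$member_channels),
                cl$area_mm2, if (cl$is_weak) " [weak]" else ""))
  if (is.finite(x$classic$area_mm2))
    cat(sprintf("  classic %.0f%%-of-max area: %d members, %.2f mm^2\n",
                100 * x$classic$fraction,
                length(x$classic$member_channels), x$classic$area_mm2))
  invisible(x)
}

#' Serialize / deserialize a pipeline report
#'
#' Reports are written as a single self-describing JSON document; the same
#' inputs, configuration and seed always produce a byte-identical file.
#'
#' @param report a `sep_report` from [run_pipeline()].
#' @param path output / input JSON path.
#' @return `write_report` returns `path` invisibly; `read_report` the
#'   report as a list.
#' @export
write_report <- function(report, path) {
  r <- unclass(report)
  # named numeric vectors serialize as bare arrays; keep the channel keys
  r$clusters <- lapply(r$clusters, function(cl) {
    cl$pi <- as.list(cl$pi)
    cl
  })
  jsonlite::write_json(r, path, digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Compare a scalar field across two groups of reports
#'
#' Extracts one numeric quantity per report (e.g. the strongest network's
#' `area_mm2`) and runs [compare_groups()].
#'
#' @param reports_a,reports_b lists of reports (or report file paths),
#'   >= 2 per group.
#' @param field `"area_mm2"`, `"eigenvalue"`, `"pi_threshold"` or
#'   `"max_pi"` — taken from each report's strongest non-weak cluster —
#'   or `"classic_area_mm2"` / `"n_clusters"` at report level.
#' @return a [compare_groups()] result plus the extracted per-group values.
#' @export
compare_runs <- function(reports_a, reports_b, field = "area_mm2") {
  pull <- function(reports) {
    vapply(reports, function(r) {
      if (is.character(r)) r <- read_report(r)
      if (field == "n_clusters") return(as.numeric(r$n_clusters))
      if (field == "classic_area_mm2") return(as.numeric(r$classic$area_mm2))
      cls <- r$clusters
      # a JSON round-trip may simplify the cluster list to a data.frame
      if (is.data.frame(cls))
        cls <- lapply(seq_len(nrow(cls)), function(i) as.list(cls[i, ]))
      if (!length(cls)) stop("report has no detected cluster")
      strong <- Filter(function(cl) !isTRUE(cl$is_weak), cls)
      if (!length(strong)) strong <- cls
      val <- strong[[1]][[field]]
      if (is.null(val)) stop("field `", field, "` not found in report")
      as.numeric(val)
    }, 0)
  }
  a <- pull(reports_a); b <- pull(reports_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 reports")
  out <- compare_groups(a, b)
  out$values_a <- a; out$values_b <- b; out$field <- field
  out
}
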