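#' Canonical SEP-like waveform
#'
#' A deterministic evoked-potential template: a negative Gaussian bump
#' (N1) followed by a larger positive Gaussian bump (P1).  With the
#' defaults (N1 at 9.5 ms, 15 uV deep; P1 at 21 ms, 35 uV high) the
#' peak-to-trough N1-P1 amplitude is ~50 uV, typical of an averaged rat
#' sciatic-nerve SEP.
#'
#' @param fs sampling rate (Hz), default 20000.
#' @param duration_ms trace duration, default 50 ms (`fs * duration_ms /
#'   1000` must be a whole number of samples).
#' @param n1_latency_ms,p1_latency_ms bump centres in ms; must satisfy
#'   `n1 < p1 < duration`.
#' @param n1_amp_uV,p1_amp_uV bump magnitudes in uV (both non-negative;
#'   N1 is applied with negative sign).
#' @param n1_width_ms,p1_width_ms Gaussian SD of each bump in ms.
#' @return numeric vector of `fs * duration_ms / 1000` samples (uV),
#'   sample 1 at t = 0 (stimulus).
#' @export
sep_waveform <- function(fs = 20000, duration_ms = 50,
                         n1_latency_ms = 9.5, p1_latency_ms = 21,
                         n1_amp_uV = 15, p1_amp_uV = 35,
                         n1_width_ms = 1.5, p1_width_ms = 3) {
  if (!(n1_latency_ms < p1_latency_ms && p1_latency_ms < duration_ms))
    stop("need n1_latency_ms < p1_latency_ms < duration_ms")
  if (n1_amp_uV < 0 || p1_amp_uV < 0)
    stop("bump magnitudes must be non-negative")
  T_ <- fs * duration_ms / 1000
  if (abs(T_ - round(T_)) > 1e-9)
    stop("fs * duration_ms must give a whole number of samples")
  T_ <- as.integer(round(T_))
  t_ms <- (seq_len(T_) - 1L) / fs * 1000
  -n1_amp_uV * exp(-(t_ms - n1_latency_ms)^2 / (2 * n1_width_ms^2)) +
    p1_amp_uV * exp(-(t_ms - p1_latency_ms)^2 / (2 * p1_width_ms^2))
}

#' Specification for a synthetic multichannel SEP recording
#'
#' Describes a rectangular electrode grid and a set of ground-truth
#' synchronized clusters.  Each cluster has a centre on the cortex, a
#' Gaussian spatial gain profile `gain(d) = exp(-d^2 / (2 radius^2))`
#' (anisotropic if `radius_mm` has separate ML/AP components) and its own
#' SEP waveform; every channel records the gain-weighted sum of the
#' cluster waveforms plus independent Gaussian noise.
#'
#' @param n_ap,n_ml,pitch_mm,ml_origin,ap_origin grid geometry, see
#'   [rect_grid()].
#' @param fs,duration_ms sampling (defaults 20 kHz, 50 ms; T = 1000).
#' @param clusters list of cluster descriptions; each a list with
#'   `center = c(ml_mm, ap_mm)`, `radius_mm` (scalar or `c(ml, ap)`), and
#'   optional waveform parameters passed to [sep_waveform()].
#' @param noise_sd_uV SD of the iid additive Gaussian noise per channel and
#'   sample (default 5 uV, a realistic residual for a 200-sweep average).
#' @param noise_spatial_range_mm optional range of an exponential spatial
#'   correlation kernel for the noise (`NULL`, the default, keeps noise
#'   independent across channels).
#' @param seed RNG seed used by [synth_generate()].
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_ap = 16L, n_ml = 12L, pitch_mm = 0.5,
                       ml_origin = 1.0, ap_origin = -5.5,
                       fs = 20000, duration_ms = 50,
                       clusters = list(list(center = c(3.5, -2.5),
                                            radius_mm = 1.0)),
                       noise_sd_uV = 5, noise_spatial_range_mm = NULL,
                       seed = 1L) {
  if (noise_sd_uV <= 0) stop("noise_sd_uV must be > 0")
  T_ <- fs * duration_ms / 1000
  if (abs(T_ - round(T_)) > 1e-9)
    stop("fs * duration_ms must give a whole number of samples")
  ml_max <- ml_origin + (n_ml - 1L) * pitch_mm
  ap_max <- ap_origin + (n_ap - 1L) * pitch_mm
  for (cl in clusters) {
    if (cl$center[1] < ml_origin || cl$center[1] > ml_max ||
        cl$center[2] < ap_origin || cl$center[2] > ap_max)
      stop("cluster centre (", cl$center[1], ", ", cl$center[2],
           ") lies outside the grid hull")
  }
  structure(
    list(n_ap = as.integer(n_ap), n_ml = as.integer(n_ml),
         pitch_mm = pitch_mm, ml_origin = ml_origin, ap_origin = ap_origin,
         fs = fs, duration_ms = duration_ms, clusters = clusters,
         noise_sd_uV = noise_sd_uV,
         noise_spatial_range_mm = noise_spatial_range_mm,
         seed = as.integer(seed)),
    class = "synth_spec")
}

#' Preset synthetic conditions
#'
#' Two single-cluster presets emulating the qualitative group differences
#' seen between intact and acutely nerve-injured animals, plus a
#' well-separated two-cluster configuration for detection tests:
#' \describe{
#'   \item{`"normal"`}{one compact isotropic cluster (radius 1.0 mm)
#'     centred posterior to bregma; waveform N1 9.5 ms / P1 21 ms with
#'     ~50 uV N1-P1 amplitude.}
#'   \item{`"injured"`}{one larger, AP-elongated cluster shifted toward
#'     bregma so the network spills anterior as well as posterior;
#'     shorter latencies (N1 7.6 ms / P1 18.5 ms) and ~94 uV N1-P1
#'     amplitude.}
#'   \item{`"two_cluster"`}{two compact clusters at opposite corners of
#'     the grid with different waveform latencies, for multi-network
#'     detection tests.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed stored in the spec.
#' @return a [synth_spec()].
#' @export
synth_preset <- function(name = c("normal", "injured", "two_cluster"),
                         seed = 1L) {
  name <- match.arg(name)
  base <- list(
    normal = list(list(center = c(3.5, -2.5), radius_mm = 1.0,
                       n1_latency_ms = 9.5, p1_latency_ms = 21,
                       n1_amp_uV = 15, p1_amp_uV = 35)),
    injured = list(list(center = c(3.5, -0.8), radius_mm = c(1.05, 1.55),
                        n1_latency_ms = 7.6, p1_latency_ms = 18.5,
                        n1_amp_uV = 28, p1_amp_uV = 66)),
    two_cluster = list(list(center = c(2.0, -4.0), radius_mm = 0.8,
                            n1_latency_ms = 9.5, p1_latency_ms = 21,
                            n1_amp_uV = 15, p1_amp_uV = 35),
                       list(center = c(5.5, 0.5), radius_mm = 0.8,
                            n1_latency_ms = 14, p1_latency_ms = 30,
                            n1_amp_uV = 15, p1_amp_uV = 35)))
  synth_spec(clusters = base[[name]], seed = seed)
}

#' Generate a synthetic SEP recording with ground truth
#'
#' Channel `i` records `sum_c gain_c(i) * waveform_c + noise`, with
#' `gain_c(i) = exp(-d(i, center_c)^2 / (2 radius_c^2))` and iid Gaussian
#' noise of SD `noise_sd_uV`.  Fully reproducible from `spec$seed`.
#' Ground-truth membership of a cluster is `gain >= 0.1 * max(gain)` (a
#' fixed, documented cutoff used by the recovery tests).
#'
#' @param spec a [synth_spec()].
#' @return list: `traces` ([traceset()]), `grid` ([electrode_grid()]),
#'   `truth` (per-cluster `members`, `gains` matrix channels x clusters,
#'   `waveforms` clusters x samples).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  grid <- rect_grid(spec$n_ap, spec$n_ml, spec$pitch_mm,
                    spec$ml_origin, spec$ap_origin)
  M <- nrow(grid$positions)
  T_ <- as.integer(round(spec$fs * spec$duration_ms / 1000))
  nC <- length(spec$clusters)
  gains <- matrix(0, M, nC,
                  dimnames = list(grid$positions$channel_id, NULL))
  wf <- matrix(0, nC, T_)
  for (c in seq_len(nC)) {
    cl <- spec$clusters[[c]]
    r <- cl$radius_mm
    if (length(r) == 1L) r <- c(r, r)
    dml <- grid$positions$ml_mm - cl$center[1]
    dap <- grid$positions$ap_mm - cl$center[2]
    gains[, c] <- exp(-(dml^2 / (2 * r[1]^2) + dap^2 / (2 * r[2]^2)))
    wargs <- cl[setdiff(names(cl), c("center", "radius_mm"))]
    wf[c, ] <- do.call(sep_waveform,
                       c(list(fs = spec$fs, duration_ms = spec$duration_ms),
                         wargs))
  }
  data <- local_seed(spec$seed, {
    noise <- matrix(stats::rnorm(M * T_, sd = spec$noise_sd_uV), M, T_)
    if (!is.null(spec$noise_spatial_range_mm)) {
      D <- as.matrix(stats::dist(grid$positions[, c("ml_mm", "ap_mm")]))
      L <- chol(exp(-D / spec$noise_spatial_range_mm) +
                  diag(1e-10, M))
      noise <- t(L) %*% noise
    }
    gains %*% wf + noise
  })
  truth <- list(
    members = lapply(seq_len(nC), function(c)
      grid$positions$channel_id[gains[, c] >= 0.1 * max(gains[, c])]),
    gains = gains, waveforms = wf)
  list(traces = traceset(data, spec$fs, grid$positions$channel_id,
                         stim_onset_index = 1L),
       grid = grid, truth = truth)
}
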