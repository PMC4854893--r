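#' Phase-randomized surrogate of a single time series
#'
#' Produces a surrogate series sharing the amplitude spectrum (hence power
#' spectrum and autocorrelation) of the input while randomizing its Fourier
#' phases, the null model of "same per-channel linear dynamics, no
#' inter-channel synchronization".
#'
#' Two variants are provided:
#' \describe{
#'   \item{`"ft"`}{classic Fourier surrogate: multiply each positive-
#'     frequency Fourier coefficient by `exp(i*theta_k)` with independent
#'     uniform phases, mirrored Hermitian-symmetrically
#'     (`theta[T-k] = -theta[k]`); the DC and (for even T) Nyquist bins are
#'     left untouched so the inverse transform is exactly real and the mean
#'     is preserved.  The amplitude spectrum is preserved exactly.}
#'   \item{`"aaft"`}{amplitude-adjusted Fourier transform: the series is
#'     Gaussianized by rank, phase-randomized as above, and the original
#'     amplitudes are remapped by rank, preserving the amplitude
#'     *distribution* exactly and the power spectrum approximately.}
#' }
#'
#' Uses the current R random number generator state; seed upstream for
#' reproducibility.
#'
#' @param x finite numeric vector, length >= 4.
#' @param method `"ft"` (default) or `"aaft"`.
#' @return numeric vector, same length as `x`.
#' @export
phase_randomize <- function(x, method = c("ft", "aaft")) {
  method <- match.arg(method)
  T_ <- length(x)
  if (T_ < 4L || !all(is.finite(x))) stop("need a finite series of length >= 4")
  if (method == "ft") {
    drop(ft_surrogate_matrix(matrix(x, ncol = 1)))
  } else {
    g <- sort(stats::rnorm(T_))[rank(x, ties.method = "first")]
    gs <- drop(ft_surrogate_matrix(matrix(g, ncol = 1)))
    sort(x)[rank(gs, ties.method = "first")]
  }
}

# Vectorized FT surrogate: columns of `xm` (T x M) are randomized
# independently unless `shared_theta` supplies one phase vector for all.
ft_surrogate_matrix <- function(xm, shared_theta = NULL) {
  T_ <- nrow(xm); M <- ncol(xm)
  Y <- stats::mvfft(xm)
  half <- (T_ - 1L) %/% 2L                 # bins 2..(1+half) are free
  if (half > 0L) {
    th <- matrix(0, T_, M)
    if (is.null(shared_theta)) {
      th[2:(1L + half), ] <- stats::runif(half * M, 0, 2 * pi)
    } else {
      th[2:(1L + half), ] <- shared_theta
    }
    th[T_:(T_ - half + 1L), ] <- -th[2:(1L + half), ]
    # DC (bin 1) and, for even T, the Nyquist bin (T/2 + 1) keep theta = 0,
    # guaranteeing Hermitian symmetry and a real inverse transform
    Y <- Y * exp(1i * th)
  }
  Re(stats::mvfft(Y, inverse = TRUE)) / T_
}

#' Surrogate-data null distribution of correlation eigenvalues
#'
#' Repeats `n` times: phase-randomize every channel independently
#' (destroying all inter-channel phase relationships while preserving each
#' channel's power spectrum), re-z-normalize, compute the surrogate
#' correlation matrix R and its sorted eigenvalues.  Returns the per-rank
#' mean and standard deviation over repetitions — the null distribution of
#' eigenvalues under "no synchronized clusters".
#'
#' @param z a [znormalize()]d trace set (or a `traceset`, normalized here).
#' @param n number of surrogate repetitions (default 100).
#' @param method surrogate type, `"ft"` (default) or `"aaft"`; see
#'   [phase_randomize()].
#' @param seed integer RNG seed; the null is fully reproducible from it.
#' @param shared_phases if `TRUE`, one phase vector is shared by all
#'   channels within a repetition, preserving cross-spectra — a diagnostic
#'   mode, *not* the null of no synchronization (default `FALSE`).
#' @return object of class `surrogate_null`: `mean_eigs` and `sd_eigs`
#'   (length M, rank-sorted descending), `n`, `method`, `seed`, `M`,
#'   and the full `samples` matrix (n x M) of surrogate eigenvalue spectra.
#' @export
surrogate_eigen_null <- function(z, n = 100L, method = c("ft", "aaft"),
                                 seed = 1L, shared_phases = FALSE) {
  method <- match.arg(method)
  if (!inherits(z, "zscored_traces")) z <- znormalize(z)
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 surrogate repetitions")
  M <- nrow(z$data); T_ <- ncol(z$data)
  half <- (T_ - 1L) %/% 2L

  samples <- matrix(NA_real_, n, M)
  xm <- t(z$data)                          # T x M, FFT once per null
  Y0 <- stats::mvfft(xm)
  local_seed(seed, {
    for (r in seq_len(n)) {
      if (method == "ft") {
        th <- matrix(0, T_, M)
        if (half > 0L) {
          free <- if (shared_phases)
            matrix(stats::runif(half, 0, 2 * pi), half, M)
          else matrix(stats::runif(half * M, 0, 2 * pi), half, M)
          th[2:(1L + half), ] <- free
          th[T_:(T_ - half + 1L), ] <- -free
        }
        xs <- Re(stats::mvfft(Y0 * exp(1i * th), inverse = TRUE)) / T_
      } else {
        th <- if (shared_phases && half > 0L)
          stats::runif(half, 0, 2 * pi) else NULL
        xs <- apply(xm, 2, function(x) {
          g <- sort(stats::rnorm(T_))[rank(x, ties.method = "first")]
          gs <- drop(ft_surrogate_matrix(matrix(g, ncol = 1),
                                         shared_theta = th))
          sort(x)[rank(gs, ties.method = "first")]
        })
      }
      # re-z-normalize columns so R is a true correlation matrix
      mu <- colMeans(xs)
      xs <- sweep(xs, 2, mu)
      sds <- sqrt(colMeans(xs^2))
      if (any(sds == 0))
        stop("degenerate surrogate channel (zero variance)")
      xs <- sweep(xs, 2, sds, "/")
      R <- crossprod(xs) / T_
      samples[r, ] <- eigen((R + t(R)) / 2, symmetric = TRUE,
                            only.values = TRUE)$values
    }
  })
  structure(
    list(mean_eigs = colMeans(samples),
         sd_eigs = apply(samples, 2, stats::sd),
         n = n, method = method, seed = as.integer(seed), M = M,
         samples = samples),
    class = "surrogate_null")
}

#' Count significant synchronized clusters
#'
#' An observed eigenvalue indicates a synchronized cluster when it exceeds
#' the surrogate mean by `K` surrogate standard deviations at the same
#' rank: `lambda_i > mean'_i + K * SD_i`.  The default `K = 3` corresponds
#' to the 99.7% confidence band of a Gaussian null (the three-sigma rule).
#'
#' @param es an [eigendecompose()]d system (descending eigenvalues).
#' @param null a [surrogate_eigen_null()] built from the same channels.
#' @param K significance multiplier (default 3).
#' @return object of class `cluster_decision`: `n_clusters`,
#'   `significant_indices` (ranks, 1 = strongest), `K`, and the
#'   per-rank `threshold` vector `mean'_i + K * SD_i`.
#' @export
count_clusters <- function(es, null, K = 3) {
  stopifnot(inherits(es, "eigen_system"), inherits(null, "surrogate_null"))
  M <- length(es$values)
  if (null$M != M)
    stop("channel count mismatch: eigen system has ", M,
         " channels, surrogate null has ", null$M)
  thr <- null$mean_eigs + K * null$sd_eigs
  sig <- which(es$values > thr)
  if (length(sig) && !identical(sig, seq_along(sig)))
    warning("significant eigenvalue ranks are not a contiguous prefix: ",
            paste(sig, collapse = ", "))
  structure(list(n_clusters = length(sig), significant_indices = sig,
                 K = K, threshold = thr),
            class = "cluster_decision")
}

#' @export
print.cluster_decision <- function(x, ...) {
  cat("cluster_decision: ", x$n_clusters, " significant cluster(s) at K = ",
      x$K, if (x$n_clusters) paste0(" (ranks ",
                                    paste(x$significant_indices,
                                          collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
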