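#' Equal-time correlation matrix
#'
#' Computes the zero-lag Pearson correlation matrix
#' `C[i, j] = (1/T) * sum_k z_i(t_k) z_j(t_k)` of z-normalized traces.
#' Because the channels are normalized with the population SD, the diagonal
#' is exactly 1 and `trace(C) = M`.  The result is explicitly symmetrized
#' as `(C + t(C)) / 2` to remove floating-point asymmetry before
#' eigendecomposition.
#'
#' @param z a [znormalize()]d trace set (a `traceset` is normalized first).
#' @return object of class `correlation_matrix`: `C` (M x M, unit diagonal,
#'   symmetric, positive semi-definite) and `channel_ids`.
#' @export
correlation_matrix <- function(z) {
  if (!inherits(z, "zscored_traces")) z <- znormalize(z)
  T_ <- ncol(z$data)
  C <- tcrossprod(z$data) / T_
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- list(z$channel_ids, z$channel_ids)
  structure(list(C = C, channel_ids = z$channel_ids),
            class = "correlation_matrix")
}

#' Eigendecompose a correlation matrix
#'
#' Solves `C v_i = lambda_i v_i` for a symmetric correlation matrix.
#' Eigenvalues are returned in descending order (cluster 1 = strongest
#' synchronization); eigenvectors are orthonormal and each has its
#' largest-magnitude element forced positive so that reports are
#' deterministic (the participation index is insensitive to the sign).
#' The largest eigenvalue measures global synchronization: it approaches M
#' when all channels carry one common waveform and 1 when channels are
#' independent.
#'
#' @param cm a [correlation_matrix()] (or a plain symmetric matrix).
#' @return object of class `eigen_system`: `values` (length M, descending),
#'   `vectors` (M x M, columns aligned with `values`), `channel_ids`.
#' @export
eigendecompose <- function(cm) {
  if (inherits(cm, "correlation_matrix")) {
    C <- cm$C; ids <- cm$channel_ids
  } else {
    C <- (cm + t(cm)) / 2
    ids <- rownames(C); if (is.null(ids)) ids <- paste0("ch", seq_len(nrow(C)))
  }
  es <- tryCatch(eigen(C, symmetric = TRUE),
                 error = function(e) stop("eigendecomposition failed: ",
                                          conditionMessage(e)))
  V <- es$vectors
  for (i in seq_len(ncol(V))) {
    j <- which.max(abs(V[, i]))
    if (V[j, i] < 0) V[, i] <- -V[, i]
  }
  rownames(V) <- ids
  structure(list(values = es$values, vectors = V, channel_ids = ids),
            class = "eigen_system")
}

#' Participation index of each channel in each cluster
#'
#' The participation index of channel `j` in cluster `i` is
#' `PI[j, i] = lambda_i * v[j, i]^2`: the cluster's synchronization
#' strength weighted by the channel's squared loading on the corresponding
#' eigenvector.  Its spatial map over the electrode grid is the
#' synchronization topography.  When all M clusters are retained the PI of
#' each channel sums to the unit diagonal of C, i.e. exactly 1.
#'
#' Participation indices are meaningful for *significant* eigenvalues
#' (see [count_clusters()]); within a degenerate eigenvalue subspace the
#' eigenvector basis — and hence PI — is solver-dependent.
#'
#' @param es an [eigendecompose()]d system.
#' @param cluster_indices ranks (1 = largest eigenvalue) of the clusters to
#'   report; must be a non-empty subset of `1..M`.
#' @return object of class `participation_map`: `PI` (M channels x
#'   n_clusters, rownames = channel ids, colnames = `cluster<rank>`),
#'   `cluster_ranks`, `eigenvalues` of the retained clusters,
#'   `channel_ids`.
#' @export
participation_index <- function(es, cluster_indices) {
  stopifnot(inherits(es, "eigen_system"))
  if (length(cluster_indices) == 0L)
    stop("`cluster_indices` must name at least one cluster")
  cluster_indices <- as.integer(cluster_indices)
  M <- length(es$values)
  if (any(cluster_indices < 1L | cluster_indices > M))
    stop("cluster indices out of range 1..", M)
  PI <- sapply(cluster_indices,
               function(i) es$values[i] * es$vectors[, i]^2)
  PI <- matrix(PI, nrow = M,
               dimnames = list(es$channel_ids,
                               paste0("cluster", cluster_indices)))
  structure(list(PI = PI, cluster_ranks = cluster_indices,
                 eigenvalues = es$values[cluster_indices],
                 channel_ids = es$channel_ids),
            class = "participation_map")
}
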