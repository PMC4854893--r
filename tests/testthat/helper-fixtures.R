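# Shared fixture builders (all generated in code; no data files).

# small deterministic traceset: M sinusoid+noise channels
tiny_traceset <- function(M = 4, T = 64, fs = 20000, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(M * T), M, T) +
    outer(seq_len(M), seq_len(T), function(i, k) sin(k / 5 + i))
  traceset(m, fs = fs)
}

# square grid with default labels ch001..; pitch 0.5 mm
square_grid <- function(n = 4, pitch = 0.5) {
  rect_grid(n_ap = n, n_ml = n, pitch_mm = pitch,
            ml_origin = 0, ap_origin = 0)
}

# participation map built directly from a PI vector (single cluster)
fake_pm <- function(pi_values, channel_ids = sprintf("ch%03d", seq_along(pi_values)),
                    eigenvalue = sum(pi_values)) {
  structure(list(PI = matrix(pi_values, ncol = 1,
                             dimnames = list(channel_ids, "cluster1")),
                 cluster_ranks = 1L, eigenvalues = eigenvalue,
                 channel_ids = channel_ids),
            class = "participation_map")
}

fake_curve <- function(thresholds, counts) {
  structure(list(thresholds = thresholds, counts = counts, cluster_rank = 1L),
            class = "pi_curve")
}

fake_eigen <- function(values, vectors = diag(length(values)),
                       ids = paste0("ch", seq_along(values))) {
  rownames(vectors) <- ids
  structure(list(values = values, vectors = vectors, channel_ids = ids),
            class = "eigen_system")
}

fake_null <- function(mean_eigs, sd_eigs) {
  structure(list(mean_eigs = mean_eigs, sd_eigs = sd_eigs,
                 n = 100L, method = "ft", seed = 1L,
                 M = length(mean_eigs)),
            class = "surrogate_null")
}

# small, fast synthetic condition (8x6 grid, 200 samples at 4 kHz)
small_sim <- function(seed = 1, clusters = list(list(center = c(1.5, 1.5),
                                                     radius_mm = 0.75)),
                      noise_sd_uV = 5) {
  spec <- synth_spec(n_ap = 8, n_ml = 6, pitch_mm = 0.5,
                     ml_origin = 0, ap_origin = 0,
                     fs = 4000, duration_ms = 50,
                     clusters = clusters, noise_sd_uV = noise_sd_uV,
                     seed = seed)
  synth_generate(spec)
}
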