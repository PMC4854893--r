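test_that("ft surrogates preserve the amplitude spectrum, mean and variance", {
  set.seed(21)
  for (T_ in c(64, 101)) {               # even and odd lengths
    x <- as.numeric(arima.sim(list(ar = 0.8), T_))
    s <- phase_randomize(x, method = "ft")
    expect_true(all(abs(s - Re(s)) == 0))
    a0 <- Mod(fft(x)); a1 <- Mod(fft(s))
    expect_lt(max(abs(a1 - a0) / (a0 + 1e-12)), 1e-8)
    expect_equal(mean(s), mean(x), tolerance = 1e-9)   # DC untouched
    expect_equal(var(s), var(x), tolerance = 1e-8)     # Parseval
    expect_false(isTRUE(all.equal(s, x)))
  }
})

test_that("a pure cosine surrogate stays a single-bin cosine", {
  T_ <- 128; k <- 5
  x <- cos(2 * pi * k * (0:(T_ - 1)) / T_)
  set.seed(5)
  s <- phase_randomize(x, "ft")
  a <- Mod(fft(s)) / T_
  on_bins <- sort(a, decreasing = TRUE)[1:2]
  expect_equal(unname(on_bins), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(which(a > 1e-6), c(k + 1L, T_ - k + 1L))
  # still a unit cosine (sampling the shifted phase grid, so ~cos(pi/T) of 1)
  expect_equal(max(abs(s)), 1, tolerance = 1e-3)
})

test_that("aaft surrogates preserve the amplitude distribution exactly", {
  set.seed(8)
  x <- rexp(200)^2                        # strongly non-Gaussian
  s <- phase_randomize(x, "aaft")
  expect_equal(sort(s), sort(x))
  expect_false(isTRUE(all.equal(s, x)))
})

test_that("the surrogate null is reproducible and trace-conserving", {
  z <- znormalize(tiny_traceset(M = 5, T = 200, seed = 3))
  n1 <- surrogate_eigen_null(z, n = 20, seed = 99)
  n2 <- surrogate_eigen_null(z, n = 20, seed = 99)
  expect_identical(n1, n2)                              # bitwise determinism
  n3 <- surrogate_eigen_null(z, n = 20, seed = 100)
  expect_false(identical(n1$samples, n3$samples))
  expect_true(all(abs(rowSums(n1$samples) - 5) < 2e-3)) # each spectrum sums to M
  expect_equal(sum(n1$mean_eigs), 5, tolerance = 2e-3)
  expect_true(all(n1$sd_eigs >= 0))
  expect_true(all(diff(n1$mean_eigs) <= 1e-12))         # rank-sorted descending
})

test_that("phase randomization destroys inter-channel synchrony", {
  # two identical channels: surrogate correlation averages to zero
  set.seed(13)
  T_ <- 256; N <- 60
  x <- as.numeric(arima.sim(list(ar = 0.5), T_))
  r12 <- replicate(N, {
    s1 <- phase_randomize(x); s2 <- phase_randomize(x)
    cor(s1, s2)
  })
  expect_lt(abs(mean(r12)), 3 / sqrt(N * T_) * 5)
})

test_that("cluster counting applies the per-rank mean + K*SD rule", {
  es <- fake_eigen(c(4.0, 0.9, 0.6))
  null <- fake_null(c(1.5, 1.0, 0.8), c(0.2, 0.1, 0.1))
  dec <- count_clusters(es, null, K = 3)
  expect_identical(dec$n_clusters, 1L)                  # 4.0 > 1.5 + 0.6
  expect_identical(dec$significant_indices, 1L)
  # strict inequality: equality at the mean is not significant
  es0 <- fake_eigen(c(1.5, 1.0, 0.8))
  dec0 <- count_clusters(es0, fake_null(c(1.5, 1.0, 0.8), c(0, 0, 0)))
  expect_identical(dec0$n_clusters, 0L)
  expect_error(count_clusters(es, fake_null(c(1, 1), c(0, 0))), "mismatch")
})

test_that("detection turns on monotonically with shared-waveform gain", {
  # small grid: gain 0 (noise only) -> 0 clusters; strong gain -> 1 cluster
  run_gain <- function(amp, seed) {
    spec <- synth_spec(n_ap = 6, n_ml = 4, pitch_mm = 0.5, ml_origin = 0,
                       ap_origin = 0, fs = 4000, duration_ms = 50,
                       clusters = list(list(center = c(0.75, 1.25),
                                            radius_mm = 0.75,
                                            n1_amp_uV = 0.43 * amp,
                                            p1_amp_uV = amp)),
                       noise_sd_uV = 5, seed = seed)
    sim <- synth_generate(spec)
    z <- znormalize(sim$traces)
    es <- eigendecompose(correlation_matrix(z))
    null <- surrogate_eigen_null(z, n = 50, seed = seed)
    list(n = count_clusters(es, null)$n_clusters, top = es$values[1])
  }
  lo <- run_gain(1e-6, 31); hi <- run_gain(60, 31)
  expect_identical(lo$n, 0L)
  expect_identical(hi$n, 1L)
  expect_gt(hi$top, lo$top)
})

test_that("shared-phase diagnostic mode preserves inter-channel correlation", {
  set.seed(17)
  w <- as.numeric(arima.sim(list(ar = 0.9), 300))
  z <- znormalize(rbind(w + rnorm(300, sd = .05), w + rnorm(300, sd = .05),
                        rnorm(300)))
  ind <- surrogate_eigen_null(z, n = 30, seed = 1, shared_phases = FALSE)
  shr <- surrogate_eigen_null(z, n = 30, seed = 1, shared_phases = TRUE)
  # with shared phases the two synchronized channels stay synchronized,
  # keeping the top surrogate eigenvalue near the observed one
  top_obs <- eigendecompose(correlation_matrix(z))$values[1]
  expect_gt(shr$mean_eigs[1], ind$mean_eigs[1])
  expect_gt(shr$mean_eigs[1], 0.8 * top_obs)
})
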