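# independent oracle: naive double-loop equal-time correlation
naive_correlation <- function(z) {
  M <- nrow(z); T_ <- ncol(z)
  C <- matrix(0, M, M)
  for (i in seq_len(M)) for (j in seq_len(M)) {
    s <- 0
    for (k in seq_len(T_)) s <- s + z[i, k] * z[j, k]
    C[i, j] <- s / T_
  }
  C
}

test_that("correlation matrix reproduces perfect, anti- and zero correlation", {
  x <- sin(1:32)
  z1 <- znormalize(rbind(x, x))
  expect_equal(unname(correlation_matrix(z1)$C),
               matrix(1, 2, 2), tolerance = 1e-12)
  z2 <- znormalize(rbind(x, -x))
  expect_equal(correlation_matrix(z2)$C[1, 2], -1, tolerance = 1e-12)
  z3 <- znormalize(rbind(c(1, -1, 1, -1), c(1, 1, -1, -1)))
  expect_equal(correlation_matrix(z3)$C[1, 2], 0, tolerance = 1e-12)
})

test_that("correlation matches the naive double-loop oracle (M <= 4)", {
  set.seed(3)
  for (M in 2:4) {
    z <- znormalize(matrix(rnorm(M * 40), M, 40))
    expect_equal(unname(correlation_matrix(z)$C), naive_correlation(z$data),
                 tolerance = 1e-12)
  }
})

test_that("correlation matrix invariants hold on random data", {
  set.seed(4)
  z <- znormalize(matrix(rnorm(10 * 60), 10, 60))
  C <- correlation_matrix(z)$C
  expect_lt(max(abs(C - t(C))), 1e-10)
  expect_lt(max(abs(diag(C) - 1)), 1e-9)
  expect_true(all(C >= -1 - 1e-9 & C <= 1 + 1e-9))
  expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("eigenvalues match closed forms: identity, rank-1, 2x2 with rho", {
  expect_equal(eigendecompose(diag(3))$values, c(1, 1, 1))
  es <- eigendecompose(matrix(1, 2, 2))
  expect_equal(es$values, c(2, 0), tolerance = 1e-12)
  # 2x2 correlation [[1, rho], [rho, 1]] -> 1 + rho, 1 - rho
  for (rho in c(-0.9, -0.3, 0, 0.5, 0.99)) {
    C <- matrix(c(1, rho, rho, 1), 2, 2)
    expect_equal(eigendecompose(C)$values, c(1 + abs(rho), 1 - abs(rho)),
                 tolerance = 1e-12)
    # roots of the characteristic polynomial (1-l)^2 - rho^2 = 0
    expect_equal(sort(Re(polyroot(c(1 - rho^2, -2, 1)))),
                 sort(eigendecompose(C)$values), tolerance = 1e-8)
  }
})

test_that("eigensystem is orthonormal, trace-conserving, sign-deterministic", {
  ts <- tiny_traceset(M = 8, T = 120, seed = 9)
  es <- eigendecompose(correlation_matrix(znormalize(ts)))
  M <- 8
  expect_equal(sum(es$values), M, tolerance = 1e-6)
  expect_lt(max(abs(crossprod(es$vectors) - diag(M))), 1e-8)
  expect_true(all(diff(es$values) <= 1e-12))
  for (i in seq_len(M))
    expect_gte(es$vectors[which.max(abs(es$vectors[, i])), i], 0)
})

test_that("participation index follows lambda * v^2 and sums to unity", {
  es <- eigendecompose(matrix(1, 2, 2))
  pm <- participation_index(es, 1L)
  expect_equal(unname(pm$PI[, 1]), c(1, 1))      # 2 x (1/sqrt(2))^2
  ts <- tiny_traceset(M = 6, T = 90, seed = 2)
  es6 <- eigendecompose(correlation_matrix(znormalize(ts)))
  pm6 <- participation_index(es6, 1:6)
  expect_true(all(pm6$PI >= 0))
  expect_equal(unname(rowSums(pm6$PI)), rep(1, 6), tolerance = 1e-8)
  expect_error(participation_index(es6, integer(0)), "at least one")
})

test_that("channel permutation permutes C and PI, leaves eigenvalues fixed", {
  ts <- tiny_traceset(M = 5, T = 80, seed = 7)
  z <- znormalize(ts)
  perm <- c(3, 1, 5, 2, 4)
  zp <- znormalize(ts$data[perm, ])
  C <- correlation_matrix(z)$C; Cp <- correlation_matrix(zp)$C
  expect_equal(unname(Cp), unname(C[perm, perm]), tolerance = 1e-12)
  es <- eigendecompose(correlation_matrix(z))
  esp <- eigendecompose(correlation_matrix(zp))
  expect_equal(esp$values, es$values, tolerance = 1e-10)
  pi1 <- participation_index(es, 1L)$PI[, 1]
  pi1p <- participation_index(esp, 1L)$PI[, 1]
  expect_equal(unname(pi1p), unname(pi1[perm]), tolerance = 1e-8)
})

test_that("k duplicated channels among orthogonal ones give lambda_top = k", {
  # two identical channels + one orthogonal: eigenvalues 2, 1, 0
  z <- rbind(c(1, -1, 1, -1), c(1, -1, 1, -1), c(1, 1, -1, -1))
  es <- eigendecompose(correlation_matrix(znormalize(z)))
  expect_equal(es$values, c(2, 1, 0), tolerance = 1e-12)
})
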