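test_that("the PI threshold curve counts channels cumulatively", {
  pm <- fake_pm(c(0.9, 0.5, 0.1))
  cv <- pi_curve(pm)
  expect_equal(cv$thresholds, c(0.9, 0.5, 0.1))
  expect_equal(cv$counts, c(1L, 2L, 3L))
  # repeated values collapse to one threshold; final count is always M
  pm2 <- fake_pm(c(0.4, 0.4, 0.4, 0.4))
  cv2 <- pi_curve(pm2)
  expect_equal(cv2$thresholds, 0.4)
  expect_equal(cv2$counts, 4L)
  pm3 <- fake_pm(runif(20))
  expect_equal(tail(pi_curve(pm3)$counts, 1), 20L)
})

test_that("the knee lands at the junction of two linear segments", {
  # 1 channel per step down to 0.4, then 10 per step: knee at 0.4
  th <- c(seq(1.0, 0.4, by = -0.1), seq(0.3, 0, by = -0.1))
  ct <- c(1:7, 7 + cumsum(rep(10, 4)))
  k <- knee_point(fake_curve(th, ct))
  expect_equal(as.numeric(k), 0.4)
})

test_that("a linear curve has no knee: conservative tie-break plus warning", {
  th <- seq(1, 0, by = -0.25)
  ct <- seq(1, 41, by = 10)
  expect_warning(k <- knee_point(fake_curve(th, ct)), "no clear knee")
  expect_equal(as.numeric(k), 0.75)       # highest-PI interior point
})

test_that("fewer than three distinct PI values is a degenerate curve", {
  expect_error(knee_point(fake_curve(c(0.5, 0.1), c(1L, 4L))),
               class = "degenerate_curve_error")
})

test_that("boundary keeps the max-PI component and reports exact area", {
  g <- square_grid(10)                     # 100 channels, pitch 0.5
  ids <- g$positions$channel_id
  pi <- setNames(rep(0.01, 100), ids)
  # blob A: a 3x3 block containing the global max; blob B: distant 2x2
  blobA <- ids[g$col %in% 1:3 & g$row %in% 1:3]
  blobB <- ids[g$col %in% 8:9 & g$row %in% 8:9]
  pi[blobA] <- 0.5; pi[blobA[5]] <- 0.9; pi[blobB] <- 0.5
  bd <- demarcate_boundary(fake_pm(unname(pi), ids), 1L, g, threshold = 0.4)
  expect_setequal(bd$member_channels, blobA)   # disjoint blob B dropped
  expect_equal(bd$area_mm2, 9 * 0.25)
  expect_false(bd$is_weak)
  # 68 supra-threshold channels at 0.5 mm pitch -> 17 mm^2
  pi68 <- rep(0, 100); pi68[1:68] <- 0.5       # first 68 = contiguous rows
  bd68 <- demarcate_boundary(fake_pm(pi68, ids), 1L, g, threshold = 0.5)
  expect_equal(bd68$area_mm2, 17)
})

test_that("a cluster with max PI below 0.2 is flagged weak", {
  g <- square_grid(3)
  bd <- demarcate_boundary(fake_pm(c(0.15, rep(0.05, 8))), 1L, g,
                           threshold = 0.1)
  expect_true(bd$is_weak)
  expect_equal(bd$max_pi, 0.15)
})

test_that("lowering the threshold never removes a member (monotonicity)", {
  set.seed(33)
  g <- square_grid(6)
  pm <- fake_pm(runif(36))
  prev <- character(0)
  for (thr in seq(0.9, 0.05, by = -0.05)) {
    supra <- pm$channel_ids[pm$PI[, 1] >= thr]
    expect_true(all(prev %in% supra))
    prev <- supra
  }
})

test_that("area scales with the square of the electrode pitch", {
  pi <- c(rep(0.5, 4), rep(0.01, 12))
  g1 <- square_grid(4, pitch = 0.5)
  g2 <- square_grid(4, pitch = 1.0)
  b1 <- demarcate_boundary(fake_pm(pi, g1$positions$channel_id), 1L, g1, 0.4)
  b2 <- demarcate_boundary(fake_pm(pi, g2$positions$channel_id), 1L, g2, 0.4)
  expect_setequal(b1$member_channels, b2$member_channels)
  expect_equal(b2$area_mm2, 4 * b1$area_mm2)
})

test_that("the outline is a closed loop enclosing exactly the members", {
  g <- square_grid(5)
  ids <- g$positions$channel_id
  pi <- setNames(rep(0, 25), ids)
  pi[g$col %in% 1:2 & g$row %in% 1:3] <- 0.6   # 2x3 rectangle of members
  bd <- demarcate_boundary(fake_pm(unname(pi), ids), 1L, g, 0.5)
  expect_length(bd$outline, 1L)
  loop <- bd$outline[[1]]
  expect_equal(unlist(loop[1, ]), unlist(loop[nrow(loop), ]),
               ignore_attr = TRUE)              # closed
  # perimeter of a 1.0 x 1.5 mm rectangle of 0.5 mm cells = 5 mm
  seglen <- sqrt(diff(loop$ml_mm)^2 + diff(loop$ap_mm)^2)
  expect_equal(sum(seglen), 2 * (1.0 + 1.5))
})

test_that("the rendered channel map round-trips through JSON", {
  g <- square_grid(4)
  pm <- fake_pm(seq(0.9, 0.1, length.out = 16), g$positions$channel_id)
  bd <- demarcate_boundary(pm, 1L, g, threshold = 0.5)
  js <- withr::local_tempfile(fileext = ".json")
  map <- render_topography(pm, g, bd, json_path = js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$pi, map$pi)                 # exact serialization
  expect_setequal(back$channel_id[back$member], bd$member_channels)
  map2 <- render_topography(pm, g, bd)
  expect_identical(map, map2)                   # deterministic
})
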