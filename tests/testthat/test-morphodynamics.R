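test_that("medial slice selection follows the 2-of-3 / 3-of-5 rule", {
  zs3 <- array(0, c(4, 4, 3)); for (k in 1:3) zs3[, , k] <- k
  expect_equal(select_medial_slice(zs3), matrix(2, 4, 4))
  zs5 <- array(0, c(4, 4, 5)); for (k in 1:5) zs5[, , k] <- k
  expect_equal(select_medial_slice(zs5), matrix(3, 4, 4))
  one <- matrix(7, 4, 4)
  expect_identical(select_medial_slice(one), one)
  zs2 <- array(0, c(4, 4, 2))
  expect_error(select_medial_slice(zs2), "1, 3 or 5")
  # 4-D input: whole acquisition at once
  zs4 <- array(0, c(3, 3, 3, 2)); zs4[, , 2, 1] <- 5; zs4[, , 2, 2] <- 9
  out <- select_medial_slice(zs4)
  expect_equal(dim(out), c(3, 3, 2))
  expect_equal(out[1, 1, ], c(5, 9))
})

test_that("median filter matches an exhaustive 3x3 oracle and basic cases", {
  cst <- matrix(5, 6, 6)
  expect_equal(median_filter3(cst), cst)
  imp <- matrix(10, 7, 7); imp[4, 4] <- 250
  expect_equal(median_filter3(imp), matrix(10, 7, 7))
  fr <- random_frame(8, 8, seed = 42)
  out <- median_filter3(fr)
  for (i in 2:7) for (j in 2:7)
    expect_equal(out[i, j], median(fr[(i - 1):(i + 1), (j - 1):(j + 1)]))
  expect_error(median_filter3(matrix(0, 2, 5)), "3 x 3")
})

test_that("percentile normalization matches a sort-based oracle", {
  # linear ramp: everything at/above the 97th percentile maps to the max
  ramp <- matrix(seq(0, 255, length.out = 10000), 100, 100)
  out <- normalize_percentile(ramp, p = 97, max_out = 255)
  thr <- quantile(ramp, 0.97)
  expect_true(all(out[ramp >= thr] == 255))
  expect_true(all(diff(out[order(ramp)]) >= 0))  # monotone
  # random frame vs explicit affine oracle
  fr <- random_frame(20, 20, seed = 7)
  out <- normalize_percentile(fr, p = 97)
  srt <- sort(as.numeric(fr))
  pct <- quantile(srt, 0.97, names = FALSE)
  oracle <- pmin((fr - min(fr)) / (pct - min(fr)), 1)
  expect_equal(out, oracle, tolerance = 1e-12)
  # idempotent up to re-estimation of the percentile on the clipped frame
  expect_equal(normalize_percentile(out, p = 97), out, tolerance = 1e-4)
  # degenerate constant frame
  flat <- normalize_percentile(matrix(3, 5, 5))
  expect_true(all(flat == 0))
  expect_true(isTRUE(attr(flat, "degenerate")))
})

test_that("ncc satisfies identity, affine invariance, symmetry, and the oracle", {
  for (s in 1:10) {
    A <- random_frame(8, 8, seed = s)
    expect_equal(ncc(A, A), 1)
  }
  A <- random_frame(8, 8, seed = 1); B <- random_frame(8, 8, seed = 2)
  expect_equal(ncc(A, 2 * A + 10), 1)
  expect_equal(ncc(A, -A), -1)
  expect_equal(ncc(A, B), ncc(B, A))
  for (s in 1:25) {
    A <- random_frame(12, 9, seed = 2 * s); B <- random_frame(12, 9, seed = 2 * s + 1)
    expect_equal(ncc(A, B), ncc_bruteforce(A, B), tolerance = 1e-10)
  }
  # degenerate input yields a flagged missing value, never a silent number
  A <- random_frame(8, 8, seed = 1)
  flat <- matrix(4, 8, 8)
  v <- ncc(flat, A)
  expect_true(is.na(v))
  expect_true(isTRUE(attr(v, "degenerate")))
  # masked NCC only sees pixels inside the mask
  m <- matrix(FALSE, 8, 8); m[3:6, 3:6] <- TRUE
  A2 <- A; A2[!m] <- 99
  expect_equal(ncc(A, A2, mask = m), 1)
})

test_that("ncc_series is 1 at t=0, flags degenerate frames, tracks change", {
  fr <- array(rep(random_frame(16, 10, seed = 3), 4), c(16, 10, 4))
  st <- frame_stack(fr)
  out <- ncc_series(st)
  expect_equal(out$ncc, rep(1, 4))
  expect_equal(out$time_s, c(0, 10, 20, 30))
  # one all-constant frame -> missing entry, others computed
  fr2 <- fr; fr2[, , 3] <- 0
  out2 <- ncc_series(frame_stack(fr2))
  expect_true(is.na(out2$ncc[3]))
  expect_false(anyNA(out2$ncc[-3]))
})

test_that("increasing noise monotonically lowers expected ncc", {
  A <- random_frame(24, 24, seed = 9, maxval = 100)
  sds <- c(5, 20, 60)
  set.seed(11)
  mean_ncc <- vapply(sds, function(s) {
    mean(replicate(100, ncc(A, A + matrix(rnorm(576, 0, s), 24, 24))))
  }, numeric(1))
  expect_true(all(diff(mean_ncc) < 0))
})

test_that("preprocess_stack applies filter then normalization per frame", {
  sim <- simulate_vacuole_sequence(scenario(frame_count = 3, seed = 2))
  pre <- preprocess_stack(sim$stack)
  f1 <- normalize_percentile(median_filter3(sim$stack$frames[, , 2]), p = 97)
  expect_equal(pre$frames[, , 2], f1, tolerance = 1e-12)
  expect_true(max(pre$frames) <= 1)
  # pooled-histogram variant shares one affine map across frames
  pre2 <- preprocess_stack(sim$stack, per_frame = FALSE)
  expect_true(max(pre2$frames) <= 1)
})
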