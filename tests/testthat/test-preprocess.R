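test_that("Hounsfield windowing clamps to the configured range", {
  set.seed(1)
  v <- array(runif(6 * 6 * 4, -1200, 1600), c(6, 6, 4))
  w <- window_hu(v, -200, 200)
  expect_identical(dim(w), dim(v))
  expect_gte(min(w), -200)
  expect_lte(max(w), 200)
  expect_equal(window_hu(array(0, c(2, 2, 1)))[1], 0)       # interior fixed point
  expect_equal(window_hu(array(1000, c(1, 1, 1)))[1], 200)
  expect_equal(window_hu(array(-800, c(1, 1, 1)))[1], -200)
  expect_error(window_hu(v, 200, -200), "invalid config")
  vol <- ct_volume(v, c(0.8, 0.8, 1.5))
  wv <- window_hu(vol)
  expect_s3_class(wv, "ct_volume")
  expect_identical(wv$spacing, vol$spacing)
})

test_that("center crop takes the centered window, extra margin on the high side", {
  m512 <- matrix(seq_len(512 * 512), 512, 512)
  c448 <- center_crop(m512, 448)
  expect_identical(dim(c448), c(448L, 448L))
  expect_identical(c448, m512[33:480, 33:480])      # margins 32 | 32
  m7 <- matrix(seq_len(49), 7, 7)
  c4 <- center_crop(m7, 4)
  expect_identical(c4, m7[2:5, 2:5])                # margins 1 | 2 (odd diff)
  expect_identical(center_crop(m7, 7), m7)          # identity crop
  expect_error(center_crop(m7, 9), "exceeds")
})

test_that("histogram equalization maps pixels to their bin CDF", {
  # hand-computed oracle: 2x2 image with values 0..3, 4 bins over [0, 4)
  img <- matrix(c(0, 1, 2, 3), 2, 2)
  eq <- hist_equalize(img, lo = 0, hi = 4, bins = 4)
  expect_equal(eq, matrix(c(0.25, 0.5, 0.75, 1), 2, 2))
  # constant image stays constant
  expect_equal(hist_equalize(matrix(5, 3, 3)), matrix(1, 3, 3))
  # monotone non-decreasing in input ranks; output within (0, 1]
  set.seed(2)
  x <- matrix(runif(400, -200, 200), 20, 20)
  eq <- hist_equalize(x, -200, 200)
  ord <- order(x)
  expect_true(all(diff(eq[ord]) >= 0))
  expect_gt(min(eq), 0)
  expect_lte(max(eq), 1)
})

test_that("normalize01 rescales to [0,1] and maps constants to zero", {
  set.seed(3)
  x <- matrix(rnorm(100, 50, 30), 10, 10)
  n <- normalize01(x)
  expect_equal(n[which.min(x)], 0)
  expect_equal(n[which.max(x)], 1)
  expect_equal(n, (x - min(x)) / (max(x) - min(x)), tolerance = 1e-12)
  expect_equal(normalize01(matrix(7, 4, 4)), array(0, c(4, 4)))
})

test_that("tumor-slice filtering returns exactly the nonempty slice indices", {
  m <- array(0, c(5, 5, 9))
  expect_identical(filter_tumor_slices(m), integer(0))
  m[3, 3, 3] <- 1
  m[1, 5, 7] <- 1
  expect_identical(filter_tumor_slices(m), c(3L, 7L))
  # brute-force oracle on random sparse masks
  set.seed(4)
  for (rep in 1:10) {
    m <- array(as.numeric(runif(4 * 4 * 12) < 0.02), c(4, 4, 12))
    oracle <- which(vapply(1:12, function(t) any(m[, , t] > 0), logical(1)))
    expect_identical(filter_tumor_slices(m), oracle)
  }
})

test_that("2.5D stacks follow the center/zero-fill index rule exhaustively", {
  # exhaustive check over D <= 10, n in {1,3,5,7}, all center slices
  for (D in c(1, 2, 3, 5, 10)) {
    set.seed(D)
    v <- array(rnorm(4 * 4 * D), c(4, 4, D))
    for (n in c(1L, 3L, 5L, 7L)) {
      for (t in seq_len(D)) {
        st <- build_stack(v, t, n)
        expect_identical(dim(st), c(n, 4L, 4L))
        half <- n %/% 2L
        for (k in seq_len(n)) {
          s <- t + k - 1L - half
          expected <- if (s >= 1L && s <= D) v[, , s] else matrix(0, 4, 4)
          expect_equal(st[k, , ], expected)
        }
        # zero channel count matches the brute-force out-of-range count
        src <- t + seq_len(n) - 1L - half
        n_zero_expected <- sum(src < 1L | src > D)
        is_zero <- vapply(seq_len(n), function(k) all(st[k, , ] == 0), logical(1))
        n_zero <- sum(is_zero & vapply(
          seq_len(n), function(k) {
            s <- t + k - 1L - half; s < 1L || s > D || all(v[, , s] == 0)
          }, logical(1)))
        expect_gte(n_zero, n_zero_expected)
        expect_equal(st[half + 1L, , ], v[, , t])   # center channel exact
      }
    }
  }
  v <- array(rnorm(4 * 4 * 20), c(4, 4, 20))
  st <- build_stack(v, 6, 5)   # channels are slices 4..8
  for (k in 1:5) expect_equal(st[k, , ], v[, , 3 + k])
  expect_error(build_stack(v, 0, 3), "out of range")
  expect_error(build_stack(v, 21, 3), "out of range")
  expect_error(build_stack(v, 5, 2), "invalid config")
})

test_that("windowing commutes with cropping", {
  set.seed(5)
  v <- matrix(runif(30 * 30, -1000, 1000), 30, 30)
  a <- center_crop(window_hu(v, -200, 200), 20)
  b <- window_hu(center_crop(v, 20), -200, 200)
  expect_identical(a, b)
})

test_that("preprocess_case emits one aligned stack per retained slice", {
  set.seed(6)
  D <- 10L
  v <- array(runif(40 * 40 * D, -300, 300), c(40, 40, D))
  m <- array(0, c(40, 40, D))
  m[18:24, 18:24, 4] <- 1
  m[10:13, 25:30, 7] <- 1
  cfg <- preprocess_config(crop_size = 32, n_slices = 3)
  samples <- preprocess_case(v, m, cfg)
  expect_length(samples, 2L)   # exactly the tumor slices
  expect_identical(vapply(samples, `[[`, integer(1), "center_index"), c(4L, 7L))
  for (s in samples) {
    expect_identical(dim(s$stack), c(3L, 32L, 32L))
    # mask alignment: emitted mask == center_crop of that slice's mask
    expect_identical(s$mask, center_crop(m[, , s$center_index], 32))
  }
  # keep all slices at inference
  cfg_all <- preprocess_config(crop_size = 32, n_slices = 3,
                               keep_only_tumor_slices = FALSE)
  expect_length(preprocess_case(v, m, cfg_all), D)
  # no tumor voxels -> empty sequence
  expect_length(preprocess_case(v, array(0, dim(v)), cfg), 0L)
  # determinism: bit-identical reruns
  s2 <- preprocess_case(v, m, cfg)
  expect_identical(samples, s2)
})

test_that("preprocessed intensities are normalized per slice", {
  set.seed(7)
  v <- array(runif(48 * 48 * 4, -500, 500), c(48, 48, 4))
  m <- array(0, dim(v)); m[20, 20, 2] <- 1
  s <- preprocess_case(v, m, preprocess_config(crop_size = 48, n_slices = 1))
  expect_gte(min(s[[1]]$stack), 0)
  expect_lte(max(s[[1]]$stack), 1)
})
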