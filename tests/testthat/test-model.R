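test_that("parameter counting matches a layer-by-layer hand sum on a tiny config", {
  # depth 3, plan (8, 16, 32), n = 1, SE reduction 4: sum every tensor by hand.
  cbr <- function(k, cin, cout) k * k * cin * cout + 2 * cout  # bias-free conv + BN
  ris <- function(cin, cout) {
    w <- cout %/% 4; w1 <- cout - 3 * w; cb <- max(cout %/% 4, 1)
    cbr(1, cin, w1) + cbr(3, w1, w) + cbr(3, w, w) + cbr(3, w, w) + cbr(3, w, w) +
      cbr(1, cout, cout) + (cout * cb + cb + cb * cout + cout) +
      (cin * cout + 2 * cout)
  }
  hand <- ris(1, 8) + ris(8, 16) + ris(16, 32) +
    (4 * 32 * 16 + 16) + ris(32, 16) +
    (4 * 16 * 8 + 8) + ris(16, 8) +
    (8 * 1 + 1)
  cfg <- model_config(n_slices = 1, depth = 3, channel_plan = c(8, 16, 32),
                      se_reduction = 4)
  expect_identical(count_parameters(cfg, "count"), hand)
  # the formula agrees with the actually allocated tensors
  m <- ris_unet(cfg, seed = 1)
  expect_identical(count_parameters(m, "count"), count_parameters(cfg, "count"))
})

test_that("parameter count grows faster than 2x when widths double", {
  c1 <- count_parameters(model_config(depth = 3, channel_plan = c(8, 16, 32)), "count")
  c2 <- count_parameters(model_config(depth = 3, channel_plan = c(16, 32, 64)), "count")
  expect_gt(c2, 2 * c1)
})

test_that("forward pass preserves spatial shape and stays in (0,1)", {
  m <- tiny_model(seed = 2)
  for (hw in list(c(16, 16), c(32, 16), c(48, 32))) {
    set.seed(hw[1])
    x <- array(rnorm(3 * hw[1] * hw[2]), c(3, hw[1], hw[2]))
    p <- model_forward(m, x)
    expect_identical(dim(p), as.integer(hw))
    expect_gt(min(p), 0)
    expect_lt(max(p), 1)
  }
  # indivisible sizes are rejected with the constraint named
  x <- array(rnorm(3 * 18 * 18), c(3, 18, 18))
  expect_error(model_forward(m, x), "divisible")
  # inference is deterministic
  x <- array(rnorm(3 * 16 * 16), c(3, 16, 16))
  expect_identical(model_forward(m, x), model_forward(m, x))
})

test_that("the single-slice configuration runs as a plain 2D model", {
  m <- tiny_model(n_slices = 1, seed = 3)
  x <- array(rnorm(1 * 64 * 64), c(1, 64, 64))
  p <- model_forward(m, x)
  expect_identical(dim(p), c(64L, 64L))
  expect_true(all(p > 0 & p < 1))
})

test_that("SE attention matches a hand-computed forward pass", {
  # 2 channels, 2x2 spatial, bottleneck width 1, hand-set weights
  P <- new.env()
  P[["se.w1"]] <- matrix(c(0.5, -0.25), 2, 1)
  P[["se.b1"]] <- 0.1
  P[["se.w2"]] <- matrix(c(1, -2), 1, 2)
  P[["se.b2"]] <- c(0.2, -0.1)
  x <- array(c(1, 2, 3, 4, -1, 0, 1, 2), c(2, 2, 2, 1))
  s <- c(mean(x[, , 1, 1]), mean(x[, , 2, 1]))           # (2.5, 0.5)
  h <- max(0, 0.5 * s[1] - 0.25 * s[2] + 0.1)            # 1.225
  wgt <- 1 / (1 + exp(-(c(1, -2) * h + c(0.2, -0.1))))
  out <- risunet:::.se_fw(P, "se", x)
  expect_equal(out$out[, , 1, 1], x[, , 1, 1] * wgt[1], tolerance = 1e-12)
  expect_equal(out$out[, , 2, 1], x[, , 2, 1] * wgt[2], tolerance = 1e-12)
  # attention never amplifies: |out| <= |in| elementwise
  set.seed(4)
  m <- tiny_model(seed = 4)
  xr <- array(abs(rnorm(8 * 4 * 4)), c(4, 4, 8, 1))
  P2 <- m$P
  se_out <- risunet:::.se_fw(P2, "enc1.se", array(rnorm(8 * 4 * 4 * 2), c(4, 4, 8, 2)))
  expect_true(all(abs(se_out$out) <= abs(se_out$cache$x) + 1e-15))
  # constant channel pools to its value
  xc <- array(0, c(3, 3, 2, 1)); xc[, , 1, 1] <- 7; xc[, , 2, 1] <- -2
  expect_equal(as.numeric(risunet:::.channel_means(xc)), c(7, -2))
})

test_that("the F3 tap has a 7x7 receptive field by gradient-support probe", {
  # chain: 1x1 conv (F1) -> 3x3 (F2) -> 3x3 -> 3x3 (F3); probe with strictly
  # positive weights and eval-mode batch norm so support is exact
  m <- tiny_model(seed = 5)
  P <- m$P; S <- m$S
  for (nm in ls(P)) P[[nm]] <- abs(P[[nm]]) + 1e-3
  H <- 15L
  x <- array(abs(rnorm(3 * H * H)) + 0.1, c(H, H, 3, 1))
  c1 <- risunet:::.cbr_fw(P, S, "enc1.f1", x, training = FALSE)
  c2 <- risunet:::.cbr_fw(P, S, "enc1.f2", c1$out, training = FALSE)
  c3a <- risunet:::.cbr_fw(P, S, "enc1.f3a", c2$out, training = FALSE)
  c3b <- risunet:::.cbr_fw(P, S, "enc1.f3b", c3a$out, training = FALSE)
  G <- new.env()
  gy <- c3b$out * 0
  ctr <- 8L
  gy[ctr, ctr, 1, 1] <- 1
  g3a <- risunet:::.cbr_bw(P, G, S, "enc1.f3b", c3b$cache, gy)
  g2 <- risunet:::.cbr_bw(P, G, S, "enc1.f3a", c3a$cache, g3a)
  g1 <- risunet:::.cbr_bw(P, G, S, "enc1.f2", c2$cache, g2)
  gx <- risunet:::.cbr_bw(P, G, S, "enc1.f1", c1$cache, g1)
  support <- apply(abs(gx[, , , 1]) > 0, c(1, 2), any)
  on_rows <- which(apply(support, 1, any))
  on_cols <- which(apply(support, 2, any))
  expect_identical(range(on_rows), c(ctr - 3L, ctr + 3L))   # 7 rows
  expect_identical(range(on_cols), c(ctr - 3L, ctr + 3L))   # 7 cols
  expect_true(all(support[on_rows, on_cols]))
})

test_that("with SE gate open and residual zeroed the block reduces to the fused path", {
  m <- tiny_model(seed = 6)
  P <- m$P; S <- m$S
  # open the SE gate (sigmoid -> ~1) and zero the residual projection
  P[["enc1.se.w1"]][] <- 0
  P[["enc1.se.b1"]][] <- 0
  P[["enc1.se.w2"]][] <- 0
  P[["enc1.se.b2"]][] <- 30          # sigmoid(30) = 1 - 9e-14
  P[["enc1.res.w"]][] <- 0
  set.seed(6)
  x <- array(rnorm(3 * 8 * 8), c(8, 8, 3, 1))
  full <- risunet:::.ris_fw(P, S, "enc1", x, training = FALSE)
  # hand-wired fused multi-scale path alone
  c1 <- risunet:::.cbr_fw(P, S, "enc1.f1", x, FALSE)
  c2 <- risunet:::.cbr_fw(P, S, "enc1.f2", c1$out, FALSE)
  c3a <- risunet:::.cbr_fw(P, S, "enc1.f3a", c2$out, FALSE)
  c3b <- risunet:::.cbr_fw(P, S, "enc1.f3b", c3a$out, FALSE)
  pl <- risunet:::cpp_maxpool3s1_fw(c3b$out)
  c4 <- risunet:::.cbr_fw(P, S, "enc1.f4", pl$y, FALSE)
  cat_ <- risunet:::.concat_c(list(c1$out, c2$out, c3b$out, c4$out))
  fused <- risunet:::.cbr_fw(P, S, "enc1.fuse", cat_, FALSE)$out
  # residual path is conv(0) -> BN: contributes only BN's constant shift,
  # which is zero at initialization (beta = 0, running mean 0)
  expect_equal(full$out, fused, tolerance = 1e-10)
})

test_that("every trainable parameter receives a gradient", {
  m <- tiny_model(seed = 7)
  set.seed(7)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  fw <- risunet:::.model_fw(m, x, training = TRUE)
  G <- risunet:::.model_bw(m, fw$cache, hybrid_loss_grad(fw$prob, y, loss_config()))
  for (nm in ls(m$P)) {
    expect_false(is.null(G[[nm]]), info = nm)
    expect_gt(max(abs(G[[nm]])), 0)
  }
})

test_that("backprop through the whole network matches finite differences", {
  m <- tiny_model(seed = 8)
  set.seed(8)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  cfg <- loss_config()
  lossfun <- function() {
    fw <- risunet:::.model_fw(m, x, training = TRUE)
    hybrid_loss(fw$prob, y, cfg)
  }
  fw <- risunet:::.model_fw(m, x, training = TRUE)
  G <- risunet:::.model_bw(m, fw$cache, hybrid_loss_grad(fw$prob, y, cfg))
  set.seed(9)
  for (nm in sample(ls(m$P), 6)) {
    i <- sample(length(m$P[[nm]]), 1)
    eps <- 1e-5
    orig <- m$P[[nm]][i]
    m$P[[nm]][i] <- orig + eps; lp <- lossfun()
    m$P[[nm]][i] <- orig - eps; lm_ <- lossfun()
    m$P[[nm]][i] <- orig
    num <- (lp - lm_) / (2 * eps)
    expect_equal(G[[nm]][i], num, tolerance = 2e-3, info = nm)
  }
})

test_that("checkpoints round-trip to identical predictions", {
  m <- tiny_model(seed = 10)
  set.seed(10)
  x <- array(rnorm(3 * 16 * 16), c(3, 16, 16))
  p1 <- model_forward(m, x)
  path <- tempfile(fileext = ".rds")
  save_risunet(m, path)
  m2 <- load_risunet(path)
  expect_identical(model_forward(m2, x), p1)
  expect_identical(m2$config, m$config)
  unlink(path)
})

test_that("model printing reports the architecture and budget", {
  m <- tiny_model(seed = 11)
  expect_output(print(m), "Res-Inception-SE")
  expect_output(print(m), "8-16-32")
  df <- summary(m)
  expect_true(is.data.frame(df) && nrow(df) > 50)
})
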