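make_sample <- function(seed = 1, n = 3L, hw = 16L) {
  set.seed(seed)
  list(stack = array(rnorm(n * hw * hw), c(n, hw, hw)),
       mask = matrix(rbinom(hw * hw, 1, 0.2), hw, hw))
}

test_that("augmentation is identity when disabled and involutive for flips", {
  s <- make_sample(1)
  a <- augment(s$stack, s$mask, list(random_crop = FALSE, hflip = FALSE, vflip = FALSE))
  expect_identical(a$stack, s$stack)
  expect_identical(a$mask, s$mask)
  # an explicit double horizontal flip restores the input
  d <- dim(s$stack)
  flipped <- s$stack[, , d[3]:1, drop = FALSE]
  expect_identical(flipped[, , d[3]:1, drop = FALSE], s$stack)
})

test_that("flips transform stack and mask together", {
  s <- make_sample(2)
  found <- FALSE
  set.seed(3)
  for (i in 1:20) {
    a <- augment(s$stack, s$mask, list(random_crop = FALSE, hflip = TRUE, vflip = FALSE))
    if (!identical(a$stack, s$stack)) {
      d <- dim(s$stack)
      expect_identical(a$stack, s$stack[, , d[3]:1, drop = FALSE])
      expect_identical(a$mask, s$mask[, ncol(s$mask):1, drop = FALSE])
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("segmentation metrics are equivariant under flips", {
  set.seed(4)
  A <- random_mask(c(10, 10, 6), 0.3)
  B <- random_mask(c(10, 10, 6), 0.3)
  Af <- A[, 10:1, ]; Bf <- B[, 10:1, ]
  sp <- c(0.9, 1.2, 2.0)
  expect_identical(dpc(A, B), dpc(Af, Bf))
  expect_identical(voe(A, B), voe(Af, Bf))
  expect_identical(ravd(A, B), ravd(Af, Bf))
  expect_equal(assd(A, B, sp), assd(Af, Bf, sp), tolerance = 1e-12)
  expect_equal(rmsd(A, B, sp), rmsd(Af, Bf, sp), tolerance = 1e-12)
})

test_that("random-crop augmentation preserves shapes and binarity", {
  s <- make_sample(5)
  set.seed(6)
  a <- augment(s$stack, s$mask, list(random_crop = TRUE, hflip = FALSE, vflip = FALSE))
  expect_identical(dim(a$stack), dim(s$stack))
  expect_identical(dim(a$mask), dim(s$mask))
  expect_true(all(a$mask %in% c(0, 1)))
})

test_that("training is deterministic under a fixed seed and reduces the loss", {
  samples <- lapply(1:6, function(i) {
    ph <- generate_phantom(phantom_config(shape = c(32L, 32L, 8L),
                                          liver_axes = rbind(c(10, 12), c(9, 11), c(3, 3.5)),
                                          tumor_radius = c(2.2, 2.8),
                                          tumor_hu = c(-20, 5), noise_sd = 1),
                           seed = 100 + i)
    preprocess_case(ph$volume, ph$tumor, preprocess_config(crop_size = 32, n_slices = 3))
  })
  samples <- unlist(samples, recursive = FALSE)
  cfg <- train_config(max_steps = 12, epochs = 100, batch_size = 4, seed = 39)
  run <- function() {
    m <- tiny_model(seed = 39)
    train_risunet(m, samples, cfg = cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_lt(tail(f1$history$train_loss, 1), f1$history$train_loss[1])
})

test_that("predictions are invariant to slice batching and round-trip checkpoints", {
  ds <- small_dataset(seed = 41)
  ph <- ds$cases[[1]]
  m <- tiny_model(seed = 12)
  pcfg <- preprocess_config(crop_size = 32, n_slices = 3)
  p1 <- predict_volume(m, ph$volume, pcfg, batch_size = 3)
  p2 <- predict_volume(m, ph$volume, pcfg, batch_size = 8)
  expect_identical(p1, p2)
  expect_identical(dim(p1), dim(ph$volume$data))
  path <- tempfile(fileext = ".rds")
  save_risunet(m, path)
  expect_identical(predict_volume(load_risunet(path), ph$volume, pcfg), p1)
  unlink(path)
  # a model biased to large negative logits predicts the empty mask
  m$P[["final.w"]][] <- 0
  m$P[["final.b"]][] <- -50
  expect_equal(sum(predict_volume(m, ph$volume, pcfg)), 0)
  # config/model slice mismatch is caught with both values named
  expect_error(predict_volume(m, ph$volume, preprocess_config(crop_size = 32, n_slices = 5)),
               "n_slices")
})

test_that("the slice-count harness produces one metrics row per n", {
  ds <- small_dataset(n_cases = 4L, seed = 51)
  out <- run_slice_grid(n_values = c(1L, 3L),
                        dataset = ds,
                        model_base = model_config(depth = 3, channel_plan = c(8, 16, 32),
                                                  se_reduction = 4),
                        pre_cfg = preprocess_config(crop_size = 32, n_slices = 3),
                        train_cfg = train_config(max_steps = 4, epochs = 10,
                                                 batch_size = 4, seed = 39))
  expect_identical(out$n_slices, c(1L, 3L))
  expect_identical(colnames(out), c("n_slices", "dpc", "voe", "ravd", "assd", "rmsd"))
  expect_true(all(is.finite(out$dpc)))
  expect_error(run_slice_grid(n_values = c(2L), dataset = ds), "odd")
})

test_that("training writes a per-epoch log and aborts on divergence", {
  s <- list(make_sample(7, hw = 16L))
  m <- tiny_model(seed = 13)
  log <- tempfile(fileext = ".csv")
  fit <- train_risunet(m, s, cfg = train_config(max_steps = 2, epochs = 2,
                                                batch_size = 1, seed = 1),
                       log_path = log)
  h <- utils::read.csv(log)
  expect_identical(names(h), c("epoch", "step", "train_loss", "val_dpc"))
  expect_identical(nrow(h), 2L)
  unlink(log)
  # a destroyed model diverges and is reported, not silently continued
  m$P[["final.w"]][] <- NaN
  expect_error(train_risunet(m, s, cfg = train_config(max_steps = 1, seed = 1)),
               "non-finite")
})

test_that("training configs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("lr: 0.001", "batch_size: 4", "epochs: 20", "seed: 7",
               "loss:", "  alpha: 0.5", "  beta: 2.0",
               "augmentation:", "  hflip: true"), path)
  cfg <- read_train_config(path)
  expect_equal(cfg$lr, 0.001)
  expect_identical(cfg$batch_size, 4L)
  expect_identical(cfg$seed, 7L)
  expect_equal(cfg$loss$alpha, 0.5)
  expect_equal(cfg$loss$beta, 2.0)
  expect_true(cfg$augmentation$hflip)
  expect_false(cfg$augmentation$vflip)
  unlink(path)
})
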