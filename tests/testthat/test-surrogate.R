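test_that("convolution/pool length arithmetic matches the architecture", {
  scfg <- surrogate_config()
  expect_identical(compressed_length(512L, scfg), 21L)
  # monotone in the input length
  lens <- vapply(64:300, compressed_length, integer(1), cfg = scfg)
  expect_true(all(diff(lens) >= 0))
  # boundary: smallest input yielding one compressed step
  n_min <- min(which(vapply(1:200, compressed_length, integer(1),
                            cfg = scfg) >= 1L))
  expect_identical(compressed_length(n_min, scfg), 1L)
  expect_identical(compressed_length(n_min - 1L, scfg), 0L)
})

test_that("formula length equals the network's actual emitted length", {
  # oracle equivalence: run the convolutional front-end alone on varying
  # input lengths and compare its output length against the arithmetic
  set.seed(12)
  params <- sixmass:::init_crnn_params(tiny_scfg())
  for (n_in in c(64L, 65L, 100L, 233L, 512L, 777L, 1024L)) {
    x1 <- array(rnorm(2 * n_in), c(2, n_in, 1))
    c1 <- sixmass:::conv1d_fwd(x1, params$conv1_W, params$conv1_b, 3L, 3L)
    p1 <- sixmass:::maxpool2_fwd(sixmass:::relu_fwd(c1$out)$out)
    c2 <- sixmass:::conv1d_fwd(p1$out, params$conv2_W, params$conv2_b, 3L, 2L)
    p2 <- sixmass:::maxpool2_fwd(sixmass:::relu_fwd(c2$out)$out)
    expect_identical(dim(p2$out)[2], compressed_length(n_in))
  }
})

test_that("preprocessing obeys the shape, sign and determinism contracts", {
  ds <- micro_dataset()
  tr <- ds$records[[1]]$traj
  scfg <- surrogate_config()
  pp <- preprocess_trajectories(tr, scfg, training = FALSE)
  expect_identical(dim(pp$x), c(6L, 512L))
  expect_true(all(pp$x[1:3, ] <= 0))
  expect_true(all(pp$x[4:6, ] >= 0))
  # eval mode: deterministic, equals the raw first eligible window after
  # zero-truncation
  pp2 <- preprocess_trajectories(tr, scfg, training = FALSE)
  expect_identical(pp$x, pp2$x)
  raw <- tr$values[, 301:812]
  raw[1:3, ] <- pmin(raw[1:3, ], 0); raw[4:6, ] <- pmax(raw[4:6, ], 0)
  expect_equal(unname(pp$x), unname(raw))
  # zero noise + fixed window: training mode is the raw slice too
  scfg0 <- surrogate_config(noise_level = 0)
  set.seed(1); pp3 <- preprocess_trajectories(tr, scfg0, training = TRUE)
  expect_true(all(pp3$x[1:3, ] <= 0) && all(pp3$x[4:6, ] >= 0))
  # training windows are re-rolled
  set.seed(2)
  starts <- replicate(20, {
    p <- preprocess_trajectories(tr, scfg0, training = TRUE)
    p$x[6, 1]
  })
  expect_gt(length(unique(starts)), 1L)
  # too-short input rejected
  expect_error(preprocess_trajectories(tr$values[, 1:600], scfg), "too short")
  # means are the pre-noise window means
  expect_equal(pp$means, rowMeans(tr$values[, 301:812]),
               ignore_attr = TRUE)
})

test_that("rmsle satisfies its examples and scale invariance", {
  q <- rep(1, 14)
  expect_equal(rmsle(q, q), 0)
  expect_equal(rmsle(q, rep(exp(1), 14)), 1)
  set.seed(3)
  a <- exp(rnorm(14)); b <- exp(rnorm(14))
  expect_equal(rmsle(3.7 * a, 3.7 * b), rmsle(a, b))
  expect_error(rmsle(c(-1, rep(1, 13)), q), "positive")
  # pseudo-metric on sampled triples: symmetry and triangle inequality
  for (i in 1:25) {
    x <- exp(rnorm(14)); y <- exp(rnorm(14)); z <- exp(rnorm(14))
    expect_equal(rmsle(x, y), rmsle(y, x))
    expect_lte(rmsle(x, z), rmsle(x, y) + rmsle(y, z) + 1e-12)
  }
})

test_that("network outputs are positive, shaped B x 14, and batch-independent", {
  set.seed(9)
  scfg <- tiny_scfg()
  params <- sixmass:::init_crnn_params(scfg)
  B <- 5L
  X <- array(rnorm(B * 6 * 512), c(B, 6, 512))
  M <- matrix(rnorm(B * 6), B, 6)
  fw <- sixmass:::crnn_forward_cache(params, X, M, scfg)
  q <- exp(sixmass:::log_prediction(fw$out, scfg$positivity)$logq)
  expect_identical(dim(q), c(B, 14L))
  expect_true(all(q > 0))
  # permuting samples permutes outputs identically
  perm <- c(3L, 1L, 5L, 2L, 4L)
  fw2 <- sixmass:::crnn_forward_cache(params, X[perm, , , drop = FALSE],
                                      M[perm, , drop = FALSE], scfg)
  expect_equal(fw2$out, fw$out[perm, ], tolerance = 1e-12)
  # B = 1 works
  fw1 <- sixmass:::crnn_forward_cache(params, X[1, , , drop = FALSE],
                                      M[1, , drop = FALSE], scfg)
  expect_equal(fw1$out, fw$out[1, , drop = FALSE], tolerance = 1e-12)
  # alternative positivity activations stay positive
  for (act in c("softplus", "softmax")) {
    lp <- sixmass:::log_prediction(fw$out, act)
    expect_true(all(is.finite(lp$logq)))
    if (act == "softmax") expect_equal(rowSums(exp(lp$logq)), rep(1, B))
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(13)
  scfg <- surrogate_config(window_len = 96L, gru_hidden = 4L)
  params <- sixmass:::init_crnn_params(scfg)
  B <- 2L
  X <- array(rnorm(B * 6 * 96), c(B, 6, 96))
  M <- matrix(rnorm(B * 6), B, 6)
  logQ <- matrix(rnorm(B * 14, 0, 0.5), B, 14)
  lossfn <- function(p) {
    fw <- sixmass:::crnn_forward_cache(p, X, M, scfg)
    lp <- sixmass:::log_prediction(fw$out, scfg$positivity)
    sixmass:::rmsle_batch(lp$logq, logQ)$loss
  }
  fw <- sixmass:::crnn_forward_cache(params, X, M, scfg)
  lp <- sixmass:::log_prediction(fw$out, scfg$positivity)
  ls <- sixmass:::rmsle_batch(lp$logq, logQ)
  grads <- sixmass:::crnn_backward(params, ls$d_logq * lp$dlogq_do,
                                   fw$cache, scfg)
  eps <- 1e-6
  for (nm in names(params)) {
    p <- params[[nm]]
    for (ii in sample(length(p), min(3L, length(p)))) {
      pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
      num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      ana <- grads[[nm]][ii]
      expect_lt(abs(num - ana), 1e-6 + 1e-3 * (abs(num) + abs(ana)))
    }
  }
})

test_that("training reduces the loss on a learnable dataset", {
  ds <- micro_dataset(n = 96L, seed = 5L)
  scfg <- surrogate_config(gru_hidden = 8L, seed = 5)
  tcfg <- train_config(batch_size = 32L, max_epochs = 6L, seed = 5L)
  fit <- train_surrogate(ds, scfg, tcfg)
  expect_s3_class(fit, "sixmass_surrogate")
  # smoke monotonicity: the training loss goes down over the first epochs
  tl <- fit$curves$train_rmsle
  expect_lt(tl[length(tl)], tl[1])
  # bookkeeping invariants
  expect_equal(fit$best_val_loss, min(fit$curves$val_rmsle))
  expect_lte(fit$epochs_trained, tcfg$max_epochs)
  expect_identical(nrow(fit$curves), fit$epochs_trained)
  expect_identical(nrow(tidy(fit)), 14L)
  g <- glance(fit)
  expect_equal(g$n_train + g$n_val, length(ds$records))
  # prediction interface: tibble, positive, one row per sample
  pr <- predict(fit, ds)
  expect_true(tibble::is_tibble(pr))
  expect_identical(dim(pr), c(length(ds$records), 14L))
  expect_true(all(as.matrix(pr) > 0))
  # repeated evaluation-mode prediction is deterministic
  expect_identical(pr, predict(fit, ds))
})

test_that("trained surrogates round-trip through their artifact file", {
  ds <- micro_dataset(n = 96L, seed = 5L)
  fit <- train_surrogate(ds, surrogate_config(gru_hidden = 8L),
                         train_config(batch_size = 32L, max_epochs = 2L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_surrogate(fit, path)
  back <- load_surrogate(path)
  expect_identical(predict(back, ds), predict(fit, ds))
  # tampered configuration is rejected by the fingerprint
  broken <- readRDS(path)
  broken$scfg$gru_hidden <- 999L
  saveRDS(broken, path)
  expect_error(load_surrogate(path), "fingerprint")
})

test_that("subperformant runs are excluded by the 10% rule", {
  mk <- function(loss) structure(list(best_val_loss = loss),
                                 class = "sixmass_surrogate")
  runs <- lapply(c(0.10, 0.105, 0.12), mk)
  kept <- exclude_subperformant(runs)
  expect_identical(vapply(kept, `[[`, numeric(1), "best_val_loss"),
                   c(0.10, 0.105))
  expect_length(exclude_subperformant(runs[1]), 1L)
  same <- lapply(rep(0.2, 4), mk)
  expect_length(exclude_subperformant(same), 4L)
})
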