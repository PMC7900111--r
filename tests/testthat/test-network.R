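test_that("network builds are deterministic under a seed", {
  cfg <- network_config(in_channels = 20, base_width = 6, seed = 31)
  a <- build_network(cfg)
  b <- build_network(cfg)
  expect_identical(ildseg:::pack_params(a), ildseg:::pack_params(b))
  c2 <- build_network(network_config(in_channels = 20, base_width = 6, seed = 32))
  expect_false(identical(ildseg:::pack_params(a), ildseg:::pack_params(c2)))
})

test_that("output preserves spatial shape and stays strictly inside (0,1)", {
  set.seed(1)
  for (cfg in list(network_config(in_channels = 20, base_width = 4),
                   network_config(in_channels = 20, base_width = 4,
                                  dilation_rates = c(1, 1)),  # degenerate rates
                   network_config(in_channels = 6, base_width = 3,
                                  n_stages = 1, dilation_rates = 2))) {
    model <- build_network(cfg)
    H <- 64; W <- 64
    ctx <- ildseg:::make_conv_context(H, W, 1L, c(1L, cfg$dilation_rates))
    X <- matrix(rnorm(H * W * cfg$in_channels), H * W, cfg$in_channels)
    p <- ildseg:::network_forward(model, X, ctx)$p
    expect_length(p, H * W)   # one output channel, same spatial extent
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("backprop matches numerical gradients", {
  set.seed(5)
  cfg <- network_config(in_channels = 5, base_width = 3, n_stages = 2,
                        dilation_rates = c(1, 2), seed = 8)
  model <- build_network(cfg)
  H <- 6; W <- 5; B <- 2
  ctx <- ildseg:::make_conv_context(H, W, B, c(1L, cfg$dilation_rates))
  X <- matrix(rnorm(B * H * W * cfg$in_channels), B * H * W)
  y <- as.numeric(runif(B * H * W) < 0.3)

  loss_at <- function(theta) {
    m <- ildseg:::unpack_params(model, theta)
    p <- ildseg:::network_forward(m, X, ctx)$p
    ildseg:::seg_loss(p, y, "bce_dice", 5)$loss
  }
  fwd <- ildseg:::network_forward(model, X, ctx, keep_cache = TRUE)
  ls <- ildseg:::seg_loss(fwd$p, y, "bce_dice", 5)
  g <- ildseg:::network_backward(model, X, fwd$cache, ls$dlogit, ctx)
  grad <- ildseg:::pack_grads(model, g)
  theta <- ildseg:::pack_params(model)

  eps <- 1e-6
  idx <- sort(sample(length(theta), 40))
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    num <- (loss_at(tp) - loss_at(tm)) / (2 * eps)
    expect_lt(abs(num - grad[i]) / max(1e-4, abs(num) + abs(grad[i])), 1e-4)
  }
})

test_that("checkpoints round-trip through JSON", {
  model <- build_network(network_config(in_channels = 8, base_width = 3, seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  save_model(model, f)
  back <- load_model(f)
  expect_equal(ildseg:::pack_params(back), ildseg:::pack_params(model),
               tolerance = 1e-12)
  expect_identical(back$config$dilation_rates, model$config$dilation_rates)
})

make_smoke_phantoms <- function(n, seed0, noise = 0) {
  lapply(seq_len(n), function(i) {
    generate_phantom(tiny_phantom_config(
      seed = derive_seed(seed0, i), noise_sd = noise,
      lesion_count_range = c(1L, 1L), lesion_radius_range = c(3, 5)))
  })
}

test_that("training reduces the loss on noise-free single-lesion phantoms", {
  studies <- make_smoke_phantoms(8, 500)
  model <- build_network(network_config(in_channels = 12, base_width = 5, seed = 3))
  cfg <- train_config(epochs = 5, batch_size = 8, slab_half_width = 1L, seed = 3)
  fit <- train_model(model, studies, cfg)
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  expect_identical(nrow(fit$history), 5L)
})

test_that("training is bit-reproducible and the d=0 policy reproduces a no-dropout model", {
  studies <- make_smoke_phantoms(4, 600, noise = 0.1)
  cfg <- train_config(epochs = 2, batch_size = 8, slab_half_width = 1L,
                      dropout_policy = dropout_policy(0L), seed = 9)
  model <- build_network(network_config(in_channels = 12, base_width = 4, seed = 4))
  fit1 <- train_model(model, studies, cfg)
  fit2 <- train_model(model, studies, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(ildseg:::pack_params(fit1$model), ildseg:::pack_params(fit2$model))
  # the d=0 policy never drops a sequence
  expect_identical(as.integer(fit1$pattern_histogram["0"]),
                   sum(fit1$pattern_histogram))
})

test_that("training aborts on invalid setups with clear diagnostics", {
  studies <- make_smoke_phantoms(2, 700)
  model <- build_network(network_config(in_channels = 12, base_width = 3, seed = 1))
  empty <- studies[[1]]
  empty$ground_truth[] <- 0L
  expect_error(train_model(model, list(empty),
                           train_config(slab_half_width = 1L)),
               "nonempty ground truth")
  expect_error(train_model(model, studies,
                           train_config(slab_half_width = 2L)),
               "channels")
})
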