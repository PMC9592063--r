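# Target transforms, network training, prediction contracts.

test_that("scheme defaults match the published hyperparameters", {
  c1 <- model_config("single_f0", 10)
  expect_equal(c1$learning_rate, 0.001); expect_equal(c1$batch_size, 1024L)
  c2 <- model_config("single_intensity", 10)
  expect_equal(c2$learning_rate, 0.005); expect_equal(c2$batch_size, 2048L)
  c3 <- model_config("multi_f0", 10)
  expect_equal(c3$learning_rate, 0.001); expect_equal(c3$batch_size, 1024L)
  c4 <- model_config("multi_intensity", 10)
  expect_equal(c4$learning_rate, 0.0005); expect_equal(c4$batch_size, 4096L)
  expect_true(c4$batch_norm_first)
  expect_false(any(c1$batch_norm_first, c2$batch_norm_first,
                   c3$batch_norm_first))
  # schemes differ only in transform, defaults and the batch-norm flag
  shared <- c("activation", "max_epochs", "patience", "output_resolution")
  expect_identical(unclass(c1)[shared], unclass(c4)[shared])
})

test_that("target transforms are exact and invertible", {
  st <- speaker_stats(f0_hz = c(100, 150, 200), intensity_db = c(60, 80))
  # speaker-mean reference centres the training targets near 0 ST
  f <- c(110, 150, 190)
  t1 <- transform_targets(f, "st_ref_speaker_mean", st)
  expect_equal(invert_targets(t1, "st_ref_speaker_mean", st), f,
               tolerance = 1e-9)
  expect_equal(transform_targets(90, "st_ref_90hz"), 0)
  expect_equal(transform_targets(180, "st_ref_90hz"), 12)
  t2 <- transform_targets(c(60, 70, 80), "spl_normalized_0_1", st)
  expect_equal(t2, c(0, 0.5, 1))
  expect_equal(invert_targets(t2, "spl_normalized_0_1", st), c(60, 70, 80))
  expect_error(transform_targets(
    1, "spl_normalized_0_1", speaker_stats(intensity_db = c(70, 70))),
    "degenerate")
  expect_error(transform_targets(100, "st_ref_speaker_mean"), "required")
})

test_that("hz/semitone conversion properties", {
  expect_equal(hz_to_semitones(120, 120), 0)
  expect_equal(hz_to_semitones(180, 90), 12)
  with_seed_local(3, x <- runif(1000, 30, 800))
  expect_equal(semitones_to_hz(hz_to_semitones(x, 90), 90), x,
               tolerance = 1e-12)
  # strictly increasing
  xs <- sort(x)
  expect_true(all(diff(hz_to_semitones(xs, 123)) > 0))
  expect_error(hz_to_semitones(-1, 90), "positive")
})

make_linear_problem <- function(n = 2000, d = 8, noise_sd = 0.5, seed = 21) {
  with_seed_local(seed, {
    x <- matrix(rnorm(n * d), n, d)
    w <- rnorm(d)
    y <- drop(x %*% w) + rnorm(n, sd = noise_sd)
    list(x = x, y = y, noise_var = noise_sd^2)
  })
}

test_that("training reaches the noise floor on a linear mapping", {
  p <- make_linear_problem()
  tr <- 1:1600; va <- 1601:2000
  cfg <- model_config("single_intensity", 8, hidden_layers = c(32, 16),
                      batch_size = 256, max_epochs = 150, patience = 25,
                      seed = 5)
  m <- train_model(cfg, p$x[tr, ], p$y[tr], p$x[va, ], p$y[va])
  expect_lt(min(m$history$val_loss), 2 * p$noise_var)
  expect_true(all(is.finite(unlist(m$net$W))))
  expect_gte(nrow(m$history), 1L)
})

test_that("training is reproducible under the same seed", {
  p <- make_linear_problem(n = 400)
  cfg <- model_config("single_f0", 8, hidden_layers = c(16), batch_size = 128,
                      max_epochs = 10, patience = 10, seed = 77)
  st <- speaker_stats(f0_hz = 120)
  m1 <- train_model(cfg, p$x[1:300, ], p$y[1:300], p$x[301:400, ],
                    p$y[301:400], stats = st)
  m2 <- train_model(cfg, p$x[1:300, ], p$y[1:300], p$x[301:400, ],
                    p$y[301:400], stats = st)
  expect_identical(m1$net$W, m2$net$W)
  expect_identical(m1$history, m2$history)
})

test_that("training loss decreases on a noiseless problem", {
  p <- make_linear_problem(n = 1000, noise_sd = 0)
  cfg <- model_config("single_intensity", 8, hidden_layers = c(16),
                      batch_size = 256, max_epochs = 60, patience = 60,
                      seed = 2)
  m <- train_model(cfg, p$x[1:800, ], p$y[1:800], p$x[801:1000, ],
                   p$y[801:1000])
  h <- m$history$train_loss
  # monotone up to plateau tolerance: smoothed curve decreasing overall
  expect_lt(h[length(h)], h[1] / 10)
  thirds <- split(h, cut(seq_along(h), 3, labels = FALSE))
  expect_true(all(diff(vapply(thirds, mean, 0)) < 0))
})

test_that("a tiny set can be memorized", {
  with_seed_local(4, {
    x <- matrix(rnorm(64 * 5), 64, 5)
    y <- rnorm(64)
  })
  cfg <- model_config("single_intensity", 5, hidden_layers = c(64, 32),
                      batch_size = 64, max_epochs = 400, patience = 400,
                      seed = 13)
  m <- train_model(cfg, x, y, x, y)
  pred <- predict(m, x, transformed = TRUE)
  expect_lt(sqrt(mean((pred - y)^2)), 0.1)
})

test_that("prediction contracts: resolution, width check, batch consistency", {
  p <- make_linear_problem(n = 300)
  cfg <- model_config("single_intensity", 8, hidden_layers = c(8),
                      batch_size = 128, max_epochs = 5, patience = 5,
                      seed = 1)
  m <- train_model(cfg, p$x[1:200, ], p$y[1:200], p$x[201:300, ],
                   p$y[201:300])
  out <- predict(m, p$x[201:300, ])
  expect_equal(out, round(out / 0.01) * 0.01, tolerance = 1e-9)
  expect_error(predict(m, p$x[, 1:5]), "width")
  one <- predict(m, p$x[201, , drop = FALSE], transformed = TRUE)
  many <- predict(m, p$x[201:210, ], transformed = TRUE)
  expect_equal(one, many[1], tolerance = 1e-6)
})

test_that("batch norm variant trains and uses running statistics", {
  p <- make_linear_problem(n = 600, seed = 31)
  y01 <- (p$y - min(p$y)) / diff(range(p$y))
  cfg <- model_config("multi_intensity", 8, hidden_layers = c(16),
                      batch_size = 128, max_epochs = 150, patience = 150,
                      seed = 3)
  st <- speaker_stats(intensity_db = range(p$y))
  m <- train_model(cfg, p$x[1:500, ], y01[1:500], p$x[501:600, ],
                   y01[501:600], stats = st)
  expect_true(all(is.finite(m$net$bn$run_mean)))
  pr <- predict(m, p$x[501:600, ], transformed = TRUE)
  expect_lt(mean((pr - y01[501:600])^2), var(y01))
})
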