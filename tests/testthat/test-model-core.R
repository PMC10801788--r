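# Model substrate: construction, training, validation, determinism.

test_that("build_model honors the spec and is reproducible under a seed", {
  spec <- mlp_spec(80, c(16, 16, 16))
  m <- build_model(spec, seed = 1)
  expect_identical(hidden_units(m), c(16L, 16L, 16L))
  m2 <- build_model(spec, seed = 1)
  expect_identical(m$layers, m2$layers)
  m3 <- build_model(spec, seed = 2)
  expect_false(identical(m$layers, m3$layers))
})

test_that("invalid specs are rejected as configuration errors", {
  expect_error(mlp_spec(80, integer(0)), class = "jgrs_config_error")
  expect_error(layer_spec("dense", 0), class = "jgrs_config_error")
  expect_error(
    model_spec("cnn", c(1, 8, 8),
               list(layer_spec("dense", 4), layer_spec("conv", 2))),
    class = "jgrs_config_error"
  )
  expect_error(train_config(epochs = 0), class = "jgrs_config_error")
})

test_that("training separates two linearly separable clusters", {
  ds <- split_8_1_1(generate_embedding_like(n = 600, dim = 10, separation = 6,
                                            seed = 4), 4)
  m <- build_model(mlp_spec(10, c(8, 8)), seed = 4)
  m <- train_model(m, dataset_split(ds, "train"),
                   fast_cfg(epochs = 30))
  expect_gt(validate(m, dataset_split(ds, "validation")), 0.9)
})

test_that("training is deterministic for a fixed model, data and seed", {
  ds <- pinned_dataset(n = 200, seed = 5)
  tr <- dataset_split(ds, "train")
  cfg <- train_config(epochs = 5, seed = 99)
  m0 <- build_model(mlp_spec(10, c(6, 6)), seed = 5)
  a <- train_model(m0, tr, cfg)
  b <- train_model(m0, tr, cfg)
  expect_identical(a$layers, b$layers)
})

test_that("constant-label training reaches the majority-class share", {
  x <- matrix(rnorm(200 * 5), 200, 5)
  y <- rep(1L, 200)
  pair <- as_data_pair(x, y)
  m <- build_model(mlp_spec(5, c(4)), seed = 1)
  m <- train_model(m, pair, fast_cfg(epochs = 15))
  expect_equal(validate(m, pair), 1.0)
})

test_that("validate counts correct predictions and rejects empty splits", {
  ds <- pinned_dataset(n = 300, seed = 6)
  va <- dataset_split(ds, "validation")
  m <- build_model(mlp_spec(10, c(6)), seed = 6)
  # independent count oracle
  pred <- predict(m, va$x, type = "class")
  expect_equal(validate(m, va), sum(pred == va$y) / length(va$y))
  expect_error(validate(m, as_data_pair(va$x[0, , drop = FALSE], integer(0))),
               class = "jgrs_data_error")
  expect_error(validate(m, as_data_pair(va$x[, 1:3], va$y)),
               class = "jgrs_data_error")
})

test_that("fine_tune warm-starts and increments the retrain counter", {
  ds <- split_8_1_1(generate_embedding_like(n = 200, dim = 10, separation = 2,
                                            seed = 7), 7)
  tr <- dataset_split(ds, "train")
  m <- build_model(mlp_spec(10, c(6, 6)), seed = 7)
  reset_call_counters()
  before <- call_counters()$fine_tune
  m2 <- fine_tune(m, tr, fast_cfg())
  expect_identical(call_counters()$fine_tune, before + 1L)
  # warm start: weights evolve smoothly from the current ones rather than
  # being re-initialized, so a short fine-tune leaves them nearby
  expect_false(identical(m$layers[[1]]$W, m2$layers[[1]]$W))
  expect_equal(dim(m$layers[[1]]$W), dim(m2$layers[[1]]$W))
  expect_lt(max(abs(m2$layers[[1]]$W - m$layers[[1]]$W)), 1)
  # a converged model (zero gradient everywhere) is a fixed point
  mp <- pinned_trained_model(pinned_dataset(n = 200, seed = 7),
                             hidden = c(6, 6), seed = 7)
  mp2 <- fine_tune(mp, dataset_split(pinned_dataset(n = 200, seed = 7),
                                     "train"), fast_cfg())
  expect_identical(mp$layers, mp2$layers)
})

test_that("a CNN trains above chance on image-like two-class data", {
  set.seed(8)
  n <- 240
  # class 1 has a bright top-left quadrant
  x <- matrix(rnorm(n * 36), n, 36)
  y <- rep(0:1, each = n / 2)
  bright <- as.vector(outer(1:3, (0:2) * 6, `+`)) # top-left 3x3 block
  x[y == 1, bright] <- x[y == 1, bright] + 2
  spec <- model_spec("cnn", c(1, 6, 6),
                     list(layer_spec("conv", 4, kernel = 3),
                          layer_spec("dense", 8)))
  m <- build_model(spec, seed = 8)
  pair <- as_data_pair(x, y)
  m <- train_model(m, pair, fast_cfg(epochs = 25))
  expect_gt(validate(m, pair), 0.85)
})
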