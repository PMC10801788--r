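# Synthetic dataset generators and splitting.

test_that("calcium-trace datasets have the documented shape and are seeded", {
  ds <- generate_msn_like(msn_gen_params(beta = 114, seed = 41))
  expect_equal(dim(ds$features), c(3000L, 114L))
  expect_true(all(ds$labels %in% 0:1))
  expect_true(all(is.finite(ds$features)))
  ds2 <- generate_msn_like(msn_gen_params(beta = 114, seed = 41))
  expect_identical(ds$features, ds2$features)
  expect_identical(ds$labels, ds2$labels)
  expect_error(generate_msn_like(msn_gen_params(beta = 10, n_informative = 11)),
               class = "jgrs_config_error")
})

test_that("labels persist in time and informative neurons track them", {
  ds <- generate_msn_like(msn_gen_params(beta = 40, n_informative = 10,
                                         seed = 42))
  # temporal persistence: far fewer switches than a memoryless chain
  switches <- sum(diff(ds$labels) != 0)
  expect_lt(switches, 0.25 * 3000)
  # label-coupled neurons correlate with the state, background ones less so
  cors <- abs(apply(ds$features, 2, cor, y = ds$labels))
  expect_gt(mean(cors[1:10]), 2 * mean(cors[11:40]))
})

test_that("a decoder learns informative traces but not null-signal traces", {
  ds <- generate_msn_like(msn_gen_params(beta = 30, n_informative = 10,
                                         noise_sd = 0.05, seed = 43))
  ds <- split_8_1_1(ds, 43)
  m <- build_model(mlp_spec(30, c(16, 16)), seed = 43)
  m <- train_model(m, dataset_split(ds, "train"), fast_cfg(epochs = 30))
  expect_gt(validate(m, dataset_split(ds, "validation")), 0.8)
  # n_informative = 0: labels independent of traces, accuracy near majority.
  # Near-memoryless traces are used here because sample-level splitting of
  # autocorrelated traces leaks temporal fingerprints into validation even
  # without any label-coupled neuron (documented limitation).
  ds0 <- generate_msn_like(msn_gen_params(beta = 30, n_informative = 0,
                                          transient_decay_s = 0.05,
                                          label_persistence_s = 0.5,
                                          seed = 44))
  ds0 <- split_8_1_1(ds0, 44)
  m0 <- build_model(mlp_spec(30, c(16, 16)), seed = 44)
  m0 <- train_model(m0, dataset_split(ds0, "train"), fast_cfg(epochs = 15))
  va <- dataset_split(ds0, "validation")
  maj_val <- max(table(va$y)) / length(va$y)
  expect_lt(abs(validate(m0, va) - maj_val), 0.1)
})

test_that("embedding datasets are balanced with separation-controlled difficulty", {
  ds <- generate_embedding_like()
  expect_equal(dim(ds$features), c(1600L, 80L))
  expect_equal(sum(ds$labels == 0), 800L)
  expect_equal(sum(ds$labels == 1), 800L)
  expect_error(generate_embedding_like(n = 15), class = "jgrs_config_error")
  # separation 0: no signal, a decoder stays near chance
  ds0 <- split_8_1_1(generate_embedding_like(n = 600, dim = 10,
                                             separation = 0, seed = 45), 45)
  m <- build_model(mlp_spec(10, c(8)), seed = 45)
  m <- train_model(m, dataset_split(ds0, "train"), fast_cfg(epochs = 15))
  expect_lt(abs(validate(m, dataset_split(ds0, "validation")) - 0.5), 0.15)
  # large separation: accuracy approaches the Gaussian-overlap bound ~ 1
  ds1 <- split_8_1_1(generate_embedding_like(n = 600, dim = 10,
                                             separation = 10, seed = 46), 46)
  m1 <- build_model(mlp_spec(10, c(8)), seed = 46)
  m1 <- train_model(m1, dataset_split(ds1, "train"), fast_cfg(epochs = 20))
  expect_gt(validate(m1, dataset_split(ds1, "validation")), 0.99)
})

test_that("planted-parity labels need the planted capacity", {
  ds <- generate_planted_subnetwork(n = 1600, dim = 10, seed = 47)
  expect_true(all(ds$labels %in% 0:1))
  # parity is balanced by construction up to sampling noise
  expect_lt(abs(mean(ds$labels) - 0.5), 0.05)
  # no single coordinate is linearly informative about parity
  expect_lt(max(abs(apply(ds$features, 2, cor, y = ds$labels))), 0.1)
})

test_that("the 8:1:1 split partitions the samples with floor-rule sizes", {
  for (n in c(3000L, 1600L, 37L)) {
    sp <- split_8_1_1(n, seed = 48)
    k <- n %/% 10L
    expect_length(sp$validation, k)
    expect_length(sp$test, k)
    expect_length(sp$train, n - 2L * k)
    all_idx <- c(sp$train, sp$validation, sp$test)
    expect_setequal(all_idx, seq_len(n))
    expect_equal(anyDuplicated(all_idx), 0L)
  }
  expect_error(split_8_1_1(9L), class = "jgrs_data_error")
  # attaching to a dataset and extracting pairs
  ds <- split_8_1_1(generate_embedding_like(n = 100, dim = 5, seed = 48), 48)
  expect_equal(nrow(dataset_split(ds, "train")$x), 80L)
  expect_equal(nrow(dataset_split(ds, "validation")$x), 10L)
})

test_that("dataset CSV round-trips", {
  ds <- generate_embedding_like(n = 20, dim = 4, seed = 49)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  expect_equal(unname(back$features), unname(ds$features), tolerance = 1e-12)
  expect_identical(back$labels, ds$labels)
})
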