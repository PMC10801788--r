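# Pruning schedule: midpoint algebra, random cuts, far subphases, GRS, and
# the JGRS driver.

test_that("pruning_midpoint follows the half-distance-with-clamp rule", {
  expect_equal(pruning_midpoint(16, 2), 7)
  expect_equal(pruning_midpoint(3, 2), 1)
  expect_equal(pruning_midpoint(2, 2), 1)
  expect_equal(pruning_midpoint(273, 2), 135)
  expect_error(pruning_midpoint(0, 1), class = "jgrs_config_error")
})

test_that("stage compression rates match the schedule", {
  m <- build_model(mlp_spec(20, c(16, 16, 16)), seed = 1)
  expect_equal(stage_compression_rate("far1", m, c(2, 2, 2)), 21L)
  expect_equal(stage_compression_rate("far2", m, c(2, 2, 2), layer = 2), 7L)
  expect_equal(stage_compression_rate("near", m, c(2, 2, 2)), 1L)
  m9 <- remove_units(m, 1, 1:7)
  expect_equal(stage_compression_rate("far2", m9, c(2, 2, 2), layer = 1), 3L)
  expect_error(stage_compression_rate("far2", m, c(2, 2, 2)),
               class = "jgrs_config_error")
  # layers already at the floor contribute nothing to the sweep CR
  m_floor <- build_model(mlp_spec(20, c(2, 16)), seed = 1)
  expect_equal(stage_compression_rate("far1", m_floor, c(2, 2)), 7L)
})

test_that("random_cut_units is uniform, seedable, and respects bounds", {
  m <- build_model(mlp_spec(5, c(4, 3)), seed = 2)
  a <- random_cut_units(m, 1, 2, seed = 7)
  b <- random_cut_units(m, 1, 2, seed = 7)
  expect_identical(attr(a, "removed_units"), attr(b, "removed_units"))
  expect_identical(hidden_units(a), c(2L, 3L))
  # uniformity: each of 4 units picked ~2500 times over 10000 single cuts
  set.seed(3)
  hits <- tabulate(vapply(seq_len(10000), function(i) {
    attr(random_cut_units(m, 1, 1), "removed_units")
  }, integer(1)), nbins = 4)
  expect_true(all(abs(hits - 2500) <= 150))
})

test_that("far subphase 1 sweeps along the midpoint descent to the floor", {
  ds <- pinned_dataset(seed = 21)
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  m <- pinned_trained_model(ds, seed = 21)
  reset_call_counters()
  r <- far_subphase_1(m, tr, va, c(2, 2, 2), 0.999, fast_cfg(), seed = 121)
  expect_identical(hidden_units(r$model), c(2L, 2L, 2L))
  # widths halve toward the floor: 16 -> 9 -> 6 -> 4 -> 3 -> 2 per layer,
  # one fine-tune + one validate per sweep
  expect_equal(r$trace$cr, c(21, 9, 6, 3, 3))
  expect_equal(r$counters$fine_tune, 5L)
  expect_true(all(r$trace$accepted))
  expect_equal(r$accuracy, 1.0)
})

test_that("a rejected first sweep returns the input model at its accuracy", {
  ds <- pinned_dataset(seed = 22)
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  m <- pinned_trained_model(ds, seed = 22)
  ori <- validate(m, va)
  r <- far_subphase_1(m, tr, va, c(2, 2, 2), val_acc_min = 1.1,
                      fast_cfg(), seed = 122)
  expect_identical(hidden_units(r$model), c(16L, 16L, 16L))
  expect_identical(r$model$layers, m$layers)
  expect_equal(r$accuracy, ori)
  expect_false(any(r$trace$accepted))
})

test_that("far subphase 2 cuts one layer's midpoint per accepted round", {
  ds <- pinned_dataset(seed = 23)
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  m <- pinned_trained_model(ds, seed = 23)
  reset_call_counters()
  r <- far_subphase_2(m, tr, va, c(2, 2, 2), 0.999, fast_cfg(), seed = 123)
  expect_identical(hidden_units(r$model), c(2L, 2L, 2L))
  acc_rounds <- r$trace[r$trace$accepted, ]
  # each accepted round removes exactly one layer's midpoint
  expect_true(all(acc_rounds$units_cut >= 1))
  expect_true(all(acc_rounds$cr == acc_rounds$units_cut))
  # per-round retrains equal the number of prunable layers at that round
  expect_gte(r$counters$fine_tune, nrow(r$trace))
})

test_that("far subphase 2 returns the input unchanged when all layers are at the floor", {
  ds <- pinned_dataset(seed = 24)
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  m <- pinned_trained_model(ds, hidden = c(2, 2), seed = 24)
  reset_call_counters()
  r <- far_subphase_2(m, tr, va, c(2, 2), 0.5, fast_cfg(), seed = 124)
  expect_identical(r$model$layers, m$layers)
  expect_equal(r$counters$fine_tune, 0L)
  expect_equal(nrow(r$trace), 0L)
})

test_that("near-phase GRS removes one unit per accepted iteration", {
  ds <- pinned_dataset(seed = 25)
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  # single prunable layer one unit above the floor: exactly one removal
  m <- pinned_trained_model(ds, hidden = c(3, 2), seed = 25)
  r <- grs_near_phase(m, tr, va, c(2, 2), 0.999, fast_cfg(), seed = 125)
  expect_identical(hidden_units(r$model), c(2L, 2L))
  expect_equal(nrow(r$trace[r$trace$accepted, ]), 1L)
  # full descent: every accepted step cuts exactly one unit
  m2 <- pinned_trained_model(ds, hidden = c(6, 6), seed = 25)
  r2 <- grs_near_phase(m2, tr, va, c(2, 2), 0.999, fast_cfg(), seed = 126)
  expect_identical(hidden_units(r2$model), c(2L, 2L))
  expect_true(all(r2$trace$cr == 1))
  expect_equal(sum(r2$trace$accepted), 8L) # (6-2) + (6-2) removals
})

test_that("jgrs with zero attempts is the identity", {
  ds <- pinned_dataset(seed = 26)
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  m <- pinned_trained_model(ds, hidden = c(8, 8), seed = 26)
  cfg <- pruning_config(c(2, 2), attempts = c(0, 0, 0), seed = 1,
                        train_cfg = fast_cfg())
  r <- jgrs(m, tr, va, cfg)
  expect_identical(r$model$layers, m$layers)
  expect_equal(r$accuracy, r$ori_val_acc)
  expect_equal(nrow(r$trace), 0L)
})

test_that("jgrs chains stages and respects the floor and tolerance", {
  ds <- pinned_dataset(seed = 27)
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  m <- pinned_trained_model(ds, seed = 27)
  cfg <- pruning_config(c(2, 2, 2), tolerance = 0.985, seed = 42,
                        train_cfg = fast_cfg())
  r <- jgrs(m, tr, va, cfg)
  expect_true(all(hidden_units(r$model) >= c(2, 2, 2)))
  expect_gte(r$accuracy, r$val_acc_min)
  expect_true(all(r$trace$stage %in% c("far1", "far2", "near")))
  # sizes are non-increasing along the trace by construction
  expect_lte(param_count(r$model), param_count(m))
})

test_that("jgrs runs are reproducible under a fixed seed", {
  ds <- pinned_dataset(seed = 28)
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  m <- pinned_trained_model(ds, hidden = c(8, 8), seed = 28)
  cfg <- pruning_config(c(2, 2), seed = 7, train_cfg = fast_cfg())
  r1 <- jgrs(m, tr, va, cfg)
  r2 <- jgrs(m, tr, va, cfg)
  expect_identical(r1$model$layers, r2$model$layers)
  expect_identical(r1$trace$unit_indices, r2$trace$unit_indices)
})
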