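test_that("the multi-step schedule drops by gamma at each milestone", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(9, cfg), 1e-4)          # boundary exclusive
  expect_equal(lr_schedule(10, cfg), 0.7e-4)
  expect_equal(lr_schedule(30, cfg), 0.343e-4)
  lrs <- vapply(0:40, lr_schedule, numeric(1), config = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(sum(diff(lrs) < 0), 3L)             # one drop per milestone
  expect_error(train_config(lr_milestones = c(10, 10, 20)), "increasing")
})

test_that("a model that cannot improve stops after `patience` epochs", {
  samples <- small_phantoms(6, seed = 83, size = 24)
  cfg <- train_config(learning_rate = 1e-30, max_epochs = 20, batch_size = 2,
                      seed = 5, loss = loss_config(rep(0.25, 4)))
  fit <- train(surrogate_segmenter(4, seed = 5), samples[1:4], samples[5:6], cfg)
  expect_true(fit$stopped_early)
  expect_equal(max(fit$log$epoch), cfg$early_stop_patience)
  expect_equal(fit$best_epoch, 0L)
  # the returned state is never worse than any recorded val loss
  expect_lte(fit$best_val_loss, min(fit$log$val_loss) + 1e-12)
})

test_that("training is deterministic given the config seed", {
  samples <- small_phantoms(8, seed = 89, size = 24)
  cfg <- train_config(max_epochs = 3, batch_size = 2, seed = 17,
                      loss = loss_config(c(0.1, 0.1, 0.9, 0.7)))
  f1 <- train(surrogate_segmenter(4, seed = 17), samples[1:6], samples[7:8], cfg)
  f2 <- train(surrogate_segmenter(4, seed = 17), samples[1:6], samples[7:8], cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$W, f2$model$W)
  expect_error(train(surrogate_segmenter(4), list(), samples[1:2], cfg),
               "non-empty")
})

test_that("a short training run reduces the validation combined loss", {
  samples <- small_phantoms(16, seed = 97, size = 32)
  cw <- compute_weights(count_classes(lapply(samples[1:12], `[[`, "label_map")))
  cfg <- train_config(max_epochs = 8, batch_size = 1, seed = 7,
                      loss = loss_config(as.numeric(cw)))
  fit <- train(surrogate_segmenter(4, seed = 7), samples[1:12], samples[13:16], cfg)
  expect_lt(fit$best_val_loss, fit$log$val_loss[1])
})

test_that("the truth-in-box oracle is perfect at offset 0; offset list [0] equals evaluate", {
  samples <- small_phantoms(4, seed = 103, size = 40)
  oracle <- oracle_segmenter("truth_in_box")
  ab <- ablate_prompts(oracle, samples, offsets = 0L)
  expect_length(ab, 1)
  expect_equal(ab[["0"]]$dsc, rep(1, 5))
  direct <- evaluate_segmenter(oracle, samples, prompt_config(offset = 0))
  expect_identical(ab[["0"]], direct)
})

test_that("mean DSC degrades monotonically as prompt offsets widen", {
  samples <- small_phantoms(6, seed = 107, size = 40)
  restricted <- ablate_prompts(oracle_segmenter("truth_in_box"), samples)
  expect_named(restricted, c("0", "10", "20"))
  mean_dsc <- vapply(restricted, function(r) r$dsc[r$class == "mean"], numeric(1))
  expect_true(all(diff(mean_dsc) <= 1e-12))       # non-increasing
  # the box-fill oracle over-segments as boxes grow: strictly decreasing
  fill <- ablate_prompts(oracle_segmenter("box_fill"), samples)
  mean_dsc_fill <- vapply(fill, function(r) r$dsc[r$class == "mean"], numeric(1))
  expect_true(all(diff(mean_dsc_fill) < 0))
})

test_that("the loss ablation trains one variant per loss and is reproducible", {
  samples <- small_phantoms(8, seed = 109, size = 24)
  cw <- compute_weights(count_classes(lapply(samples[1:6], `[[`, "label_map")))
  cfg <- train_config(max_epochs = 2, batch_size = 2, seed = 23,
                      loss = loss_config(as.numeric(cw)))
  ab1 <- ablate_losses(samples[1:6], samples[7:8], cfg)
  expect_named(ab1, c("dice", "lovasz", "combined"))
  ab2 <- ablate_losses(samples[1:6], samples[7:8], cfg, variants = "combined")
  expect_identical(ab1$combined, ab2$combined)    # same seed, same variant
})
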