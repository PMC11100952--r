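test_that("the strategy list has the nine named strategies in order", {
  st <- build_strategies()
  expect_length(st, 9)
  expect_equal(vapply(st, `[[`, "", "name"),
               c("Rz", "RC+Rz", "VF+Rz", "HF+Rz", "ROT+Rz", "CMB",
                 "RRC+Rz", "PAD+RC+Rz", "RB+ET+GN+GB"))
  # the stated constants
  expect_equal(st[[2]]$crop, 128L)
  expect_equal(st[[3]]$p, 0.3)
  expect_equal(st[[5]]$limit, 30)
  expect_equal(st[[7]]$scale, c(1.2, 1.4))
  adv <- st[[9]]
  expect_equal(adv$p, 0.5)
  expect_equal(adv$et_alpha, 1)
  expect_equal(adv$et_sigma, 50)
  expect_equal(adv$noise_var, c(10, 50))
  expect_equal(adv$blur_limit, c(3L, 7L))
})

test_that("every strategy emits a target-size sample with a label subset", {
  s <- small_phantoms(1, seed = 8, size = 96)[[1]]
  src_labels <- unique(as.vector(s$label_map))
  for (st in build_strategies(64)) {
    out <- apply_strategy(s, st, seed = 17)
    expect_equal(dim(out$image), c(64L, 64L), info = st$name)
    expect_true(all(unique(as.vector(out$label_map)) %in% src_labels),
                info = st$name)
    expect_true(all(out$image >= 0 & out$image <= 1), info = st$name)
    expect_equal(out$id, paste0(s$id, "__", st$name))
  }
})

test_that("vertical flip reverses rows exactly when the draw fires", {
  s <- small_phantoms(1, seed = 12, size = 64)[[1]]
  st <- build_strategies(64)[[3]]                 # VF+Rz
  base <- apply_strategy(s, build_strategies(64)[[1]], seed = 1)  # Rz reference
  flipped <- none <- 0L
  for (seed in 1:40) {
    out <- apply_strategy(s, st, seed = seed)
    if (identical(lab_mat(out$label_map), lab_mat(base$label_map))) {
      none <- none + 1L
    } else {
      # row-reversal oracle: label map mirrored top-to-bottom
      expect_identical(lab_mat(out$label_map),
                       lab_mat(base$label_map)[64:1, , drop = FALSE])
      expect_equal(out$image, base$image[64:1, , drop = FALSE])
      flipped <- flipped + 1L
    }
  }
  expect_gt(flipped, 0L)   # p = 0.3 fires for some seeds,
  expect_gt(none, 0L)      # no-ops for others, both still emit an output
})

test_that("intensity-only transforms leave the label map untouched", {
  s <- small_phantoms(1, seed = 23, size = 64)[[1]]
  st <- build_strategies(64)[[9]]                 # RB+ET+GN+GB
  for (seed in 1:10) {
    out <- apply_strategy(s, st, seed = seed)
    # ET at alpha 1 / sigma 50 displaces by far less than a pixel, so the
    # nearest-neighbour label map survives the whole advanced set intact
    expect_identical(unclass(out$label_map), unclass(s$label_map))
  }
})

test_that("augment_dataset emits exactly 9 outputs per input, deterministically", {
  expect_length(augment_dataset(list()), 0)
  samples <- small_phantoms(10, seed = 3, size = 48)
  a1 <- augment_dataset(samples, seed = 7)
  expect_length(a1, 90)
  expect_length(augment_dataset(samples[1], seed = 7), 9)
  # identifiers encode source stem + strategy name
  expect_equal(vapply(a1[1:9], `[[`, "", "id"),
               paste0(samples[[1]]$id, "__",
                      vapply(build_strategies(48), `[[`, "", "name")))
  a2 <- augment_dataset(samples, seed = 7)
  expect_identical(a1, a2)
  a3 <- augment_dataset(samples, seed = 8)
  expect_false(identical(a1, a3))
})

test_that("crops larger than the resized image are rejected", {
  s <- small_phantoms(1, seed = 2, size = 32)[[1]]
  st <- build_strategies(32)[[2]]
  st$crop <- 64L
  expect_error(apply_strategy(s, st, seed = 1), "crop")
})
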