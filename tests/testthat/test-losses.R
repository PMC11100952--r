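# two-pixel worked example: truth classes (0, 1), prediction hard class 0
two_pixel_case <- function() {
  truth <- encode_one_hot(label_map(matrix(c(0L, 1L), 1, 2), 2), 2)
  pred <- unclass(encode_one_hot(label_map(matrix(c(0L, 0L), 1, 2), 2), 2))
  list(pred = pred, truth = unclass(truth), w = c(0.5, 0.5))
}

test_that("weighted Dice loss matches its worked examples", {
  z <- two_pixel_case()
  # numerator 2 * 0.5, denominator 2.0 -> loss 0.5
  expect_equal(weighted_dice_loss(z$pred, z$truth, z$w), 0.5, tolerance = 1e-6)

  m <- rand_map(5, 6)
  oh <- unclass(encode_one_hot(m))
  expect_equal(weighted_dice_loss(oh, oh, c(0.1, 0.1, 0.9, 0.7)), 0,
               tolerance = 1e-6)

  # zero predicted mass on every truth class -> loss -> 1 as epsilon -> 0
  truth <- unclass(encode_one_hot(label_map(matrix(0L, 2, 2), 2), 2))
  pred <- unclass(encode_one_hot(label_map(matrix(1L, 2, 2), 2), 2))
  expect_equal(weighted_dice_loss(pred, truth, c(0.5, 0.5), epsilon = 1e-12), 1,
               tolerance = 1e-9)
  expect_error(weighted_dice_loss(pred, truth[, 1:1, , drop = FALSE], c(0.5, 0.5)),
               "shape")
})

test_that("uniform weights reduce the entry-weighted Dice to the standard Dice", {
  set.seed(5)
  for (i in 1:10) {
    m <- rand_map(4, 5)
    truth <- unclass(encode_one_hot(m))
    pred <- rand_prob(4, 4, 5)
    ld <- weighted_dice_loss(pred, truth, rep(0.25, 4), epsilon = 0)
    plain <- 1 - 2 * sum(truth * pred) / sum(truth + pred)
    expect_equal(ld, plain, tolerance = 1e-12)
  }
})

test_that("Lovasz loss matches its worked examples", {
  z <- two_pixel_case()
  # class-0 IoU 1/2, class-1 IoU 0 -> 0.5 * 0.5 + 0.5 * 1 = 0.75
  expect_equal(weighted_lovasz_loss(z$pred, z$truth, z$w), 0.75)

  m <- rand_map(5, 6)
  oh <- unclass(encode_one_hot(m))
  expect_equal(weighted_lovasz_loss(oh, oh, c(0.1, 0.1, 0.9, 0.7)), 0)
})

test_that("Lovasz equals the weighted Jaccard loss at all binary vertices", {
  set.seed(11)
  for (i in 1:200) {
    C <- sample(2:4, 1)
    h <- sample(2:4, 1); w <- sample(2:4, 1)
    truth_m <- rand_map(h, w, C)
    pred_m <- rand_map(h, w, C)
    weights <- runif(C, 0.1, 0.9)
    got <- weighted_lovasz_loss(unclass(encode_one_hot(pred_m, C)),
                                unclass(encode_one_hot(truth_m, C)), weights)
    want <- sum(weights * vapply(seq_len(C) - 1L, function(ci)
      oracle_jaccard_loss(pred_m, truth_m, ci), numeric(1))) / sum(weights)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Lovasz on soft predictions matches the prefix-set extension oracle", {
  set.seed(19)
  for (i in 1:60) {
    C <- sample(2:3, 1)
    h <- sample(1:2, 1); w <- sample(2:3, 1)   # <= 6 pixels
    truth <- unclass(encode_one_hot(rand_map(h, w, C), C))
    pred <- rand_prob(C, h, w)
    weights <- runif(C, 0.1, 0.9)
    got <- weighted_lovasz_loss(pred, truth, weights)
    want <- sum(weights * vapply(seq_len(C), function(ci)
      oracle_lovasz_ext(as.vector(truth[ci, , ]), as.vector(pred[ci, , ])),
      numeric(1))) / sum(weights)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("both losses live in [0, 1] and vanish only at perfect predictions", {
  set.seed(23)
  for (i in 1:30) {
    C <- sample(2:4, 1)
    truth_m <- rand_map(3, 3, C)
    truth <- unclass(encode_one_hot(truth_m, C))
    pred <- rand_prob(C, 3, 3)
    weights <- runif(C, 0.1, 0.9)
    ld <- weighted_dice_loss(pred, truth, weights)
    ll <- weighted_lovasz_loss(pred, truth, weights)
    expect_true(ld >= 0 && ld <= 1)
    expect_true(ll >= 0 && ll <= 1)
    if (!identical(unclass(decode_argmax(pred)), unclass(truth_m)))
      expect_gt(ll, 0)
  }
})

test_that("absent truth classes follow the penalty / skip conventions", {
  truth <- unclass(encode_one_hot(label_map(matrix(0L, 2, 2), 3), 3))
  pred <- rand_prob(3, 2, 2)
  w <- c(0.2, 0.5, 0.8)
  pen <- weighted_lovasz_loss(pred, truth, w, absent_classes = "penalty")
  # penalty term for an absent class is its maximum predicted probability
  t0 <- oracle_lovasz_ext(as.vector(truth[1, , ]), as.vector(pred[1, , ]))
  want <- (w[1] * t0 + w[2] * max(pred[2, , ]) + w[3] * max(pred[3, , ])) / sum(w)
  expect_equal(pen, want, tolerance = 1e-12)
  skip <- weighted_lovasz_loss(pred, truth, w, absent_classes = "skip")
  expect_equal(skip, t0, tolerance = 1e-12)      # only class 0 present
})

test_that("combined loss is the stated alpha/beta mixture", {
  z <- two_pixel_case()
  lv <- combined_loss(z$pred, z$truth, loss_config(z$w))
  expect_equal(lv$dice_term, 0.5, tolerance = 1e-6)
  expect_equal(lv$lovasz_term, 0.75)
  expect_equal(lv$total, 0.625, tolerance = 1e-6)

  proj <- combined_loss(z$pred, z$truth, loss_config(z$w, alpha = 1, beta = 0))
  expect_equal(proj$total, proj$dice_term)

  cfg <- loss_config(z$w)
  expect_equal(cfg$alpha, 0.5)                   # default mixture
  expect_equal(cfg$beta, 0.5)

  # linear in the two terms for arbitrary alpha/beta
  lv2 <- combined_loss(z$pred, z$truth, loss_config(z$w, alpha = 0.3, beta = 1.2))
  expect_equal(lv2$total, 0.3 * lv2$dice_term + 1.2 * lv2$lovasz_term)
})
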