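test_that("DSC matches its set-formula examples", {
  a <- label_map(matrix(c(1L, 1L, 0L, 0L), 2, 2), 2)
  expect_equal(dsc(a, a, 1), 1)
  b <- label_map(matrix(c(0L, 0L, 1L, 1L), 2, 2), 2)
  expect_equal(dsc(a, b, 1), 0)                   # disjoint equal-size sets
  # |A| = |B| = 4, |A intersect B| = 2 -> 0.5
  p <- label_map(rbind(c(1L, 1L, 1L, 1L), c(0L, 0L, 0L, 0L)), 2)
  t_ <- label_map(rbind(c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L)), 2)
  expect_equal(dsc(p, t_, 1), 0.5)
  expect_error(dsc(a, label_map(matrix(0L, 3, 3), 2), 1), "dimensions")
})

test_that("Hausdorff matches the 3-4-5 single-pixel example", {
  m1 <- matrix(0L, 6, 6); m1[1, 1] <- 1L           # (0,0)
  m2 <- matrix(0L, 6, 6); m2[4, 5] <- 1L           # (3,4)
  expect_equal(hausdorff(label_map(m1, 2), label_map(m2, 2), 1), 5)
  expect_equal(hausdorff(label_map(m1, 2), label_map(m1, 2), 1), 0)
})

test_that("directed ASD averages nearest-border distances", {
  p <- matrix(0L, 4, 4); p[1, 1:2] <- 1L           # border {(0,0),(0,1)}
  t_ <- matrix(0L, 4, 4); t_[1, 1] <- 1L           # border {(0,0)}
  expect_equal(asd(label_map(p, 2), label_map(t_, 2), 1), 0.5)  # mean of {0,1}
  # directedness: the reverse direction differs
  expect_equal(asd(label_map(t_, 2), label_map(p, 2), 1), 0)
  expect_equal(asd(label_map(p, 2), label_map(t_, 2), 1, symmetric = TRUE), 0.25)
})

test_that("DSC and HD are symmetric; empty-set conventions hold", {
  set.seed(31)
  a <- rand_map(7, 7, 3); b <- rand_map(7, 7, 3)
  expect_equal(dsc(a, b, 1), dsc(b, a, 1))
  expect_equal(hausdorff(a, b, 2), hausdorff(b, a, 2))
  empty <- label_map(matrix(0L, 7, 7), 3)
  expect_equal(dsc(empty, empty, 2), 1)
  expect_equal(hausdorff(empty, empty, 2), 0)
  expect_equal(asd(empty, empty, 2), 0)
  expect_equal(dsc(a, empty, 1), 0)
  expect_equal(hausdorff(a, empty, 1), sqrt(2) * 6)   # image diagonal
})

test_that("all three metrics match brute-force oracles on random masks", {
  set.seed(53)
  for (i in 1:40) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    C <- sample(2:4, 1)
    p <- rand_map(h, w, C); t_ <- rand_map(h, w, C)
    ci <- sample(0:(C - 1L), 1)
    expect_equal(dsc(p, t_, ci), oracle_dsc(p, t_, ci))
    expect_equal(hausdorff(p, t_, ci), oracle_hd(p, t_, ci), tolerance = 1e-12)
    expect_equal(asd(p, t_, ci), oracle_asd(p, t_, ci), tolerance = 1e-12)
  }
})

test_that("Hausdorff satisfies the triangle inequality on non-empty masks", {
  set.seed(59)
  for (i in 1:15) {
    maps <- replicate(3, rand_map(8, 8, 2), simplify = FALSE)
    hab <- hausdorff(maps[[1]], maps[[2]], 1)
    hbc <- hausdorff(maps[[2]], maps[[3]], 1)
    hac <- hausdorff(maps[[1]], maps[[3]], 1)
    expect_lte(hac, hab + hbc + 1e-12)
  }
})

test_that("evaluate reports per-class metrics plus their unweighted mean", {
  s <- small_phantoms(1, seed = 61, size = 32)[[1]]
  r <- evaluate(s$label_map, s$label_map)
  expect_s3_class(r, "eval_report")
  expect_equal(r$class, c("background", "brain", "CSP", "LV", "mean"))
  expect_equal(r$dsc, rep(1, 5))
  expect_equal(r$hd, rep(0, 5))
  expect_equal(r$asd, rep(0, 5))
  # mean row is the arithmetic average of the four class rows
  p <- rand_map(12, 12); t_ <- rand_map(12, 12)
  r2 <- evaluate(p, t_)
  expect_equal(r2$dsc[5], mean(r2$dsc[1:4]))
  expect_equal(r2$hd[5], mean(r2$hd[1:4]))
})

test_that("the published per-class rows average to the headline triple", {
  fetsam <- data.frame(class = c("background", "brain", "CSP", "LV"),
                       dsc = c(0.99506, 0.98508, 0.8037, 0.82084),
                       hd = c(2.67867, 3.07074, 1.05123, 0.65873),
                       asd = c(0.67628, 0.67105, 0.33891, 0.17955))
  m <- aggregate_mean(fetsam)
  expect_equal(round(m$dsc[5], 5), 0.90117)
  expect_equal(round(m$hd[5], 5), 1.86484)
  expect_equal(round(m$asd[5], 5), 0.46645)
})

test_that("report tables have the wide layout and round-trip through CSV", {
  s <- small_phantoms(1, seed = 67, size = 32)[[1]]
  r <- evaluate(s$label_map, s$label_map)
  tab <- report_table(list(modelA = r))
  expect_equal(nrow(tab), 1)
  expect_equal(ncol(tab), 1 + 15)                 # model + (4 classes + mean) x 3
  expect_equal(tab$model, "modelA")
  expect_true(all(c("background_DSC", "mean_ASD") %in% names(tab)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(tab, path)
  back <- read_report_csv(path)
  expect_equal(back$mean_DSC, tab$mean_DSC)
  expect_equal(names(back), names(tab))
  r2 <- evaluate(s$label_map, s$label_map, schema = label_schema(c("bg", "fg")))
  expect_error(report_table(list(a = r, b = r2)), "inconsistent")
})

test_that("report averaging is elementwise over samples", {
  s <- small_phantoms(2, seed = 71, size = 32)
  r1 <- evaluate(s[[1]]$label_map, s[[1]]$label_map)
  r2 <- evaluate(s[[1]]$label_map, s[[2]]$label_map)
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(agg$dsc, (r1$dsc + r2$dsc) / 2)
  expect_equal(agg$hd, (r1$hd + r2$hd) / 2)
})
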