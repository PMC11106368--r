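test_that("dice loss matches its formula in the smooth -> 0 limit", {
  d <- c(6, 6, 6)
  t <- array(0, d); t[1:3, 1, 1] <- 1
  expect_equal(diceLoss(t, t, smooth = 1e-12), 0, tolerance = 1e-9)
  p <- array(0, d); p[1:3, 6, 6] <- 1
  expect_equal(diceLoss(p, t, smooth = 1e-12), 1, tolerance = 1e-9)
  # prediction covers the target plus an equal extra volume -> 1 - 2/3
  p2 <- array(0, d); p2[1:6, 1, 1] <- 1; p2[1:3, 1, 1] <- 1
  t2 <- array(0, d); t2[1:3, 1, 1] <- 1
  expect_equal(diceLoss(p2, t2, smooth = 1e-12), 1 - 2 * 3 / (6 + 3),
               tolerance = 1e-9)
  expect_error(diceLoss(array(0, c(2, 2, 2)), array(0, c(3, 3, 3))),
               "shape")
})

test_that("the learning-rate schedule drops 95% every five epochs", {
  expect_equal(lrSchedule(1), 0.002)
  expect_equal(lrSchedule(6), 1e-4)
  expect_equal(lrSchedule(11), 5e-6)
  expect_equal(lrSchedule(16), 2.5e-7)
  expect_equal(lrSchedule(5), 0.002)     # constant within a 5-epoch block
})

test_that("config validation rejects inconsistent settings", {
  expect_error(unetConfig(patch = 66), "divisible")
  expect_error(unetConfig(stride = 0), "stride")
  expect_error(unetConfig(variant = "bogus"))
})

test_that("sliding-window coverage counts match brute-force enumeration", {
  d <- c(20, 20, 26)
  x <- array(0, c(d, 1))
  patch <- 8; stride <- 5
  out <- slidingWindowMap(function(p) array(1, dim(p)[1:3]), x, patch, stride)
  cov <- attr(out, "coverage")
  # brute force: enumerate windows and count coverage per voxel
  origins <- lapply(d, function(n) unique(c(seq(0, n - patch, stride),
                                            n - patch)))
  ref <- array(0, d)
  for (oz in origins[[3]]) for (oy in origins[[2]]) for (ox in origins[[1]])
    ref[ox + 1:patch, oy + 1:patch, oz + 1:patch] <-
      ref[ox + 1:patch, oy + 1:patch, oz + 1:patch] + 1
  expect_identical(cov, ref)
  expect_true(all(cov >= 1))
})

test_that("a constant scorer yields a constant prediction at any stride", {
  x <- array(rnorm(16 * 16 * 24), c(16, 16, 24, 1))
  for (stride in c(4, 8, 16)) {
    out <- slidingWindowMap(function(p) array(0.7, dim(p)[1:3]), x, 8, stride)
    expect_lt(max(abs(out - 0.7)), 1e-12)
  }
})

test_that("stride equal to patch tiles the volume without overlap", {
  x <- array(rnorm(16^3), c(16, 16, 16, 1))
  calls <- new.env(); calls$n <- 0L
  out <- slidingWindowMap(function(p) {
    calls$n <- calls$n + 1L
    array(calls$n, dim(p)[1:3])
  }, x, 8, 8)
  expect_equal(calls$n, 8L)
  expect_true(all(attr(out, "coverage") == 1))
})

test_that("training is deterministic and reduces the objective", {
  coh <- fixture_cohort(3, 41)
  cfg <- unetConfig(patch = 16, baseFilters = 2, epochs = 3, batch = 2,
                    stepsPerEpoch = 2, seed = 5)
  m1 <- unetTrain(coh, "left", cfg)
  m2 <- unetTrain(coh, "left", cfg)
  expect_identical(m1@lossTrace, m2@lossTrace)
  expect_identical(m1@weights$enc1a$W, m2@weights$enc1a$W)
  expect_lt(m1@lossTrace[length(m1@lossTrace)], m1@lossTrace[1])
})

test_that("prediction pads small volumes, stays in [0,1] and matches forward", {
  coh <- fixture_cohort(2, 43)
  cfg <- unetConfig(patch = 64, baseFilters = 2, epochs = 1, batch = 2,
                    stepsPerEpoch = 1, seed = 5)
  m <- unetTrain(coh, "left", cfg)
  soft <- unetPredict(m, coh[[1]]@image, stride = 32)
  expect_equal(dim(soft@data), dim(coh[[1]]@image@data))
  expect_true(all(soft@data >= 0 & soft@data <= 1))
})

test_that("variant channel builders apply the stated preprocessing", {
  cs <- fixture_case(seed = 6)
  ch <- lcseg:::.unet_channels(cs@image, "nmz+phase")
  expect_length(ch, 2)
  expect_equal(stats::sd(ch[[1]]@data[ch[[1]]@data != 0]), 1,
               tolerance = 1e-9)
  expect_equal(ch[[2]]@data, phaseImage(cs@image)@data, tolerance = 1e-12)
  one <- lcseg:::.unet_channels(cs@image, "image")
  expect_length(one, 1)
  # patch-wise normalization applies to nmz variants only
  expect_true(lcseg:::.unet_patchnorm("nmz"))
  expect_true(lcseg:::.unet_patchnorm("nmz+phase"))
  expect_false(lcseg:::.unet_patchnorm("phase"))
  p <- array(rnorm(4^3 * 2, mean = 7, sd = 3), c(4, 4, 4, 2))
  pn <- lcseg:::.patch_normalize(p)
  expect_lt(abs(mean(pn[, , , 1])), 1e-9)
  expect_equal(stats::sd(pn[, , , 2]), 1, tolerance = 1e-3)
})

test_that("model save/load round-trips the fingerprint and weights", {
  coh <- fixture_cohort(2, 43)
  cfg <- unetConfig(patch = 16, baseFilters = 2, epochs = 1, batch = 2,
                    stepsPerEpoch = 1, seed = 5, variant = "nmz")
  m <- unetTrain(coh, "left", cfg)
  p <- tempfile(fileext = ".rds")
  unetSaveModel(m, p)
  back <- unetLoadModel(p)
  expect_identical(back@weights, m@weights)
  expect_identical(back@config$variant, "nmz")
  expect_identical(back@config$side, "left")
  unlink(p)
})
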