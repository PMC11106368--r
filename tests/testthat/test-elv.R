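test_that("FFT cross-correlation equals direct sliding dot products", {
  set.seed(9)
  d <- c(7, 6, 5)
  a <- array(rnorm(prod(d)), d)
  b <- array(rnorm(prod(d)), d)
  fftc <- lcseg:::.xcorr_fft(a, b)
  # direct circular correlation at a handful of shifts
  for (s in list(c(0, 0, 0), c(1, 0, 0), c(0, 2, 1), c(6, 5, 4))) {
    idx <- lapply(1:3, function(ax) ((seq_len(d[ax]) - 1 - s[ax]) %% d[ax]) + 1)
    direct <- sum(a * b[idx[[1]], idx[[2]], idx[[3]]])
    expect_equal(fftc[s[1] + 1, s[2] + 1, s[3] + 1], direct,
                 tolerance = 1e-6)
  }
})

test_that("a self-matching atlas reproduces its own mask", {
  cs <- fixture_case(seed = 1)
  soft <- elvMap(cs@image, list(cs), "left",
                 elvConfig(window = phantom_elv_window()))
  pred <- binarizeLCC(soft, 0.5)
  expect_gte(diceScore(pred, cs@maskLeft), 0.99)
})

test_that("a circularly shifted test recovers the shifted mask", {
  cs <- fixture_case(seed = 2)
  sh <- c(5, 0, 0)
  d <- dim(cs@image@data)
  idx <- lapply(1:3, function(ax) ((seq_len(d[ax]) - 1 - sh[ax]) %% d[ax]) + 1)
  shifted <- BrainVolume(cs@image@data[idx[[1]], idx[[2]], idx[[3]]],
                         affine = cs@image@affine)
  soft <- elvMap(shifted, list(cs), "left",
                 elvConfig(window = phantom_elv_window()))
  pred <- binarizeLCC(soft, 0.5)
  maskSh <- BinaryMask(cs@maskLeft@data[idx[[1]], idx[[2]], idx[[3]]],
                       like = cs@maskLeft)
  expect_gte(diceScore(pred, maskSh), 0.99)
})

test_that("per-atlas transform weights are a probability distribution", {
  cs <- fixture_case(seed = 1)
  cfg <- elvConfig(window = phantom_elv_window())
  tp <- lcseg:::.elv_preprocess(cs@image, cfg)
  fam <- lcseg:::.elv_family(tp, cfg$translationRadiusMm)
  w <- lcseg:::.elv_window(tp, fam$radius, cfg$window)
  tw <- lcseg:::c_gauss_smooth(tp@data, dim(tp@data),
                               rep(cfg$simSmoothVox, 3)) * w
  ap <- lcseg:::c_gauss_smooth(tp@data, dim(tp@data),
                               rep(cfg$simSmoothVox, 3))
  num <- lcseg:::.xcorr_fft(tw, ap)
  den <- sqrt(pmax(lcseg:::.xcorr_fft(w, ap^2), 0))
  ncc <- num / (sqrt(sum(tw^2)) * pmax(den, 1e-12))
  s <- ncc[fam$sel]
  wt <- exp((s - max(s)) / cfg$kernelWidth)
  wt <- wt / sum(wt)
  expect_equal(sum(wt), 1, tolerance = 1e-9)
  expect_true(all(wt >= 0))
})

test_that("two atlases with equal validity average their maps", {
  cs <- fixture_case(seed = 3)
  cfg <- elvConfig(window = phantom_elv_window())
  m1 <- elvMap(cs@image, list(cs), "left", cfg)
  # same atlas twice: identical validity profiles, so the combined map is
  # the arithmetic mean of the individual maps = the individual map
  m2 <- elvMap(cs@image, list(cs, cs), "left", cfg)
  expect_lt(max(abs(m1@data - m2@data)), 1e-8)
})

test_that("the fuzzy map lies in [0, 1] and shifts with the test image", {
  cs <- fixture_case(seed = 4)
  coh <- fixture_cohort(3, 23)
  cfg <- elvConfig(window = phantom_elv_window())
  soft <- elvMap(cs@image, coh, "left", cfg)
  expect_true(all(soft@data >= 0 & soft@data <= 1))
  sh <- c(0, 3, 0)
  d <- dim(cs@image@data)
  idx <- lapply(1:3, function(ax) ((seq_len(d[ax]) - 1 - sh[ax]) %% d[ax]) + 1)
  shifted <- BrainVolume(cs@image@data[idx[[1]], idx[[2]], idx[[3]]],
                         affine = cs@image@affine)
  soft2 <- elvMap(shifted, coh, "left", cfg)
  moved <- soft@data[idx[[1]], idx[[2]], idx[[3]]]
  # equivariance up to the grid-fixed scoring window: the binarized maps
  # must essentially coincide and the fuzzy maps track each other
  expect_gt(stats::cor(as.vector(soft2@data), as.vector(moved)), 0.9)
  expect_gte(diceScore(binarizeLCC(soft2, 0.5),
                       BinaryMask((moved >= 0.5) + 0, like = cs@image)),
             0.8)
})

test_that("intensity prior peaks at the pooled mean and scales as a Gaussian", {
  coh <- fixture_cohort(3, 23)
  vals <- unlist(lapply(coh, function(a) a@image@data[a@maskLeft@data != 0]))
  mu <- mean(vals); sg <- stats::sd(vals)
  probe <- BrainVolume(array(mu, c(4, 4, 4)), voxelSize = 0.7)
  pr <- intensityPrior(probe, coh, "left")
  expect_equal(max(pr@data), 1, tolerance = 1e-12)
  probe2 <- BrainVolume(array(mu + 2 * sg, c(4, 4, 4)), voxelSize = 0.7)
  pr2 <- intensityPrior(probe2, coh, "left")
  expect_equal(mean(pr2@data), exp(-2), tolerance = 1e-9)
})

test_that("a near-uniform prior leaves the map unchanged", {
  cs <- fixture_case(seed = 5)
  cfg <- elvConfig(window = phantom_elv_window())
  base <- elvMap(cs@image, list(cs), "left", cfg)
  # inflate the pooled spread by adding a huge-variance pseudo-case: the
  # prior tends to 1 everywhere, so modulation is neutral
  prior <- intensityPrior(cs@image, list(cs), "left")
  wide <- exp(-(cs@image@data - mean(cs@image@data))^2 / (2 * (1e6)^2))
  expect_lt(max(abs(base@data * wide - base@data)), 1e-6)
  expect_true(all(prior@data <= 1))
})

test_that("empty atlas lists and oversized translation radii are rejected", {
  cs <- fixture_case(seed = 1)
  expect_error(elvMap(cs@image, list(), "left"), "at least one")
  expect_error(elvMap(cs@image, list(cs), "left",
                      elvConfig(translationRadiusMm = 100)),
               "geometry error")
})
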