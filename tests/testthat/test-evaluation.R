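test_that("dice score follows its formula and conventions", {
  d <- c(40, 10, 10)
  a <- mask_from_idx(d, cbind(1:30, 1, 1))
  b <- mask_from_idx(d, cbind(16:35, 1, 1))   # |a|=30 |b|=20 |overlap|=15
  expect_equal(diceScore(a, b), 2 * 15 / 50)
  expect_equal(diceScore(a, a), 1)
  expect_equal(diceScore(a, mask_from_idx(d, cbind(1:10, 5, 5))), 0)
  expect_equal(diceScore(b, a), diceScore(a, b))
  e <- BinaryMask(array(0, d), voxelSize = 1)
  expect_warning(expect_equal(diceScore(e, e), 1), "empty")
  expect_error(diceScore(a, mask_from_idx(c(5, 5, 5), cbind(1, 1, 1))),
               "grid")
})

test_that("sensitivity measures truth coverage", {
  d <- c(16, 8, 8)
  truth <- mask_from_idx(d, cbind(1:10, 2, 2))
  expect_equal(sensitivityScore(mask_from_idx(d, cbind(1:16, 2, 2)), truth), 1)
  expect_equal(sensitivityScore(mask_from_idx(d, cbind(1:5, 2, 2)), truth), 0.5)
  expect_equal(sensitivityScore(mask_from_idx(d, cbind(1:5, 7, 7)), truth), 0)
  expect_error(sensitivityScore(truth, BinaryMask(array(0, d), voxelSize = 1)),
               "empty")
})

test_that("nested prediction attains the cap with full sensitivity", {
  d <- c(60, 12, 12)
  truth <- mask_from_idx(d, cbind(1:20, 1, 1))
  pred <- mask_from_idx(d, cbind(1:54, 1, 1))   # superset, alpha = 2.7
  expect_equal(sensitivityScore(pred, truth), 1)
  expect_equal(diceScore(pred, truth), diceCap(2.7), tolerance = 1e-12)
})

test_that("binarize + largest component keeps the right blob", {
  d <- c(12, 12, 12)
  s <- array(0, d)
  s[2:3, 2:3, 2:3] <- 0.9          # 8-voxel blob
  s[8:10, 8:10, 8:9] <- 0.8        # 18-voxel blob (larger)
  out <- binarizeLCC(SoftMask(s, voxelSize = 1), 0.5)
  expect_equal(sum(out@data), 18)
  expect_true(all(out@data[8:10, 8:10, 8:9] == 1))
  # everything below threshold -> empty mask with flag
  out2 <- binarizeLCC(SoftMask(s * 0.1, voxelSize = 1), 0.5)
  expect_equal(sum(out2@data), 0)
  expect_true(isTRUE(attr(out2@data, "empty")))
})

test_that("equal-size component ties break toward the earliest voxel", {
  d <- c(10, 4, 4)
  s <- array(0, d)
  s[1:2, 1:2, 1:2] <- 1            # 8 voxels, contains linear index 1
  s[7:8, 3:4, 3:4] <- 1            # 8 voxels, later in raster order
  out <- binarizeLCC(SoftMask(s, voxelSize = 1), 0.5)
  expect_equal(sum(out@data), 8)
  expect_equal(out@data[1, 1, 1], 1)
  expect_equal(out@data[7, 3, 3], 0)
})

test_that("combining soft masks multiplies voxelwise", {
  d <- c(8, 8, 8)
  set.seed(21)
  a <- SoftMask(array(runif(prod(d)), d), voxelSize = 1)
  ones <- SoftMask(array(1, d), voxelSize = 1)
  expect_identical(combineSoft(a, ones, 0.5)@data,
                   binarizeLCC(a, 0.5)@data)
  expect_identical(combineSoft(a, a, 0.5)@data,
                   binarizeLCC(SoftMask(a@data^2, voxelSize = 1), 0.5)@data)
  # hand-computed product support
  b <- SoftMask(array(0.8, d), voxelSize = 1)
  manual <- binarizeLCC(SoftMask(a@data * 0.8, voxelSize = 1), 0.5)
  expect_identical(combineSoft(a, b, 0.5)@data, manual@data)
})

test_that("LOOCV accounts folds, oracles and failures correctly", {
  coh <- fixture_cohort(4, 19)
  oracle <- function(train, test, side)
    if (side == "left") test@maskLeft else test@maskRight
  rep <- runLOOCV(coh, oracle, "left")
  expect_equal(nrow(rep@perCase), 4)
  expect_equal(sort(rep@perCase$subject_id),
               sort(vapply(coh, function(x) x@subjectId, "")))
  expect_true(all(rep@perCase$dice == 1))
  expect_equal(rep@summary$dice_sem, 0)
  empty <- function(train, test, side)
    BinaryMask(array(0, dim(test@image@data)), like = test@image)
  repE <- runLOOCV(coh, empty, "left")
  expect_true(all(repE@perCase$dice == 0))
  broken <- function(train, test, side) stop("boom")
  repB <- runLOOCV(coh, broken, "left")
  expect_true(all(repB@perCase$failure_flag))
  expect_true(all(repB@perCase$dice == 0))
})

test_that("LOOCV with a deterministic method is order-invariant", {
  coh <- fixture_cohort(4, 19)
  method <- geomMethod()
  r1 <- runLOOCV(coh, method, "left")
  r2 <- runLOOCV(rev(coh), method, "left")
  expect_equal(r1@perCase, r2@perCase)
})

test_that("cohort statistics match textbook computations", {
  set.seed(77)
  vl <- rnorm(20, 19.5, 2); vr <- rnorm(20, 19.8, 2)
  dl <- runif(20, 0.4, 0.9); dr <- dl * 0.8 + rnorm(20, 0, 0.05)
  cs <- cohortStats(vl, vr, dl, dr)
  # independent formula-level recomputation of the paired t
  dif <- vl - vr
  tManual <- mean(dif) / (stats::sd(dif) / sqrt(20))
  expect_equal(cs$volume_t$statistic, tManual, tolerance = 1e-12)
  expect_equal(cs$volume_t$p.value,
               2 * stats::pt(-abs(tManual), 19), tolerance = 1e-12)
  rManual <- sum(scale(dl) * scale(dr)) / 19
  expect_equal(cs$dice_cor$r, rManual, tolerance = 1e-12)
  # degenerate: identical arrays
  cs0 <- cohortStats(vl, vl, dl, dl)
  expect_equal(cs0$volume_t$statistic, 0)
  expect_equal(cs0$volume_t$p.value, 1)
  # shifted arrays: r = 1, |t| large
  cs1 <- cohortStats(vl, vl + 3, dl, dl + 0.01)
  expect_gt(abs(cs1$volume_t$statistic), 1e6)
  expect_equal(cs1$dice_cor$r, 1, tolerance = 1e-9)
  # zero-variance dice flagged
  csz <- cohortStats(vl, vr, rep(0.5, 20), dr)
  expect_true(is.na(csz$dice_cor$r))
  expect_equal(csz$dice_cor$flag, "zero_variance")
})

test_that("report TSV contains per-case rows and a summary footer", {
  coh <- fixture_cohort(4, 19)
  rep <- runLOOCV(coh, geomMethod(), "left")
  p <- tempfile(fileext = ".tsv")
  writeReport(rep, p)
  lines <- readLines(p)
  expect_true(any(grepl("^#summary", lines)))
  expect_equal(sum(grepl("^sub[0-9]", lines)), 4)
  unlink(p)
})
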