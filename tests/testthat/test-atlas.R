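test_that("fuzzy atlas of identical cases equals the common mask", {
  cs <- fixture_case(seed = 1)
  atlas <- buildFuzzyAtlas(list(cs, cs, cs))
  expect_identical(atlas@fuzzyLeft@data, cs@maskLeft@data)
  expect_identical(atlas@fuzzyRight@data, cs@maskRight@data)
})

test_that("disjoint single-voxel masks average to one half", {
  d <- c(44, 44, 96)
  mk <- function(i) {
    img <- BrainVolume(array(1, d), voxelSize = 0.7)
    l <- array(0, d); l[i, 1, 1] <- 1
    r <- array(0, d); r[i, 44, 1] <- 1
    lm <- landmarkSet(c(0, 0, 0), c(1, 0, 0), c(0, -4, -3),
                      c(0, 0, -20), c(0, 0, 1))
    new("TrainingCase", image = img,
        lcLeft = BinaryMask(l, like = img), lcRight = BinaryMask(r, like = img),
        maskLeft = BinaryMask(l, like = img),
        maskRight = BinaryMask(r, like = img),
        landmarks = lm, subjectId = paste0("s", i))
  }
  atlas <- buildFuzzyAtlas(list(mk(1), mk(2)), normalize = FALSE)
  expect_equal(atlas@fuzzyLeft@data[1, 1, 1], 0.5)
  expect_equal(atlas@fuzzyLeft@data[2, 1, 1], 0.5)
  expect_equal(sum(atlas@fuzzyLeft@data), 1)
})

test_that("the fuzzy atlas is permutation-invariant and in range", {
  coh <- fixture_cohort(4, 19)
  a1 <- buildFuzzyAtlas(coh)
  a2 <- buildFuzzyAtlas(rev(coh))
  expect_equal(a1@fuzzyLeft@data, a2@fuzzyLeft@data, tolerance = 1e-12)
  expect_true(all(a1@fuzzyLeft@data >= 0 & a1@fuzzyLeft@data <= 1))
  expect_gte(max(a1@fuzzyLeft@data), 0.5)   # overlap inside the landmark slab
})

test_that("self-registration returns a negligible field", {
  cs <- fixture_case(seed = 1)
  v <- normalizeStd(cs@image)
  f <- demonsRegister(v, v, list(iterations = 5, levels = 2))
  expect_lt(max(abs(f@disp)) / 0.7, 0.1)    # < 0.1 voxel
  expect_true(f@converged)
})

test_that("a known translation is recovered within 25%", {
  cs <- fixture_case(seed = 2)
  v <- normalizeStd(cs@image)
  arr <- v@data
  sh <- array(0, dim(arr)); sh[3:44, , ] <- arr[1:42, , ]   # +2 voxels in x
  fx <- BrainVolume(sh, affine = v@affine)
  fld <- demonsRegister(v, fx, list(iterations = 20, levels = 3))
  fg <- which(fx@data != 0)
  recovered <- -mean(fld@disp[, , , 1][fg])   # moving must shift -x
  expect_lt(abs(recovered - 1.4) / 1.4, 0.25)
  # descent sanity
  expect_lte(fld@msdTrace[length(fld@msdTrace)], fld@msdTrace[1])
  # invertibility under default regularization
  J <- deformationJacobian(fld)
  expect_gte(mean(J > 0), 0.99)
})

test_that("warping preserves the soft-mask range", {
  cs <- fixture_case(seed = 3)
  v <- normalizeStd(cs@image)
  arr <- v@data
  sh <- array(0, dim(arr)); sh[, , 3:96] <- arr[, , 1:94]
  fld <- demonsRegister(v, BrainVolume(sh, affine = v@affine),
                        list(iterations = 10, levels = 2))
  s <- SoftMask(array(runif(prod(dim(arr))), dim(arr)), like = cs@image)
  w <- warpVolume(BrainVolume(s@data, affine = s@affine), fld)
  expect_gte(min(w@data), -1e-9)
  expect_lte(max(w@data), 1 + 1e-9)
})

test_that("applying the atlas to its own template is an identity warp", {
  coh <- fixture_cohort(4, 19)
  atlas <- buildFuzzyAtlas(coh)
  res <- applyAtlas(atlas, atlas@templateImage,
                    params = list(iterations = 5, levels = 2))
  ref <- binarizeLCC(atlas@fuzzyLeft, 0.5)
  expect_gte(diceScore(res$left, ref), 0.95)
})

test_that("a rigidly shifted phantom is segmented by atlas propagation", {
  coh <- fixture_cohort(4, 19)
  atlas <- buildFuzzyAtlas(coh)
  test <- fixture_case(seed = 77)
  arr <- normalizeStd(test@image)@data
  sh <- array(0, dim(arr)); sh[2:44, , ] <- arr[1:43, , ]  # +1 voxel shift
  shifted <- BrainVolume(sh, affine = test@image@affine)
  res <- applyAtlas(atlas, shifted)
  truthArr <- array(0, dim(arr))
  truthArr[2:44, , ] <- test@maskLeft@data[1:43, , ]
  truth <- BinaryMask(truthArr, like = test@maskLeft)
  expect_gte(diceScore(res$left, truth), 0.4)
})

test_that("an empty post-threshold mask is flagged, with Dice zero", {
  coh <- fixture_cohort(3, 19)
  atlas <- buildFuzzyAtlas(coh)
  # a test image with no matching structure: uniform noise
  set.seed(2)
  flat <- BrainVolume(array(abs(rnorm(prod(dim(atlas@templateImage@data)))) ,
                            dim(atlas@templateImage@data)),
                      affine = atlas@templateImage@affine)
  res <- applyAtlas(atlas, flat, params = list(iterations = 3, levels = 1),
                    threshold = 0.999)
  expect_equal(sum(res$left@data), 0)
  truth <- coh[[1]]@maskLeft
  expect_equal(diceScore(res$left, truth), 0)
})
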