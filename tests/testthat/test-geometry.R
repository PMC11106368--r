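test_that("dice cap formula matches its closed form", {
  expect_equal(round(diceCap(2.7), 2), 0.54)
  expect_equal(diceCap(1), 1.0)
  expect_equal(diceCap(3), 0.5)
  expect_error(diceCap(0), "positive")
  expect_error(diceCap(-2), "positive")
})

test_that("nested masks achieve the dice cap exactly", {
  # |A| = alpha |B| with B inside A: Dice = 2/(1+alpha) exactly
  d <- c(30, 30, 30)
  for (nB in c(10, 20, 40)) {
    nA <- 3 * nB
    a <- array(0, d); a[seq_len(nA)] <- 1
    b <- array(0, d); b[seq_len(nB)] <- 1
    A <- BinaryMask(a, voxelSize = 1); B <- BinaryMask(b, voxelSize = 1)
    expect_equal(diceScore(A, B), diceCap(nA / nB), tolerance = 1e-12)
  }
})

test_that("mask volume is voxel count times voxel volume", {
  m <- mask_from_idx(c(12, 5, 5), cbind(1:10, 1, 1), vox = 0.7)
  expect_equal(maskVolume(m), 10 * 0.7^3, tolerance = 1e-12)
  expect_equal(maskVolume(BinaryMask(array(0, c(4, 4, 4)), voxelSize = 0.7)), 0)
})

test_that("geometric mask agrees with the phantom's enlarged mask", {
  cs <- fixture_case(seed = 1)
  for (side in c("left", "right")) {
    g <- geometricLCMask(cs@landmarks, side, cs@image)
    truth <- if (side == "left") cs@maskLeft else cs@maskRight
    expect_gte(diceScore(g, truth), 0.5)
    # volume within 15% of the target
    expect_lt(abs(maskVolume(g) - 19.7) / 19.7, 0.15)
    # one connected component
    lab <- lcseg:::c_label26(array(as.integer(g@data), dim(g@data)),
                             dim(g@data))
    expect_equal(length(lab$sizes), 1L)
  }
})

test_that("geometric mask centroid sits laterally of the midline on the correct side", {
  cs <- fixture_case(seed = 2)
  for (side in c("left", "right")) {
    g <- geometricLCMask(cs@landmarks, side, cs@image)
    idx <- which(g@data != 0, arr.ind = TRUE) - 1
    ctr <- colMeans(voxelCenters(g, idx))
    lm <- cs@landmarks
    latDist <- sum((ctr - lm@midlinePoint) * lm@midlineNormal)
    expected <- if (side == "right") 3 else -3
    expect_lt(abs(latDist - expected), 0.5 * 0.7 + 0.35)
    # intersects the 16-20 mm slab above the PMJ
    h <- sum((ctr - lm@pmjPoint) * lm@pmjNormal)
    expect_gt(h, 14); expect_lt(h, 22)
  }
})

test_that("mirrored landmarks give the mirrored mask on a symmetric grid", {
  cs <- fixture_case(seed = 3)
  lm <- cs@landmarks
  mirror <- function(p) {
    mid <- lm@midlinePoint; n <- lm@midlineNormal
    p - 2 * sum((p - mid) * n) * n
  }
  lmM <- landmarkSet(lm@midlinePoint, lm@midlineNormal,
                     mirror(lm@ventricleRef), mirror(lm@pmjPoint),
                     lm@pmjNormal)
  gl <- geometricLCMask(lm, "left", cs@image)
  grM <- geometricLCMask(lmM, "right", cs@image)
  # the grid is symmetric about the midline only up to the midline jitter;
  # compare centroids reflected through the midline plane instead of voxels
  cm <- function(m) {
    idx <- which(m@data != 0, arr.ind = TRUE) - 1
    colMeans(voxelCenters(m, idx))
  }
  expect_lt(sqrt(sum((mirror(cm(gl)) - cm(grM))^2)), 0.75)
})

test_that("geometric construction is equivariant under joint rigid motion", {
  cs <- fixture_case(seed = 1)
  lm <- cs@landmarks
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(2.5, -1.5, 4)
  aff <- cs@image@affine
  aff2 <- rbind(cbind(R %*% aff[1:3, 1:3], R %*% aff[1:3, 4] + tr),
                c(0, 0, 0, 1))
  grid2 <- BrainVolume(cs@image@data, affine = aff2)
  mv <- function(p) as.vector(R %*% p + tr)
  rot <- function(p) as.vector(R %*% p)
  lm2 <- landmarkSet(mv(lm@midlinePoint), rot(lm@midlineNormal),
                     mv(lm@ventricleRef), mv(lm@pmjPoint), rot(lm@pmjNormal))
  g1 <- geometricLCMask(lm, "left", cs@image)
  g2 <- geometricLCMask(lm2, "left", grid2)
  cm <- function(m) {
    idx <- which(m@data != 0, arr.ind = TRUE) - 1
    colMeans(voxelCenters(m, idx))
  }
  expect_lt(sqrt(sum((mv(cm(g1)) - cm(g2))^2)), 0.7)  # < 1 voxel
})

test_that("ball erosion matches its definition", {
  m <- BinaryMask(array(0, c(9, 9, 9)), voxelSize = 1)
  m@data[3:7, 3:7, 3:7] <- 1
  e0 <- erodeMask(m, 0)
  expect_identical(e0@data, m@data)
  e1 <- erodeMask(m, 1)
  expect_equal(sum(e1@data), 27)                       # 5-cube -> 3-cube
  expect_true(all(e1@data[4:6, 4:6, 4:6] == 1))
  # anti-extensive on random masks
  set.seed(8)
  for (i in 1:3) {
    r <- BinaryMask(array(rbinom(9^3, 1, 0.5), c(9, 9, 9)), voxelSize = 1)
    er <- erodeMask(r, 1)
    expect_true(all(er@data <= r@data))
  }
})

test_that("out-of-grid landmarks raise a geometry error", {
  cs <- fixture_case(seed = 1)
  lm <- cs@landmarks
  lmBad <- landmarkSet(lm@midlinePoint + c(500, 0, 0), lm@midlineNormal,
                       lm@ventricleRef + c(500, 0, 0),
                       lm@pmjPoint + c(500, 0, 0), lm@pmjNormal)
  expect_error(geometricLCMask(lmBad, "left", cs@image), "geometry error")
})

test_that("landmark JSON round-trips", {
  cs <- fixture_case(seed = 1)
  p <- tempfile(fileext = ".json")
  writeLandmarks(cs@landmarks, p)
  back <- readLandmarks(p)
  expect_equal(back@ventricleRef, cs@landmarks@ventricleRef, tolerance = 1e-9)
  expect_equal(back@pmjNormal, cs@landmarks@pmjNormal, tolerance = 1e-9)
  unlink(p)
})
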