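test_that("regional means follow the mask on the same grid", {
  d <- c(8, 8, 8)
  m <- mask_from_idx(d, rbind(c(1, 1, 1), c(2, 1, 1)))
  cmap <- BrainVolume(array(3.5, d), voxelSize = 1)
  vmap <- BrainVolume(array(0, d), voxelSize = 1)
  vmap@data[1, 1, 1] <- 1; vmap@data[2, 1, 1] <- 3
  out <- regionalMeans(m, list(const = cmap, var = vmap))
  expect_equal(unname(out["const"]), 3.5)
  expect_equal(unname(out["var"]), 2.0)
})

test_that("mask propagation to a coarser grid changes volume by at most a boundary shell", {
  cs <- fixture_case(seed = 1)
  m <- cs@maskLeft
  coarse <- BrainVolume(array(0, c(25, 25, 54)), voxelSize = 1.25)
  mp <- resampleMask(m, coarse)
  # compare against a direct world-space overlap computation: count coarse
  # voxels whose centre lies inside the fine mask
  pts <- worldToVoxel(m, voxelCenters(coarse))
  inside <- lcseg:::c_nearest_sample(m@data, dim(m@data), pts)
  direct <- sum(inside) * prod(voxelSize(coarse))
  shell <- sum(m@data) * 6 * 1.25 * 0.7^2   # one boundary-voxel shell bound
  expect_lt(abs(maskVolume(mp) - direct), shell + 1e-9)
  # empty after propagation -> NA with flag
  tinym <- mask_from_idx(dim(m@data), cbind(1, 1, 1), vox = 0.7)
  tinym@affine <- m@affine
  far <- BrainVolume(array(0, c(4, 4, 4)), voxelSize = 1)
  far@affine[1:3, 4] <- c(500, 500, 500)
  out <- regionalMeans(tinym, list(x = far))
  expect_true(is.na(out["x"]))
  expect_equal(attr(out, "flags"), "x")
})

test_that("Bonferroni arithmetic reproduces the worked example", {
  # p = 1e-5 with 10 imaging and 504 external variables -> p_B = 0.0504
  expect_equal(min(1, 1e-5 * 10 * 504), 0.0504)
  set.seed(10)
  img <- as.data.frame(matrix(rnorm(30 * 10), 30))
  names(img) <- paste0("img", 1:10)
  ext <- as.data.frame(matrix(rnorm(30 * 504), 30))
  names(ext) <- paste0("ext", 1:504)
  sc <- correlationScan(img[1:2], ext[1:3])
  expect_equal(sc$p_B, pmin(1, sc$p * 2 * 3), tolerance = 1e-12)
  expect_true(all(sc$p_B >= sc$p))
})

test_that("perfect linear relation gives r = 1 and tiny p", {
  x <- seq_len(20)
  sc <- correlationScan(data.frame(a = x), data.frame(b = 2 * x))
  expect_equal(sc$r, 1, tolerance = 1e-12)
  expect_lt(sc$p, 1e-20)
})

test_that("ICV adjustment removes an ICV-driven association", {
  set.seed(42)
  hit <- 0
  for (rep in 1:200) {
    icv <- rnorm(30)
    img <- data.frame(x = 1.5 * icv + rnorm(30, sd = 0.4))
    ext <- data.frame(y = -2 * icv + rnorm(30, sd = 0.4), ICV = icv)
    r0 <- abs(correlationScan(img, ext, adjustICV = FALSE)$r[1])
    r1 <- abs(correlationScan(img, ext, adjustICV = TRUE)$r[1])
    if (r1 < r0) hit <- hit + 1
  }
  expect_gte(hit / 200, 0.95)
})

test_that("the scan controls the familywise error on null data", {
  set.seed(1234)
  n <- 30
  img <- as.data.frame(matrix(rnorm(n * 4), n)); names(img) <- paste0("i", 1:4)
  sig <- 0
  total <- 0
  for (perm in 1:200) {
    ext <- as.data.frame(matrix(rnorm(n * 20), n))
    names(ext) <- paste0("e", 1:20)
    sc <- correlationScan(img, ext)
    sig <- sig + sum(sc$p_B < 0.05, na.rm = TRUE)
    total <- total + nrow(sc)
  }
  expect_lte(sig / total, 0.05)
})

test_that("degenerate variables are flagged, not dropped", {
  img <- data.frame(a = rep(1, 10), b = rnorm(10))
  ext <- data.frame(y = rnorm(10))
  sc <- correlationScan(img, ext)
  expect_equal(nrow(sc), 2)
  row <- sc[sc$imaging_var == "a", ]
  expect_true(is.na(row$r))
  expect_equal(row$flag, "zero_variance")
  # too few complete cases
  img2 <- data.frame(a = c(1, 2, rep(NA, 8)))
  sc2 <- correlationScan(img2, ext)
  expect_equal(sc2$flag, "too_few")
})

test_that("subject alignment uses the id column", {
  img <- data.frame(subject_id = c("s1", "s2", "s3"), a = c(1, 2, 3))
  ext <- data.frame(subject_id = c("s3", "s1", "s2"), b = c(3, 1, 2))
  sc <- correlationScan(img, ext)
  expect_equal(sc$r, 1, tolerance = 1e-12)
})
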