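#' Warp a volume with a deformation field
#'
#' Samples `v` at `x + u(x)`, with the displacement `u` in mm on the
#' (axis-aligned) grid of the field. Linear interpolation for images and
#' soft masks; `"nearest"` for hard labels.
#'
#' @param v a [BrainVolume-class] on the field's grid.
#' @param field a [DeformationField-class].
#' @param mode `"linear"` or `"nearest"`.
#' @return warped [BrainVolume-class].
#' @export
warpVolume <- function(v, field, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(v@data)
  base <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
  pts <- base + sweep(matrix(field@disp, ncol = 3), 2, v@voxelSize, "/")
  vals <- if (mode == "linear") c_trilinear_sample(v@data, d, pts)
          else c_nearest_sample(v@data, d, pts)
  BrainVolume(array(vals, d), affine = v@affine)
}

# disp arrays are (nx, ny, nz, 3) in mm. Compose: (a . b)(x) = a(x) + b(x + a(x)).
.compose_disp <- function(a, b, vox) {
  d <- dim(a)[1:3]
  base <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
  pts <- base + sweep(matrix(a, ncol = 3), 2, vox, "/")
  out <- a
  for (c in 1:3)
    out[, , , c] <- a[, , , c] +
      array(c_trilinear_sample(b[, , , c], d, pts), d)
  out
}

.smooth_disp <- function(u, sigmaVox) {
  for (c in 1:3)
    u[, , , c] <- c_gauss_smooth(u[, , , c], dim(u)[1:3],
                                 rep(sigmaVox, 3))
  u
}

.grad3 <- function(x, vox) {
  d <- dim(x)
  g <- array(0, c(d, 3))
  g[2:(d[1] - 1), , , 1] <- (x[3:d[1], , ] - x[1:(d[1] - 2), , ]) / (2 * vox[1])
  g[, 2:(d[2] - 1), , 2] <- (x[, 3:d[2], ] - x[, 1:(d[2] - 2), ]) / (2 * vox[2])
  g[, , 2:(d[3] - 1), 3] <- (x[, , 3:d[3]] - x[, , 1:(d[3] - 2)]) / (2 * vox[3])
  g
}

#' Diffeomorphic-demons deformable registration
#'
#' Asymmetric (atlas-to-image) intensity-driven registration: at each
#' iteration the classic demons force
#' \deqn{u = (f - m\circ\phi)\,\nabla(m\circ\phi) /
#'       (\|\nabla(m\circ\phi)\|^2 + (f - m\circ\phi)^2)}
#' is Gaussian-smoothed (fluid regularization, `sigmaUpdate`), optionally
#' exponentiated by scaling-and-squaring (`diffeo = TRUE`, keeping the
#' warp invertible), composed with the current field, and the field is
#' smoothed again (elastic regularization, `sigmaField`). Runs over a
#' multi-resolution pyramid. Both inputs should be intensity-normalized
#' ([normalizeStd()]) and on one grid.
#'
#' If the mean squared intensity difference fails to decrease over some
#' level, the returned field carries `converged = FALSE` — a warning
#' flag, not an error, since downstream evaluation records registration
#' failures per case.
#'
#' @param moving,fixed [BrainVolume-class] volumes on the same grid.
#' @param params list with `step` (force scaling), `sigmaUpdate` and
#'   `sigmaField` (voxels), `iterations` (per level), `levels`, `diffeo`.
#' @return a [DeformationField-class] (displacement in mm, on the fixed
#'   grid) with the MSD trace.
#' @export
demonsRegister <- function(moving, fixed,
                           params = list(step = 1.0, sigmaUpdate = 1.0,
                                         sigmaField = 1.5, iterations = 30,
                                         levels = 3, diffeo = TRUE)) {
  if (!sameGrid(moving, fixed)) stop("moving and fixed must share one grid")
  p <- utils::modifyList(list(step = 1.0, sigmaUpdate = 1.0, sigmaField = 1.5,
                              iterations = 30, levels = 3, diffeo = TRUE),
                         params)
  disp <- NULL
  msdTrace <- c()
  converged <- TRUE
  for (lev in rev(seq_len(p$levels) - 1)) {
    f <- 2^lev
    mv <- if (f > 1) resampleVolume(moving, moving@voxelSize * f) else moving
    fx <- if (f > 1) resampleVolume(fixed, fixed@voxelSize * f) else fixed
    d <- dim(fx@data)
    vox <- fx@voxelSize
    if (is.null(disp)) {
      disp <- array(0, c(d, 3))
    } else {
      old <- disp
      grid <- BrainVolume(array(0, d), affine = fx@affine)
      disp <- array(0, c(d, 3))
      for (c in 1:3) {
        comp <- BrainVolume(old[, , , c], affine = attr(old, "affine"))
        disp[, , , c] <- resampleToGrid(comp, grid, "linear")@data
      }
    }
    fld <- function() new("DeformationField", disp = disp,
                          affine = fx@affine, voxelSize = vox,
                          converged = TRUE, msdTrace = numeric())
    msd0 <- mean((fx@data - warpVolume(mv, fld())@data)^2)
    msd <- msd0
    for (it in seq_len(p$iterations)) {
      mw <- warpVolume(mv, fld())@data
      diff <- fx@data - mw
      g <- .grad3(mw, vox)
      g2 <- g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2
      denom <- g2 + diff^2
      u <- array(0, c(d, 3))
      ok <- denom > 1e-12
      for (c in 1:3) {
        uc <- array(0, d)
        uc[ok] <- p$step * diff[ok] * g[, , , c][ok] / denom[ok]
        u[, , , c] <- uc
      }
      u <- .smooth_disp(u, p$sigmaUpdate)
      if (p$diffeo) {
        mx <- max(abs(u)) / min(vox)
        n <- max(0L, ceiling(log2(max(mx / 0.5, 1e-12))))
        if (n > 0) {
          u <- u / 2^n
          for (s in seq_len(n)) u <- .compose_disp(u, u, vox)
        }
      }
      disp <- .compose_disp(u, disp, vox)
      disp <- .smooth_disp(disp, p$sigmaField)
      msd <- mean((fx@data - warpVolume(mv, fld())@data)^2)
      msdTrace <- c(msdTrace, msd)
    }
    if (msd > msd0) converged <- FALSE
    attr(disp, "affine") <- fx@affine
  }
  new("DeformationField", disp = array(disp, c(dim(fixed@data), 3)),
      affine = fixed@affine, voxelSize = fixed@voxelSize,
      converged = converged, msdTrace = msdTrace)
}

#' Jacobian determinant of a deformation field
#'
#' Determinant of `I + du/dx` by central differences; values > 0 indicate
#' a locally invertible (orientation-preserving) warp.
#' @param field a [DeformationField-class].
#' @return 3D array of determinants.
#' @export
deformationJacobian <- function(field) {
  u <- field@disp
  vox <- field@voxelSize
  d <- dim(u)[1:3]
  J <- vector("list", 9)
  idx <- 1
  for (c in 1:3) {
    g <- .grad3(u[, , , c], vox)
    for (a in 1:3) {
      J[[idx]] <- g[, , , a] + (a == c)
      idx <- idx + 1
    }
  }
  # J[[3*(c-1)+a]] = d u_c / d x_a + delta
  J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
}

#' Build a fuzzy atlas from aligned cases
#'
#' Voxelwise mean of the (intensity-normalized) images and of the binary
#' presumptive masks, after warping each case to the template grid with
#' its supplied field (`NULL` entries mean identity, for pre-aligned
#' cohorts such as the phantom). The mean of N identical masks equals the
#' mask itself, and the construction is invariant to case order.
#'
#' @param cases list of [TrainingCase-class].
#' @param toTemplate list of [DeformationField-class] or `NULL` per case
#'   (or `NULL` for all-identity).
#' @param normalize intensity-normalize images before averaging.
#' @return a [FuzzyAtlas-class] on the first case's grid.
#' @export
buildFuzzyAtlas <- function(cases, toTemplate = NULL, normalize = TRUE) {
  if (!length(cases)) stop("need at least one case")
  ref <- cases[[1]]@image
  n <- length(cases)
  accI <- array(0, dim(ref@data))
  accL <- accI; accR <- accI
  for (i in seq_len(n)) {
    cs <- cases[[i]]
    img <- if (normalize) normalizeStd(cs@image) else cs@image
    fl <- if (is.null(toTemplate)) NULL else toTemplate[[i]]
    wL <- cs@maskLeft; wR <- cs@maskRight
    if (!is.null(fl)) {
      img <- warpVolume(img, fl)
      wL <- BrainVolume(wL@data, affine = wL@affine)
      wR <- BrainVolume(wR@data, affine = wR@affine)
      wL <- warpVolume(wL, fl)
      wR <- warpVolume(wR, fl)
    }
    if (!identical(dim(img@data), dim(ref@data)))
      stop("geometry error: case grids disagree after warping")
    accI <- accI + img@data
    accL <- accL + (if (is(wL, "BrainVolume")) wL@data else wL@data)
    accR <- accR + wR@data
  }
  template <- BrainVolume(accI / n, affine = ref@affine)
  new("FuzzyAtlas", templateImage = template,
      fuzzyLeft = SoftMask(.clip01(accL / n), like = ref),
      fuzzyRight = SoftMask(.clip01(accR / n), like = ref))
}

#' Atlas-based segmentation of a test image
#'
#' Registers the atlas template to the (intensity-normalized) test image
#' with [demonsRegister()], warps the fuzzy masks through the resulting
#' field, binarizes at `threshold` and keeps the largest connected
#' component. An empty post-threshold mask is returned empty (its Dice
#' will be 0); non-convergence is carried in the `converged` element.
#'
#' @param atlas a [FuzzyAtlas-class].
#' @param test a [BrainVolume-class] on the atlas grid.
#' @param params registration parameters, see [demonsRegister()].
#' @param threshold binarization level.
#' @return list with `left`, `right` ([BinaryMask-class]), `field`,
#'   `converged`.
#' @export
applyAtlas <- function(atlas, test, params = list(), threshold = 0.5) {
  tn <- normalizeStd(test)
  field <- demonsRegister(normalizeStd(atlas@templateImage), tn, params)
  wl <- warpVolume(BrainVolume(atlas@fuzzyLeft@data,
                               affine = atlas@fuzzyLeft@affine), field)
  wr <- warpVolume(BrainVolume(atlas@fuzzyRight@data,
                               affine = atlas@fuzzyRight@affine), field)
  left <- binarizeLCC(SoftMask(.clip01(wl@data), like = test), threshold)
  right <- binarizeLCC(SoftMask(.clip01(wr@data), like = test), threshold)
  list(left = left, right = right, field = field,
       converged = field@converged)
}

#' Atlas-based segmentation as a LOOCV method
#'
#' Builds a fuzzy atlas from the training cases (identity alignment, for
#' pre-aligned cohorts) and applies it to the test image.
#' @param params registration parameters.
#' @param threshold binarization level.
#' @export
atlasMethod <- function(params = list(), threshold = 0.5) {
  function(train, test, side) {
    atlas <- buildFuzzyAtlas(train)
    res <- applyAtlas(atlas, test@image, params, threshold)
    if (side == "left") res$left else res$right
  }
}
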