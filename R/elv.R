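#' Configuration of the expected-label-value localizer
#'
#' The localizer scores a family of atlas-to-image transformations
#' (integer-voxel 3D translations by default) by a transformation-validity
#' measure — a softmax over windowed normalized cross-correlation — and
#' accumulates each atlas's presumptive mask under every transformation,
#' weighted by that validity. No deformable registration is involved.
#'
#' @param translationRadiusMm half-extent of the translation family per
#'   axis, mm (translations are whole voxels within this radius).
#' @param kernelWidth softness of the similarity-to-weight softmax (in
#'   correlation units; small values concentrate the weight mass on the
#'   best transformations).
#' @param simSmoothVox Gaussian sigma (voxels) applied to the
#'   *similarity* images before cross-correlation; the phase image
#'   whitens the spectrum, so a little smoothing restores the
#'   signal-to-noise of the alignment score. Label accumulation is not
#'   smoothed. 0 disables.
#' @param window optional world-space box `c(xmin, xmax, ymin, ymax, zmin,
#'   zmax)` within which similarity is scored; `NULL` scores over the
#'   whole grid minus a margin of the translation radius (which also makes
#'   the FFT-accelerated correlation exactly equal to direct sliding-window
#'   dot products).
#' @param threshold binarization level for the fuzzy output, in (0, 1).
#' @param usePhase preprocess images with [phaseImage()] (the base
#'   variant); otherwise intensity-normalize with [normalizeStd()].
#' @param useIntensityPrior modulate the fuzzy map by [intensityPrior()].
#' @param epsilonFrac regularization for the phase transform.
#' @return named list of class `"ELVConfig"`.
#' @export
elvConfig <- function(translationRadiusMm = 5, kernelWidth = 0.005,
                      simSmoothVox = 0.8, window = NULL, threshold = 0.5,
                      usePhase = TRUE, useIntensityPrior = FALSE,
                      epsilonFrac = 0.001) {
  if (translationRadiusMm <= 0) stop("translationRadiusMm must be positive")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (kernelWidth <= 0) stop("kernelWidth must be positive")
  if (simSmoothVox < 0) stop("simSmoothVox must be >= 0")
  structure(list(translationRadiusMm = translationRadiusMm,
                 kernelWidth = kernelWidth, simSmoothVox = simSmoothVox,
                 window = window, threshold = threshold, usePhase = usePhase,
                 useIntensityPrior = useIntensityPrior,
                 epsilonFrac = epsilonFrac),
            class = "ELVConfig")
}

.elv_preprocess <- function(v, config) {
  if (config$usePhase) phaseImage(v, config$epsilonFrac) else normalizeStd(v)
}

# Full circular cross-correlation cube via FFT:
# out[T] = sum_x a(x) b(x - T)   (T = 0-based shift, wrapped)
.xcorr_fft <- function(a, b) {
  Fa <- stats::fft(a)
  Fb <- stats::fft(b)
  Re(stats::fft(Fa * Conj(Fb), inverse = TRUE)) / length(a)
}

# Circular convolution: out(x) = sum_T k[T] m(x - T)
.cconv_fft <- function(m, k) {
  Re(stats::fft(stats::fft(m) * stats::fft(k), inverse = TRUE)) / length(m)
}

# Window indicator: interior box inset by `margin` voxels per axis
# (so every scored translation keeps the window inside the grid), possibly
# intersected with a user-supplied world-space box.
.elv_window <- function(grid, margin, worldBox = NULL) {
  d <- dim(grid@data)
  if (any(2 * margin + 1 > d))
    stop("geometry error: translation radius leaves no scoring window")
  w <- array(0, d)
  w[(margin[1] + 1):(d[1] - margin[1]),
    (margin[2] + 1):(d[2] - margin[2]),
    (margin[3] + 1):(d[3] - margin[3])] <- 1
  if (!is.null(worldBox)) {
    P <- voxelCenters(grid)
    inbox <- P[, 1] >= worldBox[1] & P[, 1] <= worldBox[2] &
      P[, 2] >= worldBox[3] & P[, 2] <= worldBox[4] &
      P[, 3] >= worldBox[5] & P[, 3] <= worldBox[6]
    if (!any(inbox)) stop("geometry error: scoring window outside the grid")
    w <- w * array(as.numeric(inbox), d)
  }
  if (sum(w) == 0) stop("geometry error: empty scoring window")
  w
}

# Shifts within the translation family, as a logical array over the
# (wrapped) shift cube, plus the per-axis voxel radius.
.elv_family <- function(grid, radiusMm) {
  d <- dim(grid@data)
  r <- floor(radiusMm / voxelSize(grid))
  if (any(2 * r + 1 > d))
    stop("geometry error: translation family exceeds the grid")
  sel <- array(FALSE, d)
  ix <- function(n, rr) c(1:(rr + 1), if (rr > 0) (n - rr + 1):n)
  sel[ix(d[1], r[1]), ix(d[2], r[2]), ix(d[3], r[3])] <- TRUE
  list(sel = sel, radius = r)
}

#' Expected-label-value fuzzy map
#'
#' For each atlas `a` and translation `T` in the family, the validity
#' weight is `w_a(T) = exp(ncc_a(T) / kernelWidth)` normalized to sum to 1
#' over `T`, where `ncc_a(T)` is the normalized cross-correlation between
#' the translated atlas image and the test image over the scoring window.
#' The fuzzy map is the average over atlases of the weight-blended,
#' translated atlas masks:
#' `ELV(x) = (1/N) sum_a sum_T w_a(T) [T(mask_a)](x)`, with values in
#' `[0, 1]`. All correlations are computed exactly (FFT-accelerated,
#' identical to direct sliding-window dot products within numerical
#' round-off, since the window is inset by the translation radius).
#'
#' @param test a [BrainVolume-class]; raw image — preprocessing (phase or
#'   normalization) is applied internally per `config`.
#' @param atlases nonempty list of [TrainingCase-class].
#' @param side `"left"` or `"right"` (selects the atlases' presumptive
#'   masks).
#' @param config an [elvConfig()].
#' @return a [SoftMask-class] on the test grid.
#' @export
elvMap <- function(test, atlases, side = c("left", "right"),
                   config = elvConfig()) {
  side <- match.arg(side)
  if (!length(atlases)) stop("need at least one atlas case")
  tp <- .elv_preprocess(test, config)
  fam <- .elv_family(tp, config$translationRadiusMm)
  w <- .elv_window(tp, fam$radius, config$window)
  smoo <- function(x) if (config$simSmoothVox > 0)
    c_gauss_smooth(x, dim(x), rep(config$simSmoothVox, 3)) else x
  tw <- smoo(tp@data) * w
  tnorm <- sqrt(sum(tw^2))
  d <- dim(tp@data)
  acc <- array(0, d)
  for (a in atlases) {
    if (!sameGrid(test, a@image))
      stop("atlas and test volumes must share one grid")
    ap <- smoo(.elv_preprocess(a@image, config)@data)
    num <- .xcorr_fft(tw, ap)                 # sum_x w t a(x - T)
    den <- sqrt(pmax(.xcorr_fft(w, ap^2), 0)) # sqrt(sum_x w a(x-T)^2)
    ncc <- array(0, d)
    ok <- den > 1e-12 * tnorm
    ncc[ok] <- num[ok] / (tnorm * den[ok])
    s <- ncc[fam$sel]
    wt <- exp((s - max(s)) / config$kernelWidth)
    wt <- wt / sum(wt)
    K <- array(0, d)
    K[fam$sel] <- wt
    mask <- if (side == "left") a@maskLeft else a@maskRight
    acc <- acc + .cconv_fft(mask@data, K)
  }
  acc <- acc / length(atlases)
  acc <- pmin(1, pmax(0, acc))   # clip FFT round-off
  out <- SoftMask(array(acc, d), like = test)
  if (config$useIntensityPrior) {
    pr <- intensityPrior(test, atlases, side)
    out <- SoftMask(out@data * pr@data, like = test)
  }
  out
}

#' Voxelwise intensity prior from atlas in-mask intensities
#'
#' A Gaussian likelihood of each test voxel's intensity under the pooled
#' mean and standard deviation of the atlases' in-mask intensities,
#' rescaled so its mode equals 1:
#' `prior(x) = exp(-(I(x) - mu)^2 / (2 sigma^2))`. Multiplying the fuzzy
#' map by this prior gives the "phase + image" variant; in the limit of an
#' infinite pooled spread the prior is uniform and leaves the map
#' unchanged.
#'
#' @param test a [BrainVolume-class] (raw intensities).
#' @param atlases list of [TrainingCase-class].
#' @param side `"left"` or `"right"`.
#' @return a [SoftMask-class] of prior values in `(0, 1]`.
#' @export
intensityPrior <- function(test, atlases, side = c("left", "right")) {
  side <- match.arg(side)
  vals <- unlist(lapply(atlases, function(a) {
    m <- if (side == "left") a@maskLeft else a@maskRight
    a@image@data[m@data != 0]
  }))
  mu <- mean(vals)
  sg <- stats::sd(vals)
  if (!is.finite(sg) || sg == 0)
    stop("pooled in-mask intensity standard deviation is zero")
  SoftMask(exp(-(test@data - mu)^2 / (2 * sg^2)), like = test)
}

#' ELV as a LOOCV method
#'
#' Returns a `function(trainCases, testCase, side)` suitable for
#' [runLOOCV()].
#' @param config an [elvConfig()].
#' @export
elvMethod <- function(config = elvConfig()) {
  function(train, test, side) elvMap(test@image, train, side, config)
}
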