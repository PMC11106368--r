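#' Spectral phase-image transform
#'
#' Computes the "phase image" of a volume: the 3D discrete Fourier
#' transform is divided by its regularized magnitude and inverted,
#'
#' \deqn{out = Re\,\mathcal{F}^{-1}\!\big[F / (|F| + \epsilon\,\|F\|)\big],
#'       \quad F = \mathcal{F}[v],}
#'
#' where \eqn{\|F\|} is the L2 (Frobenius) norm over all frequency
#' coefficients and \eqn{\epsilon} = `epsilonFrac` (default 0.001). This
#' discards the Fourier magnitude — keeping edge/border structure while
#' suppressing the intensity distribution — which makes the representation
#' robust to inter-dataset intensity shifts. It is *not* scanner phase
#' data: it is a spectral-whitening transform of a magnitude image.
#'
#' The output is exactly invariant to global positive rescaling of the
#' input (both \eqn{|F|} and \eqn{\|F\|} scale with the input), and
#' equivariant under circular translation. The result is real up to
#' floating-point round-off (Hermitian symmetry is preserved); the real
#' part is returned.
#'
#' @param v a [BrainVolume-class] with finite, not-all-zero data.
#' @param epsilonFrac regularization constant as a fraction of the
#'   spectral L2 norm; >= 0. With `normType = "linf"` the maximal spectral
#'   magnitude is used as \eqn{\|F\|} instead.
#' @param normType `"l2"` (default) or `"linf"`.
#' @return a [BrainVolume-class] on the same grid.
#' @export
phaseImage <- function(v, epsilonFrac = 0.001, normType = c("l2", "linf")) {
  normType <- match.arg(normType)
  if (epsilonFrac < 0) stop("epsilonFrac must be >= 0")
  x <- v@data
  if (all(x == 0))
    stop("phase image undefined for an all-zero volume (zero spectral norm)")
  F <- stats::fft(x)
  mag <- Mod(F)
  nrm <- if (normType == "l2") sqrt(sum(mag^2)) else max(mag)
  denom <- mag + epsilonFrac * nrm
  # with epsilonFrac = 0 a zero coefficient stays zero (0/0 -> 0)
  ratio <- F / denom
  ratio[denom == 0] <- 0
  out <- stats::fft(ratio, inverse = TRUE) / length(x)
  res <- Re(out)
  imagResid <- sqrt(sum(Im(out)^2))
  if (imagResid > 1e-8 * max(sqrt(sum(res^2)), .Machine$double.eps))
    warning("phase image has unexpectedly large imaginary residual")
  BrainVolume(array(res, dim(x)), affine = v@affine)
}

#' Normalize a volume by its intensity standard deviation
#'
#' Divides the image by the standard deviation of its voxel intensities.
#' With `foregroundOnly = TRUE` (the default, matching brain-extracted,
#' zero-background inputs) only nonzero voxels enter the standard
#' deviation. The output is invariant to global positive rescaling of the
#' input; the foreground standard deviation of the output is 1.
#'
#' @param v a [BrainVolume-class].
#' @param foregroundOnly use only nonzero voxels for the scale estimate.
#' @return a [BrainVolume-class] on the same grid.
#' @export
normalizeStd <- function(v, foregroundOnly = TRUE) {
  x <- v@data
  sel <- if (foregroundOnly) x[x != 0] else as.vector(x)
  if (length(sel) < 2L)
    stop("not enough voxels selected for intensity normalization")
  s <- stats::sd(sel)
  if (!is.finite(s) || s == 0)
    stop("zero intensity standard deviation; cannot normalize")
  BrainVolume(x / s, affine = v@affine)
}
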