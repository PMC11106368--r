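#' Read a NIfTI-1 volume
#'
#' Reads a `.nii` / `.nii.gz` file into a [BrainVolume-class], taking the
#' voxel-to-world affine from the header (sform when set, otherwise qform)
#' and casting the data to double. 4D inputs are rejected; a trailing
#' singleton dimension is tolerated and dropped.
#'
#' @param path path to a NIfTI-1 file.
#' @return a [BrainVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path))
    stop("cannot read NIfTI file (no such file): ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read NIfTI file '", path, "': ",
                         conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
    aff <- unclass(RNifti::xform(img))
    return(BrainVolume(img2, affine = .strip_attrs(aff)))
  }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D input: ", path)
  aff <- .strip_attrs(unclass(RNifti::xform(img)))
  data <- array(as.numeric(img), d)
  if (!all(is.finite(data)))
    stop("volume contains non-finite values: ", path)
  BrainVolume(data, affine = aff)
}

.strip_attrs <- function(m) {
  m <- m[1:4, 1:4, drop = FALSE]
  attributes(m) <- list(dim = c(4L, 4L))
  m
}

#' Write a volume as NIfTI-1
#'
#' Writes data as float64 with the affine stored in both qform and sform
#' (code 2), so that `readVolume(writeVolume(v))` round-trips data, affine
#' and spacing. gzip is applied for `.gz` paths.
#'
#' @param v a [BrainVolume-class] (or subclass).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(v, path) {
  nii <- RNifti::asNifti(v@data)
  RNifti::pixdim(nii) <- v@voxelSize
  nii <- RNifti::`qform<-`(nii, structure(v@affine, code = 2L))
  nii <- RNifti::`sform<-`(nii, structure(v@affine, code = 2L))
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

#' Resample a volume to a new voxel size
#'
#' Builds a target grid covering the same world-space extent (field of
#' view) as the input, with the requested spacing along the input's axis
#' directions, then interpolates. `"linear"` performs trilinear
#' interpolation; `"nearest"` takes the nearest voxel and therefore
#' preserves the input's value set (use it for label volumes when a hard
#' assignment is wanted). Sample positions outside the input grid fill
#' with 0, the background value of masks and brain-extracted images.
#'
#' Binary masks resampled with `mode = "linear"` are soft-warped; callers
#' who need a binary result threshold at 0.5 afterwards (see
#' [resampleMask()]).
#'
#' @param v a [BrainVolume-class].
#' @param targetVoxel length-3 (or scalar) target spacing in mm, > 0.
#' @param mode `"linear"` or `"nearest"`.
#' @return a [BrainVolume-class] on the new grid.
#' @export
resampleVolume <- function(v, targetVoxel, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  targetVoxel <- rep_len(as.numeric(targetVoxel), 3L)
  if (any(!is.finite(targetVoxel)) || any(targetVoxel <= 0))
    stop("targetVoxel must be positive along every axis")
  d <- dim(v@data)
  newShape <- pmax(1L, as.integer(ceiling(d * v@voxelSize / targetVoxel - 1e-9)))
  dirs <- sweep(v@affine[1:3, 1:3, drop = FALSE], 2, v@voxelSize, "/")
  A3 <- sweep(dirs, 2, targetVoxel, "*")
  # align the field-of-view corner: voxel centres sit half a voxel inside it
  corner <- v@affine[1:3, 4] - dirs %*% (v@voxelSize / 2)
  origin <- corner + A3 %*% rep(0.5, 3)
  affine <- rbind(cbind(A3, origin), c(0, 0, 0, 1))
  target <- BrainVolume(array(0, newShape), affine = affine)
  .sample_onto(v, target, mode)
}

#' Resample a volume onto the grid of another volume
#'
#' World-space resampling: each voxel centre of `target`'s grid is mapped
#' through the affines into `v` and interpolated there. Used to propagate
#' masks between native and dMRI grids.
#'
#' @param v source [BrainVolume-class].
#' @param target [BrainVolume-class] whose grid defines the output.
#' @param mode `"linear"` or `"nearest"`.
#' @export
resampleToGrid <- function(v, target, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  .sample_onto(v, target, mode)
}

.sample_onto <- function(v, target, mode) {
  xyz <- voxelCenters(target)
  pts <- worldToVoxel(v, xyz)
  vals <- if (mode == "linear")
    c_trilinear_sample(v@data, dim(v@data), pts)
  else
    c_nearest_sample(v@data, dim(v@data), pts)
  BrainVolume(array(vals, dim(target@data)), affine = target@affine)
}

#' Resample a mask with the appropriate post-processing
#'
#' Soft masks are interpolated linearly and clipped to `[0, 1]`; binary
#' masks are interpolated linearly and thresholded at 0.5 (the soft-warp
#' then binarize rule used when propagating masks to the dMRI grid).
#'
#' @param m a [BinaryMask-class] or [SoftMask-class].
#' @param target grid-defining [BrainVolume-class].
#' @param threshold binarization level for binary masks.
#' @return mask of the same class as `m` on the target grid.
#' @export
resampleMask <- function(m, target, threshold = 0.5) {
  r <- resampleToGrid(m, target, "linear")
  if (is(m, "BinaryMask"))
    BinaryMask(r@data >= threshold, like = r)
  else
    SoftMask(.clip01(r@data), like = r)
}
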