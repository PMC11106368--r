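#' Accessors for volume geometry
#'
#' `volData` returns the voxel array, `volAffine` the 4x4 voxel-to-world
#' transform, `voxelSize` the per-axis spacing in mm and `voxelVolume` the
#' volume of one voxel in mm^3.
#'
#' @param x a [BrainVolume-class] (or subclass).
#' @return array, matrix or numeric as described.
#' @aliases volData volAffine voxelSize voxelVolume
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname volData
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))

#' @rdname volData
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname volData
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname volData
setMethod("volData", "BrainVolume", function(x) x@data)

#' @rdname volData
setMethod("volAffine", "BrainVolume", function(x) x@affine)

#' @rdname volData
setMethod("voxelSize", "BrainVolume", function(x) x@voxelSize)

#' @rdname volData
setMethod("voxelVolume", "BrainVolume", function(x) prod(x@voxelSize))

#' Construct a BrainVolume
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm, RAS, 0-based voxel indices).
#'   Defaults to an axis-aligned affine with the given `voxelSize` and the
#'   world origin at the grid centre.
#' @param voxelSize per-axis spacing in mm; derived from `affine` when that
#'   is supplied.
#' @return a [BrainVolume-class].
#' @export
BrainVolume <- function(data, affine = NULL, voxelSize = c(1, 1, 1)) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (is.null(affine)) {
    voxelSize <- rep_len(as.numeric(voxelSize), 3L)
    affine <- diag(c(voxelSize, 1))
    affine[1:3, 4] <- -voxelSize * (dim(data) - 1) / 2
  } else {
    voxelSize <- .col_norms(affine)
  }
  new("BrainVolume", data = data, affine = affine, voxelSize = voxelSize)
}

#' Construct a BinaryMask or SoftMask
#'
#' `BinaryMask` accepts logical or 0/1 numeric data; `SoftMask` accepts
#' values in `[0, 1]`. Geometry arguments as in [BrainVolume()]; a
#' reference volume can be given instead to copy its grid.
#'
#' @param data 3D array of mask values.
#' @param affine,voxelSize grid geometry, as in [BrainVolume()].
#' @param like optional [BrainVolume-class] whose grid is copied.
#' @return a [BinaryMask-class] / [SoftMask-class].
#' @export
BinaryMask <- function(data, affine = NULL, voxelSize = c(1, 1, 1),
                       like = NULL) {
  isLogical <- is.logical(data)
  v <- .mask_geom(data, affine, voxelSize, like)
  if (!isLogical && !all(v$data %in% c(0, 1)))
    stop("BinaryMask data must be logical or exactly 0 or 1")
  new("BinaryMask", data = (v$data != 0) + 0, affine = v$affine,
      voxelSize = v$voxelSize)
}

#' @rdname BinaryMask
#' @export
SoftMask <- function(data, affine = NULL, voxelSize = c(1, 1, 1),
                     like = NULL) {
  v <- .mask_geom(data, affine, voxelSize, like)
  new("SoftMask", data = v$data, affine = v$affine, voxelSize = v$voxelSize)
}

.mask_geom <- function(data, affine, voxelSize, like) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (!is.null(like)) {
    affine <- volAffine(like)
    voxelSize <- voxelSize(like)
  } else if (is.null(affine)) {
    voxelSize <- rep_len(as.numeric(voxelSize), 3L)
    affine <- diag(c(voxelSize, 1))
    affine[1:3, 4] <- -voxelSize * (dim(data) - 1) / 2
  } else {
    voxelSize <- .col_norms(affine)
  }
  list(data = data, affine = affine, voxelSize = voxelSize)
}

# Clip values into [0, 1] preserving array shape (pmax(0, x) would drop
# the dim attribute of its array argument).
.clip01 <- function(a) array(pmin(1, pmax(0, a)), dim(a))

#' Do two volumes live on the same grid?
#'
#' Same array dimensions and affines equal within `tol` (mm).
#' @param a,b [BrainVolume-class] objects.
#' @param tol tolerance on affine entries, mm.
#' @export
sameGrid <- function(a, b, tol = 1e-4) {
  identical(dim(a@data), dim(b@data)) &&
    max(abs(a@affine - b@affine)) <= tol
}

#' World coordinates of voxel centres
#'
#' Maps 0-based voxel indices through the affine. With `ijk = NULL` the
#' centres of all voxels are returned (column-major order), an n x 3 matrix.
#' @param v a [BrainVolume-class].
#' @param ijk n x 3 matrix of 0-based voxel indices, or NULL for all voxels.
#' @export
voxelCenters <- function(v, ijk = NULL) {
  d <- dim(v@data)
  if (is.null(ijk)) {
    ijk <- cbind(
      rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
      rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
      rep(seq_len(d[3]) - 1, each = d[1] * d[2])
    )
  }
  p <- ijk %*% t(v@affine[1:3, 1:3])
  sweep(p, 2, v@affine[1:3, 4], "+")
}

#' Map world coordinates to continuous 0-based voxel indices
#' @param v a [BrainVolume-class].
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @export
worldToVoxel <- function(v, xyz) {
  inv <- solve(v@affine)
  p <- xyz %*% t(inv[1:3, 1:3])
  sweep(p, 2, inv[1:3, 4], "+")
}

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              class(object), d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
  invisible(object)
})

setMethod("show", "TrainingCase", function(object) {
  cat(sprintf("TrainingCase '%s'\n", object@subjectId))
  show(object@image)
  cat(sprintf("  truth volumes L/R: %.2f / %.2f mm^3; mask volumes L/R: %.2f / %.2f mm^3\n",
              maskVolume(object@lcLeft), maskVolume(object@lcRight),
              maskVolume(object@maskLeft), maskVolume(object@maskRight)))
  invisible(object)
})

setMethod("show", "FuzzyAtlas", function(object) {
  cat("FuzzyAtlas\n")
  show(object@templateImage)
  cat(sprintf("  fuzzy mask maxima L/R: %.3f / %.3f\n",
              max(object@fuzzyLeft@data), max(object@fuzzyRight@data)))
  invisible(object)
})

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  cat(sprintf("UNetModel: depth %d, %d base filters, variant '%s', patch %d\n",
              cfg$depth, cfg$baseFilters, cfg$variant, cfg$patch))
  if (length(object@lossTrace))
    cat(sprintf("  trained %d epochs; dice loss %.4f -> %.4f\n",
                length(object@lossTrace), object@lossTrace[1],
                object@lossTrace[length(object@lossTrace)]))
  invisible(object)
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  print(object@summary, row.names = FALSE)
  invisible(object)
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@disp)
  cat(sprintf("DeformationField: %d x %d x %d, max |u| = %.3f mm, %s\n",
              d[1], d[2], d[3], max(abs(object@disp)),
              if (object@converged) "converged" else "NOT converged"))
  invisible(object)
})
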