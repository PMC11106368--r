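#' @useDynLib lcseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.affine_ok <- function(a) {
  is.matrix(a) && all(dim(a) == c(4L, 4L)) && all(is.finite(a)) &&
    all(abs(a[4L, ] - c(0, 0, 0, 1)) < 1e-8)
}

.col_norms <- function(a) sqrt(colSums(a[1:3, 1:3, drop = FALSE]^2))

#' BrainVolume: a 3D scalar grid with world-space geometry
#'
#' The basic data carrier of the package: a 3D array of voxel values, a
#' 4x4 voxel-to-world affine (RAS millimetres; 0-based voxel indices, so
#' the world position of voxel `(i, j, k)` is `affine %*% c(i, j, k, 1)`),
#' and the per-axis voxel size in mm, which must equal the column norms of
#' the affine's 3x3 block.
#'
#' @slot data 3D numeric array of voxel values (finite everywhere).
#' @slot affine 4x4 voxel-to-world transform in mm.
#' @slot voxelSize length-3 numeric, mm per voxel along each axis.
#' @export
setClass("BrainVolume",
  representation(data = "array", affine = "matrix", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (!all(is.finite(object@data)))
      msg <- c(msg, "data must be finite everywhere (no NA/NaN/Inf)")
    if (!.affine_ok(object@affine))
      msg <- c(msg, "affine must be a finite 4x4 matrix with last row (0,0,0,1)")
    else {
      if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        msg <- c(msg, "voxelSize must be 3 positive numbers")
      else if (max(abs(object@voxelSize - .col_norms(object@affine))) > 1e-6)
        msg <- c(msg, "voxelSize must equal the affine's column norms (tol 1e-6)")
    }
    if (length(msg)) msg else TRUE
  }
)

#' BinaryMask: a label volume with values exactly 0 or 1
#' @export
setClass("BinaryMask", contains = "BrainVolume",
  validity = function(object) {
    if (!all(object@data %in% c(0, 1)))
      "BinaryMask values must be exactly 0 or 1" else TRUE
  }
)

#' SoftMask: a fuzzy label volume with values in the unit interval
#' @export
setClass("SoftMask", contains = "BrainVolume",
  validity = function(object) {
    if (any(object@data < 0 | object@data > 1))
      "SoftMask values must lie in [0, 1]" else TRUE
  }
)

#' LandmarkSet: the three geometric references of the LC protocol
#'
#' World-space landmarks used to place the presumptive LC region: the
#' sagittal midline plane, a reference point on the floor of the fourth
#' ventricle, and the pontomedullary-junction (PMJ) plane. The midline and
#' PMJ normals must be perpendicular within 5 degrees, and the ventricle
#' reference must lie rostral to (above) the PMJ plane.
#'
#' @slot midlinePoint,midlineNormal point and unit normal of the midline
#'   plane; the normal points toward the anatomical right.
#' @slot ventricleRef world point on the fourth-ventricle floor.
#' @slot pmjPoint,pmjNormal point and unit normal of the PMJ plane; the
#'   normal points rostrally (toward the head).
#' @export
setClass("LandmarkSet",
  representation(midlinePoint = "numeric", midlineNormal = "numeric",
                 ventricleRef = "numeric", pmjPoint = "numeric",
                 pmjNormal = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("midlinePoint", "midlineNormal", "ventricleRef",
                "pmjPoint", "pmjNormal")) {
      v <- slot(object, s)
      if (length(v) != 3L || !all(is.finite(v)))
        msg <- c(msg, sprintf("%s must be a finite length-3 vector", s))
    }
    if (!length(msg)) {
      ang <- acos(min(1, abs(sum(object@midlineNormal * object@pmjNormal) /
        (sqrt(sum(object@midlineNormal^2)) * sqrt(sum(object@pmjNormal^2))))))
      if (abs(ang - pi / 2) > 5 * pi / 180)
        msg <- c(msg, "midline and PMJ normals must be perpendicular within 5 degrees")
      h <- sum((object@ventricleRef - object@pmjPoint) * object@pmjNormal)
      if (h <= 0)
        msg <- c(msg, "ventricleRef must lie above the PMJ plane")
    }
    if (length(msg)) msg else TRUE
  }
)

#' TrainingCase: one subject's image, truth labels, presumptive masks and landmarks
#'
#' The atom of training and evaluation: a brain image, the left/right
#' ground-truth LC labels, the enlarged presumptive region masks that
#' contain them, and the landmark set used to place the masks. All volumes
#' share one grid; each truth label is contained in its presumptive mask,
#' and the left and right presumptive masks are disjoint.
#'
#' @export
setClass("TrainingCase",
  representation(image = "BrainVolume", lcLeft = "BinaryMask",
                 lcRight = "BinaryMask", maskLeft = "BinaryMask",
                 maskRight = "BinaryMask", landmarks = "LandmarkSet",
                 subjectId = "character"),
  validity = function(object) {
    msg <- character()
    vols <- list(object@lcLeft, object@lcRight, object@maskLeft, object@maskRight)
    for (v in vols)
      if (!sameGrid(object@image, v)) {
        msg <- c(msg, "all volumes of a TrainingCase must share one grid")
        break
      }
    if (!length(msg)) {
      if (any(object@lcLeft@data > object@maskLeft@data))
        msg <- c(msg, "lcLeft must be contained in maskLeft")
      if (any(object@lcRight@data > object@maskRight@data))
        msg <- c(msg, "lcRight must be contained in maskRight")
      if (any(object@maskLeft@data + object@maskRight@data > 1))
        msg <- c(msg, "left and right presumptive masks must be disjoint")
    }
    if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
      msg <- c(msg, "subjectId must be a nonempty string")
    if (length(msg)) msg else TRUE
  }
)

#' PhantomSpec: parameters of the synthetic brainstem phantom
#'
#' Everything that determines one phantom case; the seed fully determines
#' the output. See [makePhantom()] for the geometry and intensity model.
#'
#' @slot gridShape integer 3-vector of voxel counts.
#' @slot voxelSize mm per voxel (3-vector).
#' @slot seed integer RNG seed.
#' @slot site `"A"` or `"B"`; site B applies a monotone contrast remap and
#'   higher noise, emulating a field-strength / scanner change.
#' @slot noiseSigma Gaussian noise standard deviation (intensity units,
#'   tissue contrast is order 1).
#' @slot biasAmplitude peak fractional amplitude of the smooth
#'   multiplicative bias field.
#' @slot jitterMm positional jitter applied to landmarks (mm).
#' @slot shapeJitter fractional jitter of the truth/mask volume scale.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 seed = "integer", site = "character",
                 noiseSigma = "numeric", biasAmplitude = "numeric",
                 jitterMm = "numeric", shapeJitter = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
      msg <- c(msg, "gridShape must be 3 integers >= 4")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive numbers")
    if (!length(msg)) {
      ext <- object@gridShape * object@voxelSize
      if (max(ext) < 60)
        msg <- c(msg, "grid must hold a 60 mm brainstem segment along its long axis")
      if (sort(ext, decreasing = TRUE)[2] < 24)
        msg <- c(msg, "in-plane extent must be at least 24 mm")
    }
    if (!object@site %in% c("A", "B"))
      msg <- c(msg, "site must be 'A' or 'B'")
    if (object@noiseSigma < 0 || object@biasAmplitude < 0 ||
        object@jitterMm < 0 || object@shapeJitter < 0)
      msg <- c(msg, "noiseSigma, biasAmplitude, jitterMm, shapeJitter must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' FuzzyAtlas: template image plus fuzzy left/right LC masks
#'
#' Voxelwise means of aligned, intensity-normalized images and of aligned
#' binary presumptive masks, all on one template grid.
#' @export
setClass("FuzzyAtlas",
  representation(templateImage = "BrainVolume", fuzzyLeft = "SoftMask",
                 fuzzyRight = "SoftMask"),
  validity = function(object) {
    if (!sameGrid(object@templateImage, object@fuzzyLeft) ||
        !sameGrid(object@templateImage, object@fuzzyRight))
      "template image and fuzzy masks must share one grid" else TRUE
  }
)

#' DeformationField: a dense displacement field on a volume grid
#'
#' Per-voxel 3D displacement in mm (world axes, axis-aligned grids), as
#' produced by [demonsRegister()]. `converged` is FALSE when the mean
#' squared intensity difference failed to decrease at some resolution
#' level; the failure is flagged, not raised, mirroring how registration
#' failures are carried through evaluation.
#' @export
setClass("DeformationField",
  representation(disp = "array", affine = "matrix", voxelSize = "numeric",
                 converged = "logical", msdTrace = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@disp)
    if (length(d) != 4L || d[4] != 3L)
      msg <- c(msg, "disp must be an (nx, ny, nz, 3) array")
    if (!all(is.finite(object@disp)))
      msg <- c(msg, "displacements must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' UNetModel: trained weights plus configuration fingerprint
#'
#' @slot weights named list of convolution weight matrices and bias vectors.
#' @slot config the [unetConfig()] list the model was trained with (the
#'   preprocessing fingerprint: variant, patch, depth, filters, seed).
#' @slot lossTrace mean Dice loss per epoch during training.
#' @export
setClass("UNetModel",
  representation(weights = "list", config = "list", lossTrace = "numeric"))

#' EvalReport: per-case metrics and their summary
#'
#' @slot perCase data.frame with columns subject_id, side, dice,
#'   sensitivity, volume_mm3, failure_flag.
#' @slot summary data.frame of median / mean / SEM per side.
#' @slot stats list of cohort-level test results (see [cohortStats()]).
#' @export
setClass("EvalReport",
  representation(perCase = "data.frame", summary = "data.frame",
                 stats = "list"))
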