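#' Parameters of the landmark-driven presumptive-mask construction
#'
#' Defaults encode the geometric protocol: 3 mm lateral from the midline,
#' 1 mm rostral to the fourth-ventricle floor, placed in the 16-20 mm band
#' above the pontomedullary junction, with a target mask volume of
#' 19.7 mm^3 per side. The mask is an axis-aligned tapered spindle whose
#' length spans the LC (`maskLength`, mm) and whose radius scale is solved
#' so that the voxelized volume matches `targetVolume`; set `targetVolume`
#' to `NA` to use `maskDiameter` directly instead.
#'
#' @param lateralOffset mm lateral of the midline plane (>= 0).
#' @param rostralOffset mm rostral of the ventricle floor reference (>= 0).
#' @param pmjBand mm interval above the PMJ plane in which the mask centre
#'   is placed (at the band's midpoint).
#' @param maskLength rostro-caudal mask extent, mm.
#' @param maskDiameter maximal mask diameter, mm (used when
#'   `targetVolume` is `NA`).
#' @param targetVolume target voxelized mask volume, mm^3.
#' @return a named list of class `"GeometryParams"`.
#' @export
geometryParams <- function(lateralOffset = 3, rostralOffset = 1,
                           pmjBand = c(16, 20), maskLength = 15,
                           maskDiameter = 2.5, targetVolume = 19.7,
                           rostralAxis = c("pmj", "ventral")) {
  if (lateralOffset < 0 || rostralOffset < 0)
    stop("offsets must be >= 0")
  if (length(pmjBand) != 2L || pmjBand[1] >= pmjBand[2])
    stop("pmjBand must be an increasing interval")
  if (maskLength <= 0)
    stop("maskLength must be positive")
  structure(list(lateralOffset = lateralOffset, rostralOffset = rostralOffset,
                 pmjBand = pmjBand, maskLength = maskLength,
                 maskDiameter = maskDiameter, targetVolume = targetVolume,
                 rostralAxis = match.arg(rostralAxis)),
            class = "GeometryParams")
}

#' Construct a LandmarkSet
#'
#' @param midlinePoint,midlineNormal midline plane (normal toward the right).
#' @param ventricleRef point on the fourth-ventricle floor.
#' @param pmjPoint,pmjNormal pontomedullary-junction plane (normal rostral).
#' @return a [LandmarkSet-class]; normals are normalized to unit length.
#' @export
landmarkSet <- function(midlinePoint, midlineNormal, ventricleRef,
                        pmjPoint, pmjNormal) {
  unit <- function(v) v / sqrt(sum(v^2))
  new("LandmarkSet", midlinePoint = as.numeric(midlinePoint),
      midlineNormal = unit(as.numeric(midlineNormal)),
      ventricleRef = as.numeric(ventricleRef),
      pmjPoint = as.numeric(pmjPoint),
      pmjNormal = unit(as.numeric(pmjNormal)))
}

# The ventral direction of the ventricle floor, derived from the two plane
# normals (rostral x right-lateral), so no extra landmark is needed.
.ventral_normal <- function(lm) {
  v <- c(lm@pmjNormal[2] * lm@midlineNormal[3] -
           lm@pmjNormal[3] * lm@midlineNormal[2],
         lm@pmjNormal[3] * lm@midlineNormal[1] -
           lm@pmjNormal[1] * lm@midlineNormal[3],
         lm@pmjNormal[1] * lm@midlineNormal[2] -
           lm@pmjNormal[2] * lm@midlineNormal[1])
  v / sqrt(sum(v^2))
}

# Squared radius profile of the tapered spindle at signed axial offset zeta:
# r(zeta)^2 = rmax^2 * (1 - (zeta/c)^2)^3 inside |zeta| <= c, else 0.
.spindle_rsq <- function(zeta, c, rmax) {
  t <- 1 - (zeta / c)^2
  ifelse(abs(zeta) <= c, rmax^2 * t^3, 0)
}

# Voxel-centre-inside voxelization of a spindle (optionally inflated by a
# margin w, which also lengthens the caps), returning a logical vector over
# the grid. geom = list(zeta, rho2) precomputed for the grid.
.spindle_inside <- function(geom, c, rmax, w = 0) {
  rsq <- .spindle_rsq(geom$zeta, c, rmax)
  abs(geom$zeta) <= c + w & geom$rho2 <= rsq + w^2
}

.spindle_geom <- function(grid, center, axis) {
  P <- voxelCenters(grid)
  d <- sweep(P, 2, center)
  zeta <- as.vector(d %*% axis)
  rho2 <- pmax(0, rowSums(d^2) - zeta^2)
  list(zeta = zeta, rho2 = rho2)
}

# Restrict the spindle geometry to voxels that could ever fall inside the
# shape (axial extent <= c + wCap, radial distance <= rCap); bisection then
# counts over this small candidate set instead of the whole grid.
.spindle_crop <- function(geom, c, rCap, wCap) {
  idx <- which(abs(geom$zeta) <= c + wCap & geom$rho2 <= rCap^2)
  list(idx = idx,
       geom = list(zeta = geom$zeta[idx], rho2 = geom$rho2[idx]))
}

# Solve a monotone scalar (radius scale or inflation margin) by bisection
# so that the voxel count reaches `target`. `countFun(s)` must be
# nondecreasing in s.
.bisect_count <- function(countFun, target, lo = 1e-3, hi = 12) {
  if (countFun(hi) < target)
    stop("geometry error: target volume cannot be reached on this grid")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (countFun(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Geometric construction of the presumptive LC mask from landmarks
#'
#' Codifies the manual protocol: the mask centre is placed
#' `lateralOffset` mm lateral of the midline plane on the requested side
#' and `rostralOffset` mm from the ventricle-floor reference along the
#' rostral (PMJ-normal) axis — or along the floor's ventral normal with
#' `rostralAxis = "ventral"` — and is clamped into the `pmjBand` above
#' the PMJ plane when the ventricle reference would place it outside.
#' The mask is a tapered spindle along the rostro-caudal (PMJ-normal)
#' axis; its radius scale is solved by bisection so the voxelized volume
#' matches `targetVolume` (a voxel belongs to the mask when its centre
#' lies inside the analytic shape). The largest 26-connected component is
#' returned, so the mask is a single connected region.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param side `"left"` or `"right"`.
#' @param grid a [BrainVolume-class] defining the output grid.
#' @param params a [geometryParams()] list.
#' @return a [BinaryMask-class] on `grid`'s grid.
#' @export
geometricLCMask <- function(landmarks, side = c("left", "right"), grid,
                            params = geometryParams()) {
  side <- match.arg(side)
  lm <- landmarks
  lat <- if (side == "right") lm@midlineNormal else -lm@midlineNormal
  rostral <- if (params$rostralAxis == "pmj") lm@pmjNormal
             else .ventral_normal(lm)
  center <- lm@ventricleRef + params$rostralOffset * rostral
  # "3 mm lateral from the midline": the lateral coordinate is measured
  # from the midline plane, so project out the midline-normal component
  center <- center - sum((center - lm@midlinePoint) * lm@midlineNormal) *
    lm@midlineNormal
  center <- center + params$lateralOffset * lat
  # the centre must respect the 16-20 mm band above the PMJ; clamp into
  # the band when the ventricle reference places it outside
  h <- sum((center - lm@pmjPoint) * lm@pmjNormal)
  hc <- min(max(h, params$pmjBand[1]), params$pmjBand[2])
  center <- center + (hc - h) * lm@pmjNormal
  # the centre must fall inside the grid's world extent
  vox <- worldToVoxel(grid, matrix(center, 1))
  d <- dim(grid@data)
  if (any(vox < -0.5) || any(vox > d - 0.5))
    stop("geometry error: landmark-placed mask centre lies outside the grid")
  geom <- .spindle_geom(grid, center, lm@pmjNormal)
  c_half <- params$maskLength / 2
  inside <- logical(prod(d))
  if (is.na(params$targetVolume)) {
    inside <- .spindle_inside(geom, c_half, params$maskDiameter / 2)
  } else {
    nTarget <- max(3, round(params$targetVolume / voxelVolume(grid)))
    cr <- .spindle_crop(geom, c_half, rCap = 4, wCap = 0)
    s <- .bisect_count(function(s)
      sum(.spindle_inside(cr$geom, c_half, s)), nTarget, hi = 4)
    inside[cr$idx] <- .spindle_inside(cr$geom, c_half, s)
  }
  m <- BinaryMask(array(as.numeric(inside), d), like = grid)
  binarizeLCC(SoftMask(m@data, like = m), 0.5)
}

#' Erode a binary mask with a physical-radius ball
#'
#' Morphological erosion with a ball structuring element of `radiusMm`
#' millimetres (anisotropic voxel sizes are respected). Radius 0 is the
#' identity; the result is always a subset of the input and may be empty.
#'
#' @param m a [BinaryMask-class].
#' @param radiusMm ball radius in mm, >= 0.
#' @export
erodeMask <- function(m, radiusMm) {
  if (radiusMm < 0) stop("radiusMm must be >= 0")
  vs <- m@voxelSize
  r <- floor(radiusMm / vs + 1e-9)
  off <- as.matrix(expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3]))
  keep <- sqrt(colSums((t(off) * vs)^2)) <= radiusMm + 1e-9
  off <- off[keep, , drop = FALSE]
  storage.mode(off) <- "integer"
  out <- c_erode(array(as.integer(m@data != 0), dim(m@data)), dim(m@data), off)
  BinaryMask(array(as.numeric(out), dim(m@data)), like = m)
}

#' Volume of a mask in mm^3
#'
#' Nonzero-voxel count times the voxel volume.
#' @param m a [BinaryMask-class] (or any volume; nonzero voxels counted).
#' @export
maskVolume <- function(m) sum(m@data != 0) * voxelVolume(m)

#' Upper bound on the Dice score of an inflated region
#'
#' If a region's volume is `alpha` times that of a label it contains, the
#' Dice coefficient between the two cannot exceed `2 / (1 + alpha)`; at
#' `alpha = 1` the bound is 1.
#'
#' @param alpha volume ratio, > 0.
#' @return the Dice cap, dimensionless.
#' @export
diceCap <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be a positive, finite volume ratio")
  2 / (1 + alpha)
}

#' Mean per-side mask volumes over a directory of NIfTI masks
#'
#' Reads every file matching `pattern` under `dir`, computes each mask's
#' volume in mm^3, and averages per side. Side is inferred from the file
#' name (`left`/`lh`/`_l` vs `right`/`rh`/`_r`, case-insensitive). Used to
#' summarize deposited mask collections.
#'
#' @param dir directory of `.nii`/`.nii.gz` mask files.
#' @param pattern regular expression selecting mask files.
#' @return list with per-file volumes and `left`, `right`, `bilateral`
#'   mean volumes (mm^3).
#' @export
maskDirVolumes <- function(dir, pattern = "\\.nii(\\.gz)?$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) stop("no NIfTI mask files found under ", dir)
  vols <- vapply(files, function(f) {
    v <- readVolume(f)
    maskVolume(BinaryMask(v@data >= 0.5, like = v))
  }, numeric(1))
  base <- tolower(basename(files))
  isL <- grepl("left|(^|[_\\.-])lh?([_\\.-]|$)", base)
  isR <- grepl("right|(^|[_\\.-])rh?([_\\.-]|$)", base)
  list(files = files, volumes = vols,
       left = mean(vols[isL & !isR]), right = mean(vols[isR & !isL]),
       bilateral = mean(c(vols[isL & !isR], vols[isR & !isL])))
}
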