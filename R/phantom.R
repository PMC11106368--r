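#' Specification of the synthetic brainstem phantom
#'
#' Builds a [PhantomSpec-class] with the study's default conditions: a
#' 44 x 44 x 96 grid at (0.7 mm)^3 (a ~31 x 31 x 67 mm brainstem segment),
#' tissue noise sigma 0.05 on a tissue contrast of order 1, a 10% smooth
#' multiplicative bias field, 1 mm landmark jitter and 10% shape-scale
#' jitter. Site `"B"` applies a monotone gamma-plus-gain intensity remap
#' (`I -> 1.5 * I^0.8`) and 1.5x noise to emulate an acquisition-site /
#' field-strength change; the underlying geometry is identical for both
#' sites at a given seed.
#'
#' @param gridShape integer 3-vector of voxel counts.
#' @param voxelSize mm per voxel (scalar or 3-vector), default 0.7 isotropic.
#' @param seed integer seed; fully determines the phantom.
#' @param site `"A"` or `"B"`.
#' @param noiseSigma,biasAmplitude,jitterMm,shapeJitter see
#'   [PhantomSpec-class].
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(44L, 44L, 96L), voxelSize = 0.7,
                        seed = 1L, site = "A", noiseSigma = 0.05,
                        biasAmplitude = 0.1, jitterMm = 1.0,
                        shapeJitter = 0.1) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = rep_len(as.numeric(voxelSize), 3L),
      seed = as.integer(seed), site = site, noiseSigma = noiseSigma,
      biasAmplitude = biasAmplitude, jitterMm = jitterMm,
      shapeJitter = shapeJitter)
}

# Anatomical constants of the phantom, in mm. The LC truth volume targets
# the external-label scale (~7 mm^3 per side); the enlarged presumptive
# mask targets the deposited-mask scale (19.7 mm^3 per side).
.PH <- list(
  zPmj = -20,           # PMJ plane height below grid centre
  ventY = -4,           # fourth-ventricle floor (posterior surface)
  ventZAbovePmj = 17,   # floor reference height above the PMJ
  lcLength = 14.5,      # truth spindle length
  lcVolume = 7.0,       # per-side truth volume target
  maskVolume = 19.7,    # per-side enlarged-mask volume target
  lateral = 3,          # LC centre lateral offset from midline
  rostral = 1,          # LC centre rostral offset from the floor reference
  floorClearance = 1.2, # CSF wedge carved this far posterior of the reference
  ponsRadius = 11, medullaRadius = 8, midbrainRadius = 9,
  ponsTop = 30,         # pons/midbrain transition height above PMJ
  csfLevel = 0.35       # CSF intensity relative to pons tissue = 1
)

#' Generate one synthetic brainstem phantom case
#'
#' The phantom is a brainstem-like column (medulla / pons / midbrain
#' cylinders of distinct radius) with a CSF-filled fourth-ventricle wedge
#' on its posterior surface, immersed in zero background. The bilateral
#' ground-truth LC is a pair of tapered spindles, nominally 14.5 mm long,
#' centred 3 mm lateral of the midline, 1 mm ventral of the
#' ventricle-floor reference and 18 mm above the PMJ plane; the spindle
#' radius scale is solved so each side's voxelized volume matches
#' ~7 mm^3 (the scale of manually delineated LC labels). The enlarged
#' presumptive mask inflates the same spindle by a margin solved to reach
#' ~19.7 mm^3 per side, so truth is contained in the mask by construction.
#'
#' Crucially, the image gives the LC *no* contrast against pons tissue
#' (as on T1-weighted MRI): localizers must rely on geometry relative to
#' the visible structures. Intensities carry a smooth multiplicative bias
#' field and Gaussian noise inside the head; background is exactly zero
#' (brain-extracted convention). Site B remaps contrast monotonically and
#' raises the noise, leaving geometry untouched.
#'
#' @param spec a [phantomSpec()].
#' @return a [TrainingCase-class].
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  d <- spec@gridShape
  grid <- BrainVolume(array(0, d), voxelSize = spec@voxelSize)
  j <- spec@jitterMm
  sj <- spec@shapeJitter

  # --- jittered landmarks (drawn first so geometry is site-invariant)
  midX <- runif(1, -j, j)
  ventJ <- runif(3, -j, j)
  pmjZ <- .PH$zPmj + runif(1, -j, j)
  lm <- landmarkSet(
    midlinePoint = c(midX, 0, 0), midlineNormal = c(1, 0, 0),
    ventricleRef = c(midX, .PH$ventY, pmjZ + .PH$ventZAbovePmj) + ventJ,
    pmjPoint = c(midX, 0, pmjZ), pmjNormal = c(0, 0, 1))
  sideJit <- matrix(runif(6, -j / 3, j / 3), 2)   # rows: left, right
  uLen <- runif(1, 1 - sj / 2, 1 + sj / 2)
  uTruth <- runif(2, 1 - sj, 1 + sj)
  uMask <- runif(2, 1 - sj, 1 + sj)
  biasPhase <- runif(2, 0, 2 * pi)

  # --- LC truth + enlarged masks (per the landmark rule: 1 mm rostral of
  # the ventricle-floor reference, 3 mm lateral of the midline plane; the
  # resulting height above the PMJ falls inside the protocol's 16-20 mm
  # band by construction of the landmarks). Each landmark constrains its
  # own axis: the lateral position comes from the midline plane, so the
  # ventricle reference is first projected onto it.
  base <- lm@ventricleRef + .PH$rostral * lm@pmjNormal
  base <- base - sum((base - lm@midlinePoint) * lm@midlineNormal) *
    lm@midlineNormal
  cHalf <- .PH$lcLength / 2 * uLen
  voxv <- voxelVolume(grid)
  sides <- list(left = -1, right = 1)
  truth <- list(); mask <- list()
  for (s in names(sides)) {
    i <- if (s == "left") 1L else 2L
    centre <- base + sides[[s]] * .PH$lateral * lm@midlineNormal + sideJit[i, ]
    geom <- .spindle_geom(grid, centre, lm@pmjNormal)
    cr <- .spindle_crop(geom, cHalf, rCap = 6, wCap = 3)
    nT <- max(3, round(.PH$lcVolume * uTruth[i] / voxv))
    sT <- .bisect_count(function(s_)
      sum(.spindle_inside(cr$geom, cHalf, s_)), nT, hi = 3)
    nM <- max(nT + 1, round(.PH$maskVolume * uMask[i] / voxv))
    w <- .bisect_count(function(w_)
      sum(.spindle_inside(cr$geom, cHalf, sT, w_)), nM, lo = 1e-4, hi = 3)
    tv <- logical(prod(d)); mv <- logical(prod(d))
    tv[cr$idx] <- .spindle_inside(cr$geom, cHalf, sT)
    mv[cr$idx] <- .spindle_inside(cr$geom, cHalf, sT, w)
    truth[[s]] <- BinaryMask(array(as.numeric(tv), d), like = grid)
    mask[[s]] <- BinaryMask(array(as.numeric(mv), d), like = grid)
  }

  # --- tissue image
  P <- voxelCenters(grid)
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  hz <- z - pmjZ                                  # height above the PMJ
  # medulla / pons / midbrain radii with 3 mm softened transitions
  ramp <- function(t) pmin(1, pmax(0, t))
  radius <- .PH$medullaRadius +
    (.PH$ponsRadius - .PH$medullaRadius) * ramp(hz / 3) +
    (.PH$midbrainRadius - .PH$ponsRadius) * ramp((hz - .PH$ponsTop) / 3)
  inStem <- (x - midX)^2 + y^2 <= radius^2
  # CSF wedge posterior of the floor reference (with a clearance so the
  # LC column, which sits at the reference's depth, stays in pons tissue)
  yFloor <- lm@ventricleRef[2] - .PH$floorClearance
  zV <- lm@ventricleRef[3]
  inCsf <- inStem & y < yFloor & abs(x - midX) < 8 &
    z > zV - 9 & z < zV + 11
  clean <- numeric(length(x))
  clean[inStem] <- 1
  clean[inCsf] <- .PH$csfLevel
  ext <- d * spec@voxelSize
  bias <- 1 + spec@biasAmplitude *
    cos(pi * x / ext[1] + biasPhase[1]) * cos(pi * z / ext[3] + biasPhase[2])
  clean <- clean * bias
  eps <- rnorm(length(clean))
  if (spec@site == "B") {
    clean[inStem] <- 1.5 * clean[inStem]^0.8
    sigma <- 1.5 * spec@noiseSigma
  } else sigma <- spec@noiseSigma
  img <- clean
  img[inStem] <- img[inStem] + sigma * eps[inStem]
  image <- BrainVolume(array(img, d), affine = grid@affine)

  new("TrainingCase", image = image,
      lcLeft = truth$left, lcRight = truth$right,
      maskLeft = mask$left, maskRight = mask$right,
      landmarks = lm, subjectId = sprintf("phantom-seed%d-%s",
                                          spec@seed, spec@site))
}

#' Generate a cohort of phantom cases
#'
#' Case `i` uses seed `baseSeed * 1000 + i`, so a cohort is fully
#' reproducible and per-case jitter is independent. Subject ids are unique
#' within the cohort.
#'
#' @param n number of cases, >= 1.
#' @param baseSeed integer base seed (keep below ~2e6 so derived seeds
#'   stay within integer range).
#' @param site `"A"` or `"B"`.
#' @param spec template [phantomSpec()]; its seed and site are overridden
#'   per case.
#' @return list of [TrainingCase-class] objects.
#' @export
makeCohort <- function(n, baseSeed = 1L, site = "A", spec = phantomSpec()) {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    s <- spec
    s@seed <- as.integer(baseSeed * 1000 + i)
    s@site <- site
    cs <- makePhantom(s)
    cs@subjectId <- sprintf("sub%02d-%s", i, site)
    cs
  })
}

#' Write a cohort to disk as NIfTI volumes plus landmark JSON
#'
#' Per case: `<id>_img.nii.gz`, `<id>_lc_left/right.nii.gz`,
#' `<id>_mask_left/right.nii.gz` and `<id>_landmarks.json`.
#'
#' @param cases list of [TrainingCase-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cs in cases) {
    id <- cs@subjectId
    writeVolume(cs@image, file.path(dir, paste0(id, "_img.nii.gz")))
    writeVolume(cs@lcLeft, file.path(dir, paste0(id, "_lc_left.nii.gz")))
    writeVolume(cs@lcRight, file.path(dir, paste0(id, "_lc_right.nii.gz")))
    writeVolume(cs@maskLeft, file.path(dir, paste0(id, "_mask_left.nii.gz")))
    writeVolume(cs@maskRight, file.path(dir, paste0(id, "_mask_right.nii.gz")))
    writeLandmarks(cs@landmarks, file.path(dir, paste0(id, "_landmarks.json")))
  }
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#' @param dir directory containing `*_img.nii.gz` etc.
#' @return list of [TrainingCase-class].
#' @export
readCohort <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "_img\\.nii(\\.gz)?$",
                          full.names = TRUE))
  if (!length(imgs)) stop("no cohort images found under ", dir)
  lapply(imgs, function(f) {
    id <- sub("_img\\.nii(\\.gz)?$", "", basename(f))
    p <- function(tag) file.path(dir, paste0(id, "_", tag, ".nii.gz"))
    img <- readVolume(f)
    asMask <- function(path) {
      v <- readVolume(path)
      BinaryMask(v@data >= 0.5, like = v)
    }
    new("TrainingCase", image = img,
        lcLeft = asMask(p("lc_left")), lcRight = asMask(p("lc_right")),
        maskLeft = asMask(p("mask_left")), maskRight = asMask(p("mask_right")),
        landmarks = readLandmarks(file.path(dir, paste0(id, "_landmarks.json"))),
        subjectId = id)
  })
}

#' Serialize landmarks to JSON
#' @param lm a [LandmarkSet-class].
#' @param path output path.
#' @export
writeLandmarks <- function(lm, path) {
  jsonlite::write_json(list(
    midlinePoint = lm@midlinePoint, midlineNormal = lm@midlineNormal,
    ventricleRef = lm@ventricleRef, pmjPoint = lm@pmjPoint,
    pmjNormal = lm@pmjNormal), path, digits = NA)
  invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmarkSet(x$midlinePoint, x$midlineNormal, x$ventricleRef,
              x$pmjPoint, x$pmjNormal)
}
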