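#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined to have Dice 1
#' (with a warning); an empty prediction against a nonempty truth gives 0.
#'
#' @param a,b [BinaryMask-class] objects on the same grid.
#' @return Dice score in `[0, 1]`.
#' @export
diceScore <- function(a, b) {
  if (!sameGrid(a, b)) stop("masks must share one grid")
  na <- sum(a@data); nb <- sum(b@data)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a@data * b@data) / (na + nb)
}

#' Sensitivity (truth coverage) of a prediction
#'
#' `|pred n truth| / |truth|`; the truth mask must be nonempty.
#' @param pred,truth [BinaryMask-class] objects on the same grid.
#' @export
sensitivityScore <- function(pred, truth) {
  if (!sameGrid(pred, truth)) stop("masks must share one grid")
  nt <- sum(truth@data)
  if (nt == 0) stop("truth mask is empty; sensitivity undefined")
  sum(pred@data * truth@data) / nt
}

#' Binarize a soft mask and keep the largest connected component
#'
#' Thresholds at `threshold` and retains the largest 26-connected
#' component; among equally sized components the one containing the
#' smallest linear voxel index wins (deterministic tie-break). An empty
#' post-threshold mask is returned empty with attribute `empty = TRUE`.
#'
#' @param s a [SoftMask-class] (a [BinaryMask-class] is accepted too).
#' @param threshold level in (0, 1).
#' @return a [BinaryMask-class].
#' @export
binarizeLCC <- function(s, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  bin <- s@data >= threshold
  if (!any(bin)) {
    out <- BinaryMask(array(0, dim(s@data)), like = s)
    attr(out@data, "empty") <- TRUE
    return(out)
  }
  lab <- c_label26(array(as.integer(bin), dim(s@data)), dim(s@data))
  best <- which.max(lab$sizes)   # first maximal label = smallest first voxel
  BinaryMask(array(as.numeric(lab$labels == best), dim(s@data)), like = s)
}

#' Combine two soft masks by voxelwise product, then binarize
#'
#' The combination rule for fusing two localizers' soft outputs:
#' `binarizeLCC(a * b, threshold)`.
#' @param a,b [SoftMask-class] objects on the same grid.
#' @param threshold binarization level.
#' @return a [BinaryMask-class].
#' @export
combineSoft <- function(a, b, threshold = 0.5) {
  if (!sameGrid(a, b)) stop("soft masks must share one grid")
  binarizeLCC(SoftMask(a@data * b@data, like = a), threshold)
}

#' Leave-one-out cross-validation of a localization method
#'
#' For each case, `method` is fitted on the remaining cases and applied to
#' the held-out case; the (binarized) prediction is scored against the
#' held-out case's *enlarged presumptive mask* with Dice, sensitivity and
#' volume. A method failure (error) on a fold is recorded with Dice 0 and
#' a failure flag; the run continues. With deterministic methods the
#' report is invariant to the order of `cases`.
#'
#' @param cases list of [TrainingCase-class].
#' @param method `function(trainCases, testCase, side)` returning a
#'   [SoftMask-class] or [BinaryMask-class] on the test grid (see
#'   [elvMethod()], [unetMethod()], [geomMethod()], [atlasMethod()]).
#' @param side `"left"` or `"right"`.
#' @param threshold binarization level applied to soft outputs.
#' @return an [EvalReport-class].
#' @export
runLOOCV <- function(cases, method, side = c("left", "right"),
                     threshold = 0.5) {
  side <- match.arg(side)
  if (length(cases) < 2L) stop("LOOCV needs at least 2 cases")
  rows <- lapply(seq_along(cases), function(i) {
    test <- cases[[i]]
    truth <- if (side == "left") test@maskLeft else test@maskRight
    res <- tryCatch({
      pred <- method(cases[-i], test, side)
      if (!is(pred, "BinaryMask"))
        pred <- binarizeLCC(pred, threshold)
      list(dice = diceScore(pred, truth),
           sens = sensitivityScore(pred, truth),
           vol = maskVolume(pred), fail = FALSE)
    }, error = function(e) list(dice = 0, sens = 0, vol = 0, fail = TRUE))
    data.frame(subject_id = test@subjectId, side = side, dice = res$dice,
               sensitivity = res$sens, volume_mm3 = res$vol,
               failure_flag = res$fail)
  })
  perCase <- do.call(rbind, rows)
  perCase <- perCase[order(perCase$subject_id), ]
  rownames(perCase) <- NULL
  new("EvalReport", perCase = perCase,
      summary = .eval_summary(perCase), stats = list())
}

.eval_summary <- function(perCase) {
  do.call(rbind, lapply(split(perCase, perCase$side), function(df) {
    n <- nrow(df)
    data.frame(side = df$side[1], n = n,
               dice_median = stats::median(df$dice),
               dice_mean = mean(df$dice),
               dice_sem = stats::sd(df$dice) / sqrt(n),
               sens_median = stats::median(df$sensitivity),
               sens_mean = mean(df$sensitivity),
               volume_mean = mean(df$volume_mm3),
               failures = sum(df$failure_flag))
  }))
}

#' Evaluate predictions against truth masks case by case
#'
#' Pairs predictions and truths by name and produces an [EvalReport-class].
#' @param preds,truths named lists of [BinaryMask-class] on common grids.
#' @param side label recorded in the report.
#' @export
evaluateMasks <- function(preds, truths, side = "left") {
  ids <- intersect(names(preds), names(truths))
  if (!length(ids)) stop("no common subject ids between preds and truths")
  rows <- lapply(ids, function(id) {
    p <- preds[[id]]; t <- truths[[id]]
    empty <- isTRUE(attr(p@data, "empty")) || sum(p@data) == 0
    data.frame(subject_id = id, side = side,
               dice = diceScore(p, t),
               sensitivity = sensitivityScore(p, t),
               volume_mm3 = maskVolume(p), failure_flag = empty)
  })
  perCase <- do.call(rbind, rows)
  new("EvalReport", perCase = perCase,
      summary = .eval_summary(perCase), stats = list())
}

#' Cohort-level summary statistics
#'
#' Paired two-sided t-test between left and right volumes, Pearson
#' correlation between left and right Dice scores, and means with SEM.
#' Degenerate inputs are handled explicitly: identical paired volumes give
#' t = 0, p = 1; a zero-variance Dice vector flags the correlation as
#' undefined instead of erroring.
#'
#' @param volumesLeft,volumesRight paired volume vectors (mm^3), n >= 3.
#' @param dicesLeft,dicesRight paired Dice vectors.
#' @return list with elements `volume_t` (statistic, p.value, mean_left,
#'   mean_right, sem_left, sem_right) and `dice_cor` (r, p.value, flag).
#' @export
cohortStats <- function(volumesLeft, volumesRight, dicesLeft, dicesRight) {
  if (length(volumesLeft) != length(volumesRight) ||
      length(dicesLeft) != length(dicesRight))
    stop("paired vectors must have equal length")
  n <- length(volumesLeft)
  if (n < 3) stop("need n >= 3 for cohort statistics")
  dif <- volumesLeft - volumesRight
  if (stats::sd(dif) == 0) {
    # zero-variance differences: identical arrays give t = 0, p = 1; a
    # constant nonzero shift is an infinitely strong paired difference
    vt <- if (mean(dif) == 0) list(statistic = 0, p.value = 1)
          else list(statistic = sign(mean(dif)) * Inf, p.value = 0)
  } else {
    tt <- stats::t.test(volumesLeft, volumesRight, paired = TRUE)
    vt <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  if (stats::sd(dicesLeft) == 0 || stats::sd(dicesRight) == 0) {
    dc <- list(r = NA_real_, p.value = NA_real_, flag = "zero_variance")
  } else {
    ct <- stats::cor.test(dicesLeft, dicesRight)
    dc <- list(r = unname(ct$estimate), p.value = ct$p.value, flag = "ok")
  }
  list(volume_t = c(vt, list(mean_left = mean(volumesLeft),
                             mean_right = mean(volumesRight),
                             sem_left = sem(volumesLeft),
                             sem_right = sem(volumesRight))),
       dice_cor = dc, n = n)
}

#' Write an EvalReport as TSV
#'
#' Per-case rows followed by a summary footer (rows prefixed `#summary`).
#' @param report an [EvalReport-class].
#' @param path output TSV path.
#' @export
writeReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(report@perCase, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- report@summary
  s <- cbind(data.frame(marker = rep("#summary", nrow(s))), s)
  utils::write.table(s, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
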