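#' Regional means of scalar maps under a mask
#'
#' For each named map, the mask is propagated to the map's grid when the
#' grids differ (soft linear warp, then binarization at 0.5 — the rule
#' used when moving masks from the native T1w grid to the coarser dMRI
#' grid) and the arithmetic mean of the map values under the mask is
#' taken. A mask that is empty after propagation yields `NA` with a flag.
#'
#' @param mask a [BinaryMask-class] (or [SoftMask-class], binarized at
#'   0.5 first).
#' @param maps named list of [BrainVolume-class] scalar maps.
#' @return named numeric vector of means, with attribute `flags` naming
#'   maps whose propagated mask was empty.
#' @export
regionalMeans <- function(mask, maps) {
  if (is.null(names(maps)) || any(!nzchar(names(maps))))
    stop("maps must be a named list")
  if (is(mask, "SoftMask"))
    mask <- BinaryMask(mask@data >= 0.5, like = mask)
  out <- numeric(length(maps))
  names(out) <- names(maps)
  flags <- character()
  for (nm in names(maps)) {
    mp <- maps[[nm]]
    m <- if (sameGrid(mask, mp)) mask else resampleMask(mask, mp)
    sel <- m@data != 0
    if (!any(sel)) {
      out[nm] <- NA_real_
      flags <- c(flags, nm)
    } else {
      out[nm] <- mean(mp@data[sel])
    }
  }
  attr(out, "flags") <- flags
  out
}

#' Bonferroni-corrected correlation scan of imaging against external variables
#'
#' Pearson correlation of every (imaging, external) variable pair on
#' complete cases, with the family-wise correction applied by
#' multiplication: `p_B = min(1, p * N_imaging * N_external)`. With
#' `adjustICV = TRUE`, both members of each pair are first residualized
#' on the intracranial-volume column of `external` (partial correlation;
#' the t reference uses n - 3 degrees of freedom). Zero-variance
#' variables and pairs with fewer than 3 complete cases are flagged, not
#' silently dropped. As a guard against correlations driven by single
#' subjects, the maximal Cook's distance of the pairwise regression is
#' reported per pair (`max_cook`); pairs are flagged, never excluded.
#'
#' @param imaging data.frame of imaging variables (rows = subjects); a
#'   `subject_id` column, if present, is used to align rows with
#'   `external`.
#' @param external data.frame of non-imaging variables.
#' @param adjustICV control for intracranial volume by double
#'   residualization.
#' @param icvCol name of the ICV column in `external`.
#' @return data.frame with columns `imaging_var`, `external_var`, `n`,
#'   `r`, `p`, `p_B`, `max_cook`, `flag`, sorted by `p_B`.
#' @export
correlationScan <- function(imaging, external, adjustICV = FALSE,
                            icvCol = "ICV") {
  if ("subject_id" %in% names(imaging) && "subject_id" %in% names(external)) {
    ids <- intersect(imaging$subject_id, external$subject_id)
    imaging <- imaging[match(ids, imaging$subject_id), , drop = FALSE]
    external <- external[match(ids, external$subject_id), , drop = FALSE]
  } else if (nrow(imaging) != nrow(external)) {
    stop("imaging and external tables must have matching rows or subject_id")
  }
  ivars <- setdiff(names(imaging), "subject_id")
  evars <- setdiff(names(external), c("subject_id",
                                      if (adjustICV) icvCol))
  if (adjustICV && !icvCol %in% names(external))
    stop("adjustICV requires an '", icvCol, "' column in external")
  nI <- length(ivars)
  nE <- length(evars)
  icv <- if (adjustICV) external[[icvCol]] else NULL
  rows <- vector("list", nI * nE)
  k <- 0L
  for (iv in ivars) for (ev in evars) {
    k <- k + 1L
    x <- imaging[[iv]]
    y <- external[[ev]]
    cc <- stats::complete.cases(x, y, if (adjustICV) icv)
    xs <- x[cc]; ys <- y[cc]
    n <- length(xs)
    flag <- ""
    r <- p <- mc <- NA_real_
    if (n < 3) {
      flag <- "too_few"
    } else if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      flag <- "zero_variance"
    } else if (adjustICV) {
      zs <- icv[cc]
      if (stats::sd(zs) == 0) {
        flag <- "zero_variance_icv"
      } else {
        rx <- stats::resid(stats::lm(xs ~ zs))
        ry <- stats::resid(stats::lm(ys ~ zs))
        r <- stats::cor(rx, ry)
        df <- n - 3
        tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tstat), df)
        mc <- max(stats::cooks.distance(stats::lm(ry ~ rx)))
      }
    } else {
      ct <- stats::cor.test(xs, ys)
      r <- unname(ct$estimate)
      p <- ct$p.value
      mc <- max(stats::cooks.distance(stats::lm(ys ~ xs)))
    }
    pB <- if (is.na(p)) NA_real_ else min(1, p * nI * nE)
    if (!is.na(mc) && mc > 1 && flag == "") flag <- "high_leverage"
    rows[[k]] <- data.frame(imaging_var = iv, external_var = ev, n = n,
                            r = r, p = p, p_B = pB, max_cook = mc,
                            flag = flag)
  }
  out <- do.call(rbind, rows)
  out[order(out$p_B), ]
}

#' Write a correlation-scan result as TSV
#' @param scan data.frame from [correlationScan()].
#' @param path output path.
#' @export
writeScan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
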