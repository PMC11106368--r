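#' Save / load a trained U-Net model
#'
#' The model is stored with its configuration fingerprint (variant, side,
#' patch, architecture, seed) so inference always reapplies the exact
#' preprocessing it was trained with.
#' @param model a [UNetModel-class].
#' @param path file path (`.rds`).
#' @export
unetSaveModel <- function(model, path) {
  saveRDS(list(weights = model@weights, config = model@config,
               lossTrace = model@lossTrace), path)
  invisible(path)
}

#' @rdname unetSaveModel
#' @export
unetLoadModel <- function(path) {
  x <- readRDS(path)
  new("UNetModel", weights = x$weights, config = x$config,
      lossTrace = x$lossTrace)
}

.cfg_err <- function(...) {
  stop(structure(class = c("lcseg_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
.data_err <- function(...) {
  stop(structure(class = c("lcseg_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
.method_err <- function(...) {
  stop(structure(class = c("lcseg_method_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.known_keys <- list(
  "make-phantom" = c("n", "seed", "site", "out"),
  "geom" = c("landmarks", "side", "ref", "out", "targetVolume",
             "maskLength"),
  "phase" = c("in", "out", "eps"),
  "elv" = c("test", "atlasDir", "side", "out", "threshold",
            "translationRadiusMm", "usePhase"),
  "train-unet" = c("casesDir", "side", "variant", "out", "patch", "epochs",
                   "baseFilters", "batch", "stride", "seed"),
  "predict" = c("model", "in", "out", "stride"),
  "atlas-build" = c("casesDir", "out"),
  "atlas-apply" = c("atlas", "in", "outPrefix"),
  "evaluate" = c("predDir", "truthDir", "side", "out"),
  "corr-scan" = c("imaging", "external", "out", "adjustICV", "icvCol")
)

.check_cfg <- function(command, config) {
  if (!command %in% names(.known_keys))
    .cfg_err("unknown command '", command, "'")
  bad <- setdiff(names(config), .known_keys[[command]])
  if (length(bad))
    .cfg_err("unknown config key(s) for '", command, "': ",
             paste(bad, collapse = ", "))
}

.need <- function(config, keys) {
  miss <- setdiff(keys, names(config))
  if (length(miss))
    .cfg_err("missing config key(s): ", paste(miss, collapse = ", "))
}

.provenance <- function(dirOrFile, command, config) {
  dir <- if (dir.exists(dirOrFile)) dirOrFile else dirname(dirOrFile)
  path <- file.path(dir, paste0(
    "provenance-", gsub("[^a-z-]", "", command), ".json"))
  jsonlite::write_json(
    list(command = command, config = config,
         package_version = as.character(utils::packageVersion("lcseg"))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.guard_overwrite <- function(paths, force) {
  hit <- paths[file.exists(paths)]
  if (length(hit) && !force)
    .cfg_err("output already exists (use force = TRUE / --force): ",
             hit[1])
}

#' Run one pipeline stage
#'
#' The config-driven entry point behind the `lcseg` command-line script:
#' one subcommand per stage (`make-phantom`, `geom`, `phase`, `elv`,
#' `train-unet`, `predict`, `atlas-build`, `atlas-apply`, `evaluate`,
#' `corr-scan`). Unknown config keys are rejected; every run writes a
#' provenance JSON (command + config + package version) next to its
#' outputs; existing outputs are never overwritten without `force`.
#'
#' Errors are classed: configuration problems signal
#' `lcseg_config_error`, unreadable/invalid data `lcseg_data_error`, and
#' method failures `lcseg_method_error` (mapped to exit codes 2/3/4 by
#' the CLI script in `inst/cli/lcseg`).
#'
#' @param command subcommand name.
#' @param config named list of arguments for the subcommand.
#' @param force overwrite existing outputs.
#' @return invisibly, a list of produced artifact paths.
#' @export
runPipeline <- function(command, config = list(), force = FALSE) {
  .check_cfg(command, config)
  switch(command,
    "make-phantom" = {
      .need(config, c("n", "seed", "out"))
      n <- as.integer(config$n)
      if (is.na(n) || n < 1) .cfg_err("n must be a positive integer")
      site <- if (is.null(config$site)) "A" else config$site
      cases <- makeCohort(n, as.integer(config$seed), site)
      dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
      .guard_overwrite(file.path(config$out, paste0(
        cases[[1]]@subjectId, "_img.nii.gz")), force)
      writeCohort(cases, config$out)
      .provenance(config$out, command, config)
      invisible(list(out = config$out))
    },
    "geom" = {
      .need(config, c("landmarks", "side", "ref", "out"))
      if (!file.exists(config$ref)) .data_err("no such image: ", config$ref)
      lm <- readLandmarks(config$landmarks)
      ref <- readVolume(config$ref)
      pars <- geometryParams()
      if (!is.null(config$targetVolume))
        pars$targetVolume <- as.numeric(config$targetVolume)
      if (!is.null(config$maskLength))
        pars$maskLength <- as.numeric(config$maskLength)
      m <- geometricLCMask(lm, config$side, ref, pars)
      .guard_overwrite(config$out, force)
      writeVolume(m, config$out)
      .provenance(config$out, command, config)
      invisible(list(out = config$out))
    },
    "phase" = {
      .need(config, c("in", "out"))
      if (!file.exists(config[["in"]]))
        .data_err("no such image: ", config[["in"]])
      eps <- if (is.null(config$eps)) 0.001 else as.numeric(config$eps)
      v <- readVolume(config[["in"]])
      .guard_overwrite(config$out, force)
      writeVolume(phaseImage(v, eps), config$out)
      .provenance(config$out, command, config)
      invisible(list(out = config$out))
    },
    "elv" = {
      .need(config, c("test", "atlasDir", "side", "out"))
      atlases <- readCohort(config$atlasDir)
      test <- readVolume(config$test)
      cfgArgs <- list()
      for (k in c("translationRadiusMm", "threshold"))
        if (!is.null(config[[k]])) cfgArgs[[k]] <- as.numeric(config[[k]])
      if (!is.null(config$usePhase))
        cfgArgs$usePhase <- isTRUE(config$usePhase) ||
          identical(config$usePhase, "true")
      soft <- elvMap(test, atlases, config$side,
                     do.call(elvConfig, cfgArgs))
      .guard_overwrite(config$out, force)
      writeVolume(soft, config$out)
      .provenance(config$out, command, config)
      invisible(list(out = config$out))
    },
    "train-unet" = {
      .need(config, c("casesDir", "side", "out"))
      cases <- readCohort(config$casesDir)
      args <- list()
      for (k in c("patch", "epochs", "baseFilters", "batch", "stride",
                  "seed"))
        if (!is.null(config[[k]])) args[[k]] <- as.numeric(config[[k]])
      if (!is.null(args$stride) && args$stride < 1)
        .cfg_err("stride must be >= 1 (got ", args$stride, ")")
      if (!is.null(config$variant)) args$variant <- config$variant
      cfg <- tryCatch(do.call(unetConfig, args),
                      error = function(e) .cfg_err(conditionMessage(e)))
      .guard_overwrite(config$out, force)
      model <- unetTrain(cases, config$side, cfg)
      unetSaveModel(model, config$out)
      .provenance(config$out, command, config)
      invisible(list(out = config$out))
    },
    "predict" = {
      .need(config, c("model", "in", "out"))
      if (!file.exists(config$model)) .data_err("no such model: ",
                                                config$model)
      model <- unetLoadModel(config$model)
      v <- readVolume(config[["in"]])
      stride <- if (is.null(config$stride)) NULL else
        as.integer(config$stride)
      .guard_overwrite(config$out, force)
      writeVolume(unetPredict(model, v, stride), config$out)
      .provenance(config$out, command, config)
      invisible(list(out = config$out))
    },
    "atlas-build" = {
      .need(config, c("casesDir", "out"))
      cases <- readCohort(config$casesDir)
      atlas <- buildFuzzyAtlas(cases)
      dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
      paths <- file.path(config$out, c("template.nii.gz",
                                       "fuzzy_left.nii.gz",
                                       "fuzzy_right.nii.gz"))
      .guard_overwrite(paths, force)
      writeVolume(atlas@templateImage, paths[1])
      writeVolume(atlas@fuzzyLeft, paths[2])
      writeVolume(atlas@fuzzyRight, paths[3])
      .provenance(config$out, command, config)
      invisible(list(out = config$out))
    },
    "atlas-apply" = {
      .need(config, c("atlas", "in", "outPrefix"))
      p <- function(f) file.path(config$atlas, f)
      if (!file.exists(p("template.nii.gz")))
        .data_err("no atlas found under ", config$atlas)
      tmplV <- readVolume(p("template.nii.gz"))
      atlas <- new("FuzzyAtlas", templateImage = tmplV,
        fuzzyLeft = SoftMask(.clip01(
          readVolume(p("fuzzy_left.nii.gz"))@data), like = tmplV),
        fuzzyRight = SoftMask(.clip01(
          readVolume(p("fuzzy_right.nii.gz"))@data), like = tmplV))
      test <- readVolume(config[["in"]])
      res <- applyAtlas(atlas, test)
      if (!res$converged)
        warning("registration did not converge; results flagged")
      outs <- paste0(config$outPrefix, c("left.nii.gz", "right.nii.gz"))
      .guard_overwrite(outs, force)
      writeVolume(res$left, outs[1])
      writeVolume(res$right, outs[2])
      .provenance(outs[1], command, config)
      invisible(list(left = outs[1], right = outs[2],
                     converged = res$converged))
    },
    "evaluate" = {
      .need(config, c("predDir", "truthDir", "side", "out"))
      loadMasks <- function(dir) {
        fs <- list.files(dir, pattern = "\\.nii(\\.gz)?$",
                         full.names = TRUE)
        if (!length(fs)) .data_err("no masks under ", dir)
        ms <- lapply(fs, function(f) {
          v <- readVolume(f)
          BinaryMask(v@data >= 0.5, like = v)
        })
        names(ms) <- sub("\\.nii(\\.gz)?$", "", basename(fs))
        ms
      }
      rep <- evaluateMasks(loadMasks(config$predDir),
                           loadMasks(config$truthDir), config$side)
      .guard_overwrite(config$out, force)
      writeReport(rep, config$out)
      .provenance(config$out, command, config)
      invisible(list(out = config$out))
    },
    "corr-scan" = {
      .need(config, c("imaging", "external", "out"))
      readTab <- function(f) {
        if (!file.exists(f)) .data_err("no such table: ", f)
        sep <- if (grepl("\\.csv$", f)) "," else "\t"
        utils::read.table(f, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
      }
      adj <- isTRUE(config$adjustICV) || identical(config$adjustICV, "true")
      scan <- correlationScan(readTab(config$imaging),
                              readTab(config$external), adjustICV = adj,
                              icvCol = if (is.null(config$icvCol)) "ICV"
                                       else config$icvCol)
      .guard_overwrite(config$out, force)
      writeScan(scan, config$out)
      .provenance(config$out, command, config)
      invisible(list(out = config$out))
    }
  )
}
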