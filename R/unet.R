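#' Configuration of the patch-based 3D U-Net
#'
#' Defaults mirror the reference training recipe: two down-sampling
#' stages, 16 initial filters, 132-voxel cubic patches, mini-batch 8,
#' 20 epochs of Adam starting at learning rate 0.002 and dropping by 95%
#' every five epochs, and stride-10 overlap-averaged inference. For CPU
#' desk-scale experiments the patch, filter count, batch and epochs are
#' reduced (see the package vignette); the architecture and schedule are
#' unchanged.
#'
#' @param depth number of down-sampling stages.
#' @param baseFilters filters at the first convolution.
#' @param patch cubic patch edge in voxels; must be divisible by 2^depth.
#' @param stride sliding-window stride in voxels for inference, >= 1.
#' @param epochs training epochs.
#' @param batch cases per mini-batch (one patch is drawn per case).
#' @param stepsPerEpoch gradient steps per epoch; `NULL` means one pass
#'   over the training cases (`ceiling(nCases / batch)`).
#' @param lr0 initial learning rate.
#' @param lrDropFactor,lrDropEvery multiply the rate by `lrDropFactor`
#'   every `lrDropEvery` epochs (0.05 every 5 = a 95% drop).
#' @param variant input representation: `"image"`, `"nmz"`, `"phase"`,
#'   `"image+phase"` or `"nmz+phase"`. The `nmz` variants are intensity
#'   standard-deviation normalized and additionally patch-wise zero-meaned
#'   and normalized at the input layer.
#' @param posFraction fraction of training patches whose centre is drawn
#'   from the target mask (class-imbalance countermeasure).
#' @param smooth Dice-loss smoothing term, voxels.
#' @param objective `"gdice"` (default) trains with the two-class
#'   generalized Dice loss, weighting foreground and background by their
#'   inverse squared volumes — the class-balanced Dice formulation that
#'   standard Dice segmentation layers implement, without which a
#'   sub-0.2%-prevalence target collapses the plain Dice objective to an
#'   all-background prediction. `"dice"` trains with the plain [diceLoss()].
#' @param seed RNG seed; training is deterministic given the seed.
#' @return named list of class `"UNetConfig"`.
#' @export
unetConfig <- function(depth = 2, baseFilters = 16, patch = 132, stride = 10,
                       epochs = 20, batch = 8, stepsPerEpoch = NULL,
                       lr0 = 0.002, lrDropFactor = 0.05, lrDropEvery = 5,
                       variant = c("image", "nmz", "phase", "image+phase",
                                   "nmz+phase"),
                       posFraction = 0.5, smooth = 1,
                       objective = c("gdice", "dice"), seed = 1L) {
  variant <- match.arg(variant)
  objective <- match.arg(objective)
  if (patch %% 2^depth != 0)
    stop("patch must be divisible by 2^depth")
  if (stride < 1) stop("stride must be >= 1")
  if (depth < 1 || depth > 3) stop("depth must be 1, 2 or 3")
  structure(list(depth = depth, baseFilters = baseFilters, patch = patch,
                 stride = stride, epochs = epochs, batch = batch,
                 stepsPerEpoch = stepsPerEpoch, lr0 = lr0,
                 lrDropFactor = lrDropFactor, lrDropEvery = lrDropEvery,
                 variant = variant, posFraction = posFraction,
                 smooth = smooth, objective = objective,
                 seed = as.integer(seed)),
            class = "UNetConfig")
}

#' Learning rate at a given epoch
#'
#' `lr0 * lrDropFactor^floor((epoch - 1) / lrDropEvery)`: with the default
#' schedule, epochs 1, 6, 11, 16 use 0.002, 1e-4, 5e-6, 2.5e-7.
#' @param epoch epoch number (1-based).
#' @param lr0,dropFactor,dropEvery schedule parameters.
#' @export
lrSchedule <- function(epoch, lr0 = 0.002, dropFactor = 0.05, dropEvery = 5) {
  lr0 * dropFactor^floor((epoch - 1) / dropEvery)
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p t) + s) / (sum(p) + sum(t) + s)` with smoothing `s`,
#' which stabilizes empty patches. Accepts arrays or mask objects of equal
#' shape.
#' @param pred soft prediction in `[0, 1]`.
#' @param target binary target.
#' @param smooth smoothing term `s`.
#' @export
diceLoss <- function(pred, target, smooth = 1) {
  p <- if (is(pred, "BrainVolume")) pred@data else pred
  t <- if (is(target, "BrainVolume")) target@data else target
  if (!identical(dim(p), dim(t)))
    stop("pred and target must have identical shape")
  1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

# ---- input representations ------------------------------------------------

# List of channel volumes for a variant; patch-wise normalization (if any)
# happens at patch extraction, matching an input-layer normalization.
.unet_channels <- function(v, variant, epsilonFrac = 0.001) {
  switch(variant,
    "image" = list(v),
    "nmz" = list(normalizeStd(v)),
    "phase" = list(phaseImage(v, epsilonFrac)),
    "image+phase" = list(v, phaseImage(v, epsilonFrac)),
    "nmz+phase" = list(normalizeStd(v), phaseImage(v, epsilonFrac)))
}

.unet_patchnorm <- function(variant) variant %in% c("nmz", "nmz+phase")

# Stack channels into a 4D array, zero-padded to at least `patch` per axis
# (symmetric); returns the array and the crop indices of the original grid.
.unet_stack <- function(channels, patch) {
  d <- dim(channels[[1]]@data)
  pd <- pmax(d, patch)
  lo <- (pd - d) %/% 2
  x <- array(0, c(pd, length(channels)))
  for (ci in seq_along(channels))
    x[lo[1] + 1:d[1], lo[2] + 1:d[2], lo[3] + 1:d[3], ci] <-
      channels[[ci]]@data
  list(x = x, lo = lo, dim = d)
}

.patch_normalize <- function(p) {
  for (ci in seq_len(dim(p)[4])) {
    v <- p[, , , ci]
    p[, , , ci] <- (v - mean(v)) / (stats::sd(v) + 1e-8)
  }
  p
}

# ---- network definition ---------------------------------------------------

.he_mat <- function(cin, cout) {
  matrix(stats::rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))),
         27 * cin, cout)
}

.unet_init <- function(cin, depth, F) {
  w <- list()
  ci <- cin
  for (i in seq_len(depth)) {
    co <- F * 2^(i - 1)
    w[[sprintf("enc%da", i)]] <- list(W = .he_mat(ci, co), b = numeric(co))
    w[[sprintf("enc%db", i)]] <- list(W = .he_mat(co, co), b = numeric(co))
    ci <- co
  }
  co <- F * 2^depth
  w[["bota"]] <- list(W = .he_mat(ci, co), b = numeric(co))
  w[["botb"]] <- list(W = .he_mat(co, co), b = numeric(co))
  ci <- co
  for (i in rev(seq_len(depth))) {
    co <- F * 2^(i - 1)
    w[[sprintf("dec%dr", i)]] <- list(W = .he_mat(ci, co), b = numeric(co))
    w[[sprintf("dec%da", i)]] <- list(W = .he_mat(2 * co, co), b = numeric(co))
    w[[sprintf("dec%db", i)]] <- list(W = .he_mat(co, co), b = numeric(co))
    ci <- co
  }
  # final 1x1x1 conv; bias starts negative so the initial foreground
  # probability is small (the target occupies a tiny fraction of a patch)
  w[["out"]] <- list(W = matrix(stats::rnorm(F, sd = sqrt(2 / F)), F, 1),
                     b = -2)
  w
}

# conv -> instance norm -> ReLU. Per-channel standardization keeps the
# activation scale fixed throughout training, which matters when the
# optimizer only takes a few hundred steps.
.conv_relu_fwd <- function(x, layer) {
  z <- c_conv3d_fwd(x, dim(x), layer$W, layer$b)
  d <- dim(z)
  zm <- matrix(z, ncol = d[4])
  mu <- colMeans(zm)
  sd <- sqrt(colMeans(zm^2) - mu^2 + 1e-6)
  yh <- sweep(sweep(zm, 2, mu), 2, sd, "/")
  yhat <- array(yh, d)
  list(x = x, y = pmax(yhat, 0), yhat = yhat, sd = sd, mask = yhat > 0)
}

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

.downsum2 <- function(dy) {
  d <- dim(dy)
  h <- d[1:3] / 2
  a <- array(dy, c(2, h[1], 2, h[2], 2, h[3], d[4]))
  s <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    s <- s + a[i, , j, , k, , , drop = FALSE]
  array(s, c(h, d[4]))
}

.unet_forward <- function(x, weights, depth) {
  cache <- list(enc = vector("list", depth), pool = vector("list", depth))
  cur <- x
  for (i in seq_len(depth)) {
    a <- .conv_relu_fwd(cur, weights[[sprintf("enc%da", i)]])
    b <- .conv_relu_fwd(a$y, weights[[sprintf("enc%db", i)]])
    p <- c_maxpool_fwd(b$y, dim(b$y))
    cache$enc[[i]] <- list(a = a, b = b)
    cache$pool[[i]] <- list(idx = p$idx, dimIn = dim(b$y))
    cur <- p$y
  }
  ba <- .conv_relu_fwd(cur, weights[["bota"]])
  bb <- .conv_relu_fwd(ba$y, weights[["botb"]])
  cache$bot <- list(a = ba, b = bb)
  cur <- bb$y
  cache$dec <- vector("list", depth)
  for (i in rev(seq_len(depth))) {
    up <- .upsample2(cur)
    r <- .conv_relu_fwd(up, weights[[sprintf("dec%dr", i)]])
    skip <- cache$enc[[i]]$b$y
    cat4 <- array(c(r$y, skip), c(dim(r$y)[1:3], dim(r$y)[4] + dim(skip)[4]))
    a <- .conv_relu_fwd(cat4, weights[[sprintf("dec%da", i)]])
    b <- .conv_relu_fwd(a$y, weights[[sprintf("dec%db", i)]])
    cache$dec[[i]] <- list(r = r, a = a, b = b, nr = dim(r$y)[4])
    cur <- b$y
  }
  d <- dim(cur)
  Fc <- d[4]
  feat <- matrix(cur, ncol = Fc)
  logits <- as.vector(feat %*% weights[["out"]]$W) + weights[["out"]]$b
  pred <- array(stats::plogis(logits), d[1:3])
  cache$final <- list(feat = feat, dimOut = d[1:3])
  cache$pred <- pred
  cache
}

.conv_relu_bwd <- function(layer, cacheL, dyPost) {
  d <- dim(cacheL$yhat)
  dyh <- matrix(dyPost * cacheL$mask, ncol = d[4])
  yh <- matrix(cacheL$yhat, ncol = d[4])
  # instance-norm backward: dz = (dyh - mean(dyh) - yh * mean(dyh * yh)) / sd
  dz <- sweep(dyh, 2, colMeans(dyh)) - sweep(yh, 2, colMeans(dyh * yh), "*")
  dz <- sweep(dz, 2, cacheL$sd, "/")
  c_conv3d_bwd(cacheL$x, dim(cacheL$x), layer$W, array(dz, d))
}

.unet_backward <- function(weights, cache, depth, dPred) {
  grads <- list()
  pred <- cache$pred
  dLogits <- as.vector(dPred) * as.vector(pred * (1 - pred))
  feat <- cache$final$feat
  grads[["out"]] <- list(W = crossprod(feat, dLogits), b = sum(dLogits))
  dFeat <- outer(dLogits, as.vector(weights[["out"]]$W))
  cur <- array(dFeat, c(cache$final$dimOut, ncol(feat)))
  # decoder, from the top (full-resolution) level down to the bottleneck
  dskip <- vector("list", depth)
  for (i in seq_len(depth)) {
    dc <- cache$dec[[i]]
    gb <- .conv_relu_bwd(weights[[sprintf("dec%db", i)]], dc$b, cur)
    grads[[sprintf("dec%db", i)]] <- list(W = gb$dW, b = gb$db)
    ga <- .conv_relu_bwd(weights[[sprintf("dec%da", i)]], dc$a, gb$dx)
    grads[[sprintf("dec%da", i)]] <- list(W = ga$dW, b = ga$db)
    nr <- dc$nr
    dcat <- ga$dx
    dr <- dcat[, , , seq_len(nr), drop = FALSE]
    dskip[[i]] <- dcat[, , , nr + seq_len(dim(dcat)[4] - nr), drop = FALSE]
    gr <- .conv_relu_bwd(weights[[sprintf("dec%dr", i)]], dc$r, dr)
    grads[[sprintf("dec%dr", i)]] <- list(W = gr$dW, b = gr$db)
    cur <- .downsum2(gr$dx)  # gradient wrt the level below's output
  }
  # bottleneck
  gbb <- .conv_relu_bwd(weights[["botb"]], cache$bot$b, cur)
  grads[["botb"]] <- list(W = gbb$dW, b = gbb$db)
  gba <- .conv_relu_bwd(weights[["bota"]], cache$bot$a, gbb$dx)
  grads[["bota"]] <- list(W = gba$dW, b = gba$db)
  dPoolOut <- gba$dx  # gradient wrt the deepest pooling output
  # encoder, from the deepest level back to the input
  for (i in rev(seq_len(depth))) {
    pool <- cache$pool[[i]]
    dEncOut <- dskip[[i]] +
      c_maxpool_bwd(dPoolOut, pool$idx, as.integer(pool$dimIn))
    gb2 <- .conv_relu_bwd(weights[[sprintf("enc%db", i)]],
                          cache$enc[[i]]$b, dEncOut)
    grads[[sprintf("enc%db", i)]] <- list(W = gb2$dW, b = gb2$db)
    ga2 <- .conv_relu_bwd(weights[[sprintf("enc%da", i)]],
                          cache$enc[[i]]$a, gb2$dx)
    grads[[sprintf("enc%da", i)]] <- list(W = ga2$dW, b = ga2$db)
    dPoolOut <- ga2$dx  # feeds the pooling of the level above
  }
  grads
}

# ---- training -------------------------------------------------------------

# Training objective and its gradient wrt the soft prediction.
# "dice": plain soft Dice. "gdice": two-class generalized Dice with
# inverse-squared-volume class weights, which keeps foreground gradients
# alive under extreme class imbalance.
.dice_objective <- function(p, t, s, objective) {
  if (objective == "dice") {
    num <- 2 * sum(p * t) + s
    den <- sum(p) + sum(t) + s
    return(list(loss = 1 - num / den,
                dP = -(2 * t * den - num) / den^2))
  }
  N <- length(t)
  st <- sum(t)
  w1 <- 1 / (st + s)^2
  w0 <- 1 / (N - st + s)^2
  num <- w1 * sum(p * t) + w0 * sum((1 - p) * (1 - t))
  den <- w1 * (sum(p) + st) + w0 * (2 * N - sum(p) - st)
  dnum <- w1 * t - w0 * (1 - t)
  dden <- w1 - w0
  list(loss = 1 - 2 * num / den,
       dP = -2 * (dnum * den - num * dden) / den^2)
}

.adam_init <- function(weights) {
  lapply(weights, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                   mb = l$b * 0, vb = l$b * 0))
}

.adam_step <- function(weights, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    weights[[nm]]$W <- weights[[nm]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    weights[[nm]]$b <- weights[[nm]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(weights = weights, state = state)
}

# Draw one training patch from a prepared case. `pos` centres the patch
# near a random target voxel (with quarter-patch jitter, so the target
# does not always sit at the patch centre — inference windows land at
# arbitrary offsets). Negative draws rotate through uniform patches and
# two kinds of hard negatives: the contralateral mask (the decisive
# lesson for telling the trained side from its mirror image) and the
# rostro-caudal flanks of the target (which sharpen the along-axis
# extent of the prediction).
.draw_patch <- function(prep, patch, pos) {
  pd <- dim(prep$x)[1:3]
  maxo <- pd - patch
  j <- patch %/% 4
  centre_at <- function(ctr) {
    pmin(pmax(ctr - patch %/% 2 + sample(-j:j, 3, replace = TRUE), 0), maxo)
  }
  pick <- function(idxset)
    as.vector(arrayInd(idxset[sample.int(length(idxset), 1L)], pd))
  if (pos && length(prep$targetIdx)) {
    o <- centre_at(pick(prep$targetIdx))
  } else {
    u <- stats::runif(1)
    if (length(prep$oppIdx) && u < 1 / 3) {
      o <- centre_at(pick(prep$oppIdx))
    } else if (length(prep$targetIdx) && u < 2 / 3) {
      ctr <- pick(prep$targetIdx)
      ctr[3] <- ctr[3] + sample(c(-1, 1), 1) * sample(10:20, 1)
      o <- centre_at(ctr)
    } else {
      o <- c(sample.int(maxo[1] + 1L, 1L), sample.int(maxo[2] + 1L, 1L),
             sample.int(maxo[3] + 1L, 1L)) - 1L
    }
  }
  list(x = prep$x[o[1] + 1:patch, o[2] + 1:patch, o[3] + 1:patch, ,
                  drop = FALSE],
       y = prep$t[o[1] + 1:patch, o[2] + 1:patch, o[3] + 1:patch])
}

#' Train the 3D U-Net on a set of cases
#'
#' Per epoch, the cases are traversed in a random order in mini-batches of
#' `batch`, drawing one patch per case; a `posFraction` share of the draws
#' is constrained to contain target-mask voxels (the target occupies a few
#' dozen voxels of a multi-million-voxel volume, so unconstrained sampling
#' would rarely see it). Gradients are averaged over the mini-batch and
#' applied with Adam under the dropping learning-rate schedule. Training
#' is deterministic given `config$seed` (seeded initialization and
#' sampling, deterministic single-threaded kernels).
#'
#' @param cases list of [TrainingCase-class] (>= 2).
#' @param side `"left"` or `"right"`: which presumptive mask to learn.
#' @param config a [unetConfig()].
#' @return a [UNetModel-class] with the per-epoch mean Dice-loss trace.
#' @export
unetTrain <- function(cases, side = c("left", "right"),
                      config = unetConfig()) {
  side <- match.arg(side)
  if (length(cases) < 2L) stop("need at least 2 training cases")
  patch <- config$patch
  set.seed(config$seed)
  preps <- lapply(cases, function(cs) {
    ch <- .unet_channels(cs@image, config$variant)
    st <- .unet_stack(ch, patch)
    m <- if (side == "left") cs@maskLeft else cs@maskRight
    opp <- if (side == "left") cs@maskRight else cs@maskLeft
    t <- array(0, dim(st$x)[1:3])
    t[st$lo[1] + 1:st$dim[1], st$lo[2] + 1:st$dim[2],
      st$lo[3] + 1:st$dim[3]] <- m@data
    to <- array(0, dim(st$x)[1:3])
    to[st$lo[1] + 1:st$dim[1], st$lo[2] + 1:st$dim[2],
       st$lo[3] + 1:st$dim[3]] <- opp@data
    list(x = st$x, t = t, targetIdx = which(t > 0), oppIdx = which(to > 0))
  })
  cin <- dim(preps[[1]]$x)[4]
  weights <- .unet_init(cin, config$depth, config$baseFilters)
  state <- .adam_init(weights)
  steps <- if (is.null(config$stepsPerEpoch))
    ceiling(length(cases) / config$batch) else config$stepsPerEpoch
  doNorm <- .unet_patchnorm(config$variant)
  trace <- numeric(config$epochs)
  t_adam <- 0L
  for (ep in seq_len(config$epochs)) {
    lr <- lrSchedule(ep, config$lr0, config$lrDropFactor, config$lrDropEvery)
    order <- sample.int(length(cases))
    losses <- c()
    ptr <- 1L
    for (st in seq_len(steps)) {
      grads <- NULL
      nb <- 0L
      bloss <- 0
      for (bi in seq_len(config$batch)) {
        ci <- order[(ptr - 1L) %% length(cases) + 1L]
        ptr <- ptr + 1L
        pos <- stats::runif(1) < config$posFraction
        pt <- .draw_patch(preps[[ci]], patch, pos)
        x <- if (doNorm) .patch_normalize(pt$x) else pt$x
        cache <- .unet_forward(x, weights, config$depth)
        p <- cache$pred
        lo <- .dice_objective(p, pt$y, config$smooth, config$objective)
        bloss <- bloss + lo$loss
        g <- .unet_backward(weights, cache, config$depth, lo$dP)
        grads <- if (is.null(grads)) g else
          mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                 grads[names(weights)], g[names(weights)], SIMPLIFY = FALSE)
        nb <- nb + 1L
      }
      grads <- lapply(grads[names(weights)],
                      function(g) list(W = g$W / nb, b = g$b / nb))
      t_adam <- t_adam + 1L
      upd <- .adam_step(weights, grads, state, lr, t_adam)
      weights <- upd$weights
      state <- upd$state
      losses <- c(losses, bloss / nb)
    }
    trace[ep] <- mean(losses)
  }
  cfg <- unclass(config)
  cfg$side <- side
  cfg$cin <- cin
  new("UNetModel", weights = weights, config = cfg, lossTrace = trace)
}

# ---- inference ------------------------------------------------------------

#' Overlap-averaged sliding-window application of a patch scorer
#'
#' Applies `fun` (mapping a `patch^3 x channels` array to a `patch^3`
#' score array) at every window origin of the sliding grid (all positions
#' `seq(0, n - patch, stride)` per axis, plus the final position flush
#' with the far edge), and averages the scores of all windows covering
#' each voxel. The per-voxel window counts are returned in the
#' `"coverage"` attribute.
#'
#' @param fun patch scoring function.
#' @param x 4D input array (x, y, z, channels), every axis >= `patch`.
#' @param patch window edge, voxels.
#' @param stride window stride, voxels.
#' @return 3D array of averaged scores with attribute `coverage`.
#' @export
slidingWindowMap <- function(fun, x, patch, stride) {
  d <- dim(x)[1:3]
  if (any(d < patch)) stop("input smaller than the patch")
  stride <- min(stride, patch)  # a larger stride would leave voxels uncovered
  origins <- lapply(d, function(n)
    unique(c(seq(0L, n - patch, by = stride), n - patch)))
  acc <- array(0, d)
  cnt <- array(0, d)
  for (oz in origins[[3]]) for (oy in origins[[2]]) for (ox in origins[[1]]) {
    ix <- ox + 1:patch; iy <- oy + 1:patch; iz <- oz + 1:patch
    sc <- fun(x[ix, iy, iz, , drop = FALSE])
    acc[ix, iy, iz] <- acc[ix, iy, iz] + sc
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  out <- acc / cnt
  attr(out, "coverage") <- cnt
  out
}

#' Predict a soft LC mask with a trained U-Net
#'
#' Builds the model's input representation from the raw image, zero-pads
#' to at least the patch size, scores overlapping patches at the
#' configured stride and averages them, then crops back to the input grid.
#'
#' @param model a [UNetModel-class] (or a plain `function(patchArray)`
#'   scorer, useful for oracle checks).
#' @param v the raw test [BrainVolume-class].
#' @param stride optional stride override.
#' @return a [SoftMask-class] on the grid of `v`.
#' @export
unetPredict <- function(model, v, stride = NULL) {
  if (is.function(model)) stop("use slidingWindowMap for plain functions")
  cfg <- model@config
  stride <- if (is.null(stride)) cfg$stride else stride
  ch <- .unet_channels(v, cfg$variant)
  st <- .unet_stack(ch, cfg$patch)
  doNorm <- .unet_patchnorm(cfg$variant)
  w <- model@weights
  fun <- function(p) {
    if (doNorm) p <- .patch_normalize(p)
    .unet_forward(p, w, cfg$depth)$pred
  }
  sc <- slidingWindowMap(fun, st$x, cfg$patch, stride)
  d <- st$dim
  lo <- st$lo
  cropped <- sc[lo[1] + 1:d[1], lo[2] + 1:d[2], lo[3] + 1:d[3]]
  # brain-extracted inputs are zero-background: scores outside the head
  # are meaningless (normalized near-empty patches amplify noise there)
  cropped[v@data == 0] <- 0
  SoftMask(array(pmin(1, pmax(0, cropped)), d), like = v)
}

#' U-Net as a LOOCV method
#'
#' Returns a `function(trainCases, testCase, side)` for [runLOOCV()];
#' each fold trains a fresh model with the given configuration.
#' @param config a [unetConfig()].
#' @export
unetMethod <- function(config = unetConfig()) {
  function(train, test, side) {
    m <- unetTrain(train, side, config)
    unetPredict(m, test@image)
  }
}

#' Geometric landmark rule as a LOOCV method
#'
#' Ignores the training cases and applies [geometricLCMask()] with the
#' test case's landmarks (the protocol needs no training).
#' @param params a [geometryParams()].
#' @export
geomMethod <- function(params = geometryParams()) {
  function(train, test, side)
    geometricLCMask(test@landmarks, side, test@image, params)
}
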