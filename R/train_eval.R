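#' Training configuration
#'
#' Adam with the published hyperparameters: constant learning rate 2e-4,
#' momentum coefficients 0.5 / 0.999, cross-entropy loss, batch size 4.
#'
#' @param epochs training epochs (published setting: 500; scale down for
#'   quick experiments).
#' @param batchSize mini-batch size.
#' @param inputHW network input size `c(H, W)`; images are resized
#'   bilinearly, labels with nearest neighbor.
#' @param lr learning rate.
#' @param beta1,beta2 Adam momentum coefficients.
#' @param seed integer seed controlling initialization and batch order.
#' @param verbose print per-epoch loss.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 500L, batchSize = 4L,
                        inputHW = c(256L, 256L), lr = 2e-4, beta1 = 0.5,
                        beta2 = 0.999, seed = 1L, verbose = FALSE) {
  stopifnot(lr > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 inputHW = as.integer(inputHW), lr = lr, beta1 = beta1,
                 beta2 = beta2, seed = as.integer(seed), verbose = verbose),
            class = "TrainConfig")
}

adamStep <- function(layers, grads, state, lr, beta1, beta2, t, eps = 1e-8) {
  if (is.null(state)) state <- walkParams(layers, NULL, function(p, g)
    list(m = p * 0, v = p * 0))
  newState <- walkParams2(state, grads, function(s, g) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    s
  })
  lrT <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  layers <- walkParams2(layers, newState, function(p, s)
    p - lrT * s$m / (sqrt(s$v) + eps))
  list(layers = layers, state = newState)
}

# Like walkParams but the "parameters" of the first tree may be lists
# (Adam state holds list(m, v) at each leaf position of the layer tree).
walkParams2 <- function(m, g, fn) {
  idx <- if (is.null(names(m))) seq_along(m) else names(m)
  for (nm in idx) {
    if (is.character(nm) && nm %in% .skipNames) next
    mi <- m[[nm]]
    if (is.null(mi)) next
    gi <- g[[nm]]
    leaf <- is.numeric(mi) ||
      (is.list(mi) && identical(sort(names(mi)), c("m", "v")))
    if (leaf) m[[nm]] <- fn(mi, gi)
    else if (is.list(mi)) m[[nm]] <- walkParams2(mi, gi, fn)
  }
  m
}

# Stack a list of (H, W, C) arrays / (H, W) labels into network tensors.
stackImages <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], d[3], length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x
}

stackLabels <- function(labels) {
  d <- dim(labels[[1]])
  y <- array(0L, c(d[1], d[2], length(labels)))
  for (i in seq_along(labels)) y[, , i] <- labels[[i]]
  y
}

# Copy updated BN running statistics out of forward caches into the model.
updateRunningStats <- function(model, fw) {
  syncLevel <- function(blocks, caches) {
    for (j in seq_along(blocks)) {
      blocks[[j]]$bn$rm <- caches[[j]]$bn$rm
      blocks[[j]]$bn$rv <- caches[[j]]$bn$rv
    }
    blocks
  }
  L <- length(model$cfg@channels)
  for (i in seq_len(L))
    model$layers$enc[[i]] <- syncLevel(model$layers$enc[[i]], fw$cache$encC[[i]])
  for (i in seq_len(L - 1)) {
    model$layers$dec[[i]] <- syncLevel(model$layers$dec[[i]], fw$cache$decC[[i]])
    a <- fw$cache$asppC[[i]]
    if (!is.null(a) && !is.null(a$bn)) {
      model$layers$aspp[[i]]$bn$rm <- a$bn$rm
      model$layers$aspp[[i]]$bn$rv <- a$bn$rv
    }
  }
  model
}

#' Train the segmentation network
#'
#' Full-batch shuffled mini-batch training with Adam and pixel-wise
#' cross-entropy.  Images are rescaled to `[0, 1]` and resized to
#' `cfg$inputHW` (bilinear); labels are resized with nearest neighbor.
#' Fully seeded: two runs with the same config, data and starting model are
#' identical.
#'
#' @param model a built `CCRDNetModel`, or a [NetConfig-class] (a model is
#'   then built with the config seed).
#' @param images list of `H x W x 3` arrays in 0..255.
#' @param labels list of integer label matrices.
#' @param cfg a [trainConfig()].
#' @return list with `model` (trained), `lossCurve` (per-epoch mean loss)
#'   and `bestEpoch`.
#' @export
trainModel <- function(model, images, labels, cfg = trainConfig()) {
  if (length(images) == 0L) stop("empty dataset")
  if (is(model, "NetConfig"))
    model <- withLocalSeed(cfg$seed, buildModel(model))
  K <- model$cfg@nClasses
  rng <- range(unlist(lapply(labels, range)))
  if (rng[1] < 0 || rng[2] >= K) stop("label values outside class range")
  H <- cfg$inputHW[1]; W <- cfg$inputHW[2]
  xs <- lapply(images, function(im) resizeBilinear(im, H, W) / 255)
  ys <- lapply(labels, function(lb) resizeNearest(lb, H, W))
  n <- length(xs)
  state <- NULL; t <- 0L
  lossCurve <- numeric(cfg$epochs)
  best <- list(loss = Inf, layers = model$layers, epoch = 0L)
  withLocalSeed(deriveSeed(cfg$seed, 17L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = cfg$batchSize)) {
        idx <- ord[b0:min(b0 + cfg$batchSize - 1L, n)]
        x <- stackImages(xs[idx]); y <- stackLabels(ys[idx])
        fw <- modelForward(model, x, training = TRUE)
        ce <- softmaxCE(fw$logits, y)
        grads <- modelBackward(model, fw, ce$grad)
        t <- t + 1L
        up <- adamStep(model$layers, grads, state, cfg$lr, cfg$beta1,
                       cfg$beta2, t)
        model$layers <- up$layers; state <- up$state
        model <- updateRunningStats(model, fw)
        losses <- c(losses, ce$loss)
      }
      lossCurve[ep] <- mean(losses)
      if (lossCurve[ep] < best$loss)
        best <- list(loss = lossCurve[ep], layers = model$layers, epoch = ep)
      if (cfg$verbose)
        message(sprintf("epoch %d/%d  loss %.5f", ep, cfg$epochs, lossCurve[ep]))
    }
  })
  bestModel <- model
  bestModel$layers <- best$layers
  list(model = model, bestModel = bestModel, lossCurve = lossCurve,
       bestEpoch = best$epoch)
}

#' Predict a label mask for one image
#'
#' Runs the network in evaluation mode and takes the per-pixel argmax over
#' class logits; ties resolve to the lowest class index.  The prediction is
#' computed at the network input resolution and optionally resized (nearest
#' neighbor) back to the source image size.
#'
#' @param model a trained `CCRDNetModel`.
#' @param image `H x W x 3` array in 0..255.
#' @param inputHW network input size.
#' @param resizeToInput if `TRUE` (default) the returned mask has the
#'   source image size; otherwise it stays at `inputHW`.
#' @return integer label matrix.
#' @export
predictLabel <- function(model, image, inputHW = c(256L, 256L),
                         resizeToInput = TRUE) {
  checkImage(image)
  x <- resizeBilinear(image, inputHW[1], inputHW[2]) / 255
  dim(x) <- c(dim(x), 1)
  fw <- modelForward(model, x, training = FALSE)
  lg <- fw$logits[, , , 1, drop = FALSE]
  K <- dim(lg)[3]
  pred <- matrix(1L, inputHW[1], inputHW[2])
  cur <- lg[, , 1, 1]
  for (k in 2:K) {
    sl <- lg[, , k, 1]
    upd <- sl > cur              # strict: ties keep the lower class
    pred[upd] <- k
    cur[upd] <- sl[upd]
  }
  pred <- pred - 1L
  if (resizeToInput && !all(dim(image)[1:2] == inputHW))
    pred <- resizeNearest(pred, dim(image)[1], dim(image)[2])
  pred
}

#' Pixel accuracy
#'
#' @param pred,gt integer label matrices of equal shape.
#' @return fraction of matching pixels.
#' @export
pixelAccuracy <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch")
  mean(pred == gt)
}

#' Mean intersection over union
#'
#' Per-class IoU averaged over classes; a class absent from both prediction
#' and ground truth is excluded from the mean (its IoU would be 0/0).
#'
#' @param pred,gt integer label matrices of equal shape.
#' @param nClasses number of classes.
#' @return list with `miou` and `perClass` (NA for excluded classes).
#' @export
meanIoU <- function(pred, gt, nClasses = 3L) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch")
  per <- rep(NA_real_, nClasses)
  for (k in seq_len(nClasses) - 1L) {
    p <- pred == k; g <- gt == k
    u <- sum(p | g)
    if (u > 0) per[k + 1L] <- sum(p & g) / u
  }
  list(miou = mean(per, na.rm = TRUE), perClass = per)
}

#' Evaluate a model on a scene set
#'
#' Computes segmentation metrics (pixel accuracy, mean IoU) and navigation
#' metrics (angle error, line IoU, line accuracy) over a list of rendered
#' scenes.  Labels are compared at the network input resolution; navigation
#' lines are extracted from the prediction and compared with the true line
#' re-derived at that resolution.
#'
#' @param model trained `CCRDNetModel`.
#' @param scenes list of [SceneGT-class] objects.
#' @param inputHW evaluation resolution.
#' @return list with `pa`, `miou`, `la`, `aeMean` (mean angle error over
#'   detections), `liouMean`, `nImages` and the per-image `reports`
#'   data.frame.
#' @export
evaluateModel <- function(model, scenes, inputHW = c(256L, 256L)) {
  pas <- mious <- numeric(length(scenes))
  reps <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    pred <- predictLabel(model, sc@image, inputHW, resizeToInput = FALSE)
    gtLine <- rescaleLine(sc@line, dim(sc@label), inputHW)
    gt <- composeLabels(resizeNearest(sc@vegMask * 1L, inputHW[1], inputHW[2]) > 0,
                        rasterizeLine(gtLine, inputHW), model$cfg@nClasses)
    pas[i] <- pixelAccuracy(pred, gt)
    mious[i] <- meanIoU(pred, gt, model$cfg@nClasses)$miou
    predLine <- extractNavLine(pred, lineClass = model$cfg@nClasses - 1L)
    reps[[i]] <- navReport(predLine, gtLine, inputHW)
  }
  reports <- do.call(rbind, reps)
  list(pa = mean(pas), miou = mean(mious), la = lineAccuracy(reports),
       aeMean = mean(reports$ae_deg, na.rm = TRUE),
       liouMean = mean(reports$l_iou, na.rm = TRUE),
       nImages = length(scenes), reports = reports)
}

#' Rescale a line between image resolutions
#'
#' Re-derives the navigation line in the coordinates of a resized image
#' (anisotropic scaling of the two edge crossings), rather than resampling
#' its rasterized band.
#'
#' @param line a [NavLine-class] (`xOnY`).
#' @param fromDim,toDim image sizes `c(H, W)`.
#' @return rescaled [NavLine-class].
#' @export
rescaleLine <- function(line, fromDim, toDim) {
  stopifnot(line@axis == "xOnY")
  sx <- toDim[2] / fromDim[2]; sy <- toDim[1] / fromDim[1]
  # map x = theta*y + b under (x, y) -> (sx*x, sy*y)
  navLine(theta = line@theta * sx / sy, b = line@b * sx, axis = "xOnY")
}
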