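#' Segmentation network configuration
#'
#' Architecture description of the U-shaped central-crop-row network.  The
#' network has `length(channels)` levels (the last is the bottleneck), one
#' or two convolution blocks per level, 2x2 max-pool downsampling, bilinear
#' x2 upsampling and skip connections concatenated at every level.  With
#' `useDSC` each block is a depthwise-separable convolution module
#' (depthwise 3x3 -> GELU -> pointwise 1x1 -> BatchNorm -> GELU); otherwise
#' a standard 3x3 convolution block (conv -> BatchNorm -> GELU) of the same
#' widths.  With `useASPP` the deepest three skip connections pass through
#' an atrous spatial pyramid pooling module: four parallel depthwise 3x3
#' convolutions with dilation rates `asppRates`, concatenated and projected
#' back to the skip width by a 1x1 convolution.
#'
#' The ablation grid maps `(useDSC, useASPP)` = (F,F), (F,T), (T,F), (T,T)
#' onto the baseline, +ASPP, +DSC and full variants of the network.
#'
#' @slot useDSC logical, depthwise-separable blocks.
#' @slot useASPP logical, ASPP on the deepest three skips.
#' @slot channels integer per-level widths (last = bottleneck).
#' @slot asppRates strictly increasing dilation rates (default 2, 4, 6, 8).
#' @slot nClasses output classes (default 3).
#' @slot inChannels input channels (3 for RGB).
#' @slot inputHW network input size (default 256 x 256).
#' @slot blocksPerLevel 1 or 2 convolution blocks per level.
#' @slot asppBN logical, BatchNorm after the ASPP projection.
#' @slot asppBias logical, biases on the ASPP convolutions.
#' @export
setClass("NetConfig",
  representation(useDSC = "logical", useASPP = "logical",
                 channels = "integer", asppRates = "integer",
                 nClasses = "integer", inChannels = "integer",
                 inputHW = "integer", blocksPerLevel = "integer",
                 asppBN = "logical", asppBias = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@channels) < 3L || any(object@channels < 1L))
      msg <- c(msg, "channels must be >= 3 positive widths")
    if (any(diff(object@asppRates) <= 0) || any(object@asppRates < 1L))
      msg <- c(msg, "asppRates must be strictly increasing positive integers")
    if (!object@blocksPerLevel %in% c(1L, 2L))
      msg <- c(msg, "blocksPerLevel must be 1 or 2")
    if (length(msg)) msg else TRUE
  })

#' Create a network configuration
#'
#' The default channel plan is the one produced by [solveChannelPlan()] on
#' the published parameter budgets of the four ablation variants (see the
#' methods vignette for the search and its residuals).
#'
#' @param useDSC,useASPP architecture toggles.
#' @param channels per-level widths; `NULL` = the solved default plan.
#' @param asppRates ASPP dilation rates.
#' @param nClasses number of output classes (3, or 2 for the ablation).
#' @param inChannels input channels.
#' @param inputHW network input size `c(H, W)`.
#' @param blocksPerLevel convolution blocks per level.
#' @param asppBN,asppBias ASPP normalization/bias toggles.
#' @return a [NetConfig-class].
#' @export
netConfig <- function(useDSC = TRUE, useASPP = TRUE, channels = NULL,
                      asppRates = c(2L, 4L, 6L, 8L), nClasses = 3L,
                      inChannels = 3L, inputHW = c(256L, 256L),
                      blocksPerLevel = NULL, asppBN = NULL, asppBias = NULL) {
  def <- defaultChannelPlan()
  if (is.null(channels)) channels <- def$channels
  if (is.null(blocksPerLevel)) blocksPerLevel <- def$blocksPerLevel
  if (is.null(asppBN)) asppBN <- def$asppBN
  if (is.null(asppBias)) asppBias <- def$asppBias
  new("NetConfig", useDSC = useDSC, useASPP = useASPP,
      channels = as.integer(channels), asppRates = as.integer(asppRates),
      nClasses = as.integer(nClasses), inChannels = as.integer(inChannels),
      inputHW = as.integer(inputHW),
      blocksPerLevel = as.integer(blocksPerLevel),
      asppBN = asppBN, asppBias = asppBias)
}

setMethod("show", "NetConfig", function(object) {
  cat(sprintf("NetConfig: %d levels [%s], DSC=%s, ASPP=%s (rates %s), %d classes\n",
              length(object@channels),
              paste(object@channels, collapse = ", "),
              object@useDSC, object@useASPP,
              paste(object@asppRates, collapse = ","), object@nClasses))
})

# Levels (1-based skip indices) whose skip passes through ASPP: the deepest
# three of the L - 1 skip connections.
asppLevels <- function(cfg) {
  L <- length(cfg@channels)
  seq.int(max(1L, L - 3L), L - 1L)
}

# ---- block constructors ---------------------------------------------------

heInit <- function(dims, fanIn) array(rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)

newBN <- function(C) list(gamma = rep(1, C), beta = rep(0, C),
                          rm = rep(0, C), rv = rep(1, C))

newBlock <- function(cfg, cin, cout) {
  if (cfg@useDSC)
    list(type = "dsc", wd = heInit(c(3, 3, cin), 9),
         wp = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
         bn = newBN(cout))
  else
    list(type = "std", w = heInit(c(3, 3, cin, cout), 9 * cin),
         bn = newBN(cout))
}

newASPP <- function(cfg, ch) {
  b <- list(type = "aspp",
            wd = lapply(cfg@asppRates, function(r) heInit(c(3, 3, ch), 9)),
            wp = matrix(rnorm(4 * ch * ch, 0, sqrt(2 / (4 * ch))), 4 * ch, ch))
  if (cfg@asppBias) {
    b$bd <- lapply(1:4, function(i) rep(0, ch))
    b$bp <- rep(0, ch)
  }
  if (cfg@asppBN) b$bn <- newBN(ch)
  b
}

#' Build the segmentation network
#'
#' Constructs and He-initializes all layers described by a [NetConfig-class].
#' Initialization draws from the current R RNG; call `set.seed()` first for
#' reproducible weights.
#'
#' @param cfg a [NetConfig-class].
#' @return a `CCRDNetModel` (list with elements `cfg` and `layers`).
#' @export
buildModel <- function(cfg) {
  validObject(cfg)
  ch <- cfg@channels; L <- length(ch)
  mkLevel <- function(cin, cout) {
    blocks <- list(newBlock(cfg, cin, cout))
    if (cfg@blocksPerLevel == 2L) blocks[[2]] <- newBlock(cfg, cout, cout)
    blocks
  }
  enc <- vector("list", L)
  enc[[1]] <- mkLevel(cfg@inChannels, ch[1])
  for (i in 2:L) enc[[i]] <- mkLevel(ch[i - 1], ch[i])
  dec <- vector("list", L - 1)
  for (i in (L - 1):1) dec[[i]] <- mkLevel(ch[i + 1] + ch[i], ch[i])
  aspp <- NULL
  if (cfg@useASPP) {
    aspp <- vector("list", L - 1)
    for (i in asppLevels(cfg)) aspp[[i]] <- newASPP(cfg, ch[i])
  }
  final <- list(w = matrix(rnorm(ch[1] * cfg@nClasses, 0, sqrt(2 / ch[1])),
                           ch[1], cfg@nClasses),
                b = rep(0, cfg@nClasses))
  structure(list(cfg = cfg, layers = list(enc = enc, dec = dec, aspp = aspp,
                                          final = final)),
            class = "CCRDNetModel")
}

#' @export
print.CCRDNetModel <- function(x, ...) {
  cat(sprintf("CCRDNetModel: %s trainable parameters\n",
              format(countParameters(x), big.mark = ",")))
  print(x$cfg)
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

blockFw <- function(blk, x, training) {
  if (blk$type == "std") {
    h <- .conv3x3_fw(x, blk$w, 1L, FALSE)
    bn <- bnFw(h, blk$bn$gamma, blk$bn$beta, blk$bn$rm, blk$bn$rv, training)
    list(y = geluFw(bn$y), cache = list(x = x, bn = bn, preact = bn$y))
  } else if (blk$type == "dsc") {
    h <- .conv3x3_fw(x, blk$wd, 1L, TRUE)
    g1 <- geluFw(h)
    p <- .conv1x1_fw(g1, blk$wp, NULL)
    bn <- bnFw(p, blk$bn$gamma, blk$bn$beta, blk$bn$rm, blk$bn$rv, training)
    list(y = geluFw(bn$y),
         cache = list(x = x, h = h, g1 = g1, bn = bn, preact = bn$y))
  } else stop("unknown block type")
}

blockBw <- function(blk, cache, gy) {
  g <- geluBw(cache$preact, gy)
  bnb <- bnBw(cache$bn, blk$bn$gamma, g)
  grads <- list(bn = list(gamma = bnb$ggamma, beta = bnb$gbeta))
  if (blk$type == "std") {
    cb <- .conv3x3_bw(cache$x, blk$w, bnb$gx, 1L, FALSE)
    grads$w <- cb$gw
    list(gx = cb$gx, grads = grads)
  } else {
    pb <- .conv1x1_bw(cache$g1, blk$wp, bnb$gx, FALSE)
    grads$wp <- pb$gw
    gh <- geluBw(cache$h, pb$gx)
    db <- .conv3x3_bw(cache$x, blk$wd, gh, 1L, TRUE)
    grads$wd <- db$gw
    list(gx = db$gx, grads = grads)
  }
}

levelFw <- function(blocks, x, training) {
  caches <- vector("list", length(blocks))
  for (j in seq_along(blocks)) {
    r <- blockFw(blocks[[j]], x, training)
    x <- r$y; caches[[j]] <- r$cache
  }
  list(y = x, caches = caches)
}

levelBw <- function(blocks, caches, gy) {
  grads <- vector("list", length(blocks))
  for (j in rev(seq_along(blocks))) {
    r <- blockBw(blocks[[j]], caches[[j]], gy)
    gy <- r$gx; grads[[j]] <- r$grads
  }
  list(gx = gy, grads = grads)
}

asppFw <- function(blk, x, rates, training) {
  d <- dim(x); ch <- d[3]
  branches <- vector("list", 4)
  for (i in 1:4) {
    h <- .conv3x3_fw(x, blk$wd[[i]], as.integer(rates[i]), TRUE)
    if (!is.null(blk$bd)) h <- h + rep(blk$bd[[i]], each = d[1] * d[2])
    branches[[i]] <- h
  }
  cat4 <- array(0, c(d[1], d[2], 4 * ch, d[4]))
  for (i in 1:4) cat4[, , ((i - 1) * ch + 1):(i * ch), ] <- branches[[i]]
  p <- .conv1x1_fw(cat4, blk$wp, if (is.null(blk$bp)) NULL else blk$bp)
  cache <- list(x = x, cat4 = cat4, p = p)
  if (!is.null(blk$bn)) {
    bn <- bnFw(p, blk$bn$gamma, blk$bn$beta, blk$bn$rm, blk$bn$rv, training)
    cache$bn <- bn; cache$preact <- bn$y
    list(y = geluFw(bn$y), cache = cache)
  } else {
    cache$preact <- p
    list(y = geluFw(p), cache = cache)
  }
}

asppBw <- function(blk, cache, rates, gy) {
  g <- geluBw(cache$preact, gy)
  grads <- list()
  if (!is.null(blk$bn)) {
    bnb <- bnBw(cache$bn, blk$bn$gamma, g)
    grads$bn <- list(gamma = bnb$ggamma, beta = bnb$gbeta)
    g <- bnb$gx
  }
  pb <- .conv1x1_bw(cache$cat4, blk$wp, g, !is.null(blk$bp))
  grads$wp <- pb$gw
  if (!is.null(blk$bp)) grads$bp <- pb$gb
  d <- dim(cache$x); ch <- d[3]
  gx <- array(0, d)
  grads$wd <- vector("list", 4)
  if (!is.null(blk$bd)) grads$bd <- vector("list", 4)
  for (i in 1:4) {
    gb <- pb$gx[, , ((i - 1) * ch + 1):(i * ch), , drop = FALSE]
    dim(gb) <- c(d[1], d[2], ch, d[4])
    if (!is.null(blk$bd))
      grads$bd[[i]] <- colSums(matrix(aperm(gb, c(1, 2, 4, 3)), ncol = ch))
    db <- .conv3x3_bw(cache$x, blk$wd[[i]], gb, as.integer(rates[i]), TRUE)
    grads$wd[[i]] <- db$gw
    gx <- gx + db$gx
  }
  list(gx = gx, grads = grads)
}

concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , 1:da[3], ] <- a
  out[, , (da[3] + 1):(da[3] + db[3]), ] <- b
  out
}

#' Network forward pass
#'
#' @param model a built `CCRDNetModel`.
#' @param x input array `(H, W, 3, N)` with values in `[0, 1]`; H and W must
#'   be divisible by `2^(levels - 1)`.
#' @param training logical; training mode uses batch statistics in the
#'   normalization layers and caches intermediates for [modelBackward()].
#' @return list with `logits` `(H, W, nClasses, N)` and (when training)
#'   `cache`.
#' @export
modelForward <- function(model, x, training = FALSE) {
  cfg <- model$cfg; L <- length(cfg@channels)
  if (any(dim(x)[1:2] %% 2^(L - 1) != 0))
    stop(sprintf("input size must be divisible by %d", 2^(L - 1)))
  skips <- vector("list", L - 1)
  encC <- vector("list", L); poolC <- vector("list", L - 1)
  h <- x
  for (i in 1:(L - 1)) {
    r <- levelFw(model$layers$enc[[i]], h, training)
    skips[[i]] <- r$y; encC[[i]] <- r$caches
    p <- maxpoolFw(r$y)
    h <- p$y; poolC[[i]] <- p
  }
  r <- levelFw(model$layers$enc[[L]], h, training)
  h <- r$y; encC[[L]] <- r$caches
  asppC <- vector("list", L - 1); upC <- vector("list", L - 1)
  decC <- vector("list", L - 1); skipUsed <- vector("list", L - 1)
  for (i in (L - 1):1) {
    u <- upsampleFw(h); upC[[i]] <- u
    s <- skips[[i]]
    if (cfg@useASPP && !is.null(model$layers$aspp[[i]])) {
      a <- asppFw(model$layers$aspp[[i]], s, cfg@asppRates, training)
      s <- a$y; asppC[[i]] <- a$cache
    }
    skipUsed[[i]] <- dim(s)[3]
    hcat <- concatC(u$y, s)
    r <- levelFw(model$layers$dec[[i]], hcat, training)
    h <- r$y; decC[[i]] <- r$caches
  }
  logits <- .conv1x1_fw(h, model$layers$final$w, model$layers$final$b)
  list(logits = logits,
       cache = if (training) list(encC = encC, poolC = poolC, upC = upC,
                                  asppC = asppC, decC = decC, head = h,
                                  skipUsed = skipUsed) else NULL)
}

#' Network backward pass
#'
#' @param model a `CCRDNetModel`.
#' @param fw result of `modelForward(..., training = TRUE)`.
#' @param glogits gradient of the loss w.r.t. the logits.
#' @return gradients in the same nested structure as `model$layers`.
#' @export
modelBackward <- function(model, fw, glogits) {
  cfg <- model$cfg; L <- length(cfg@channels)
  cache <- fw$cache
  fb <- .conv1x1_bw(cache$head, model$layers$final$w, glogits, TRUE)
  grads <- list(enc = vector("list", L), dec = vector("list", L - 1),
                aspp = vector("list", L - 1),
                final = list(w = fb$gw, b = fb$gb))
  gy <- fb$gx
  gSkip <- vector("list", L - 1)
  for (i in 1:(L - 1)) {
    r <- levelBw(model$layers$dec[[i]], cache$decC[[i]], gy)
    grads$dec[[i]] <- r$grads
    upCh <- dim(cache$upC[[i]]$y)[3]
    gUp <- r$gx[, , 1:upCh, , drop = FALSE]
    dim(gUp) <- c(dim(r$gx)[1:2], upCh, dim(r$gx)[4])
    gS <- r$gx[, , (upCh + 1):(upCh + cache$skipUsed[[i]]), , drop = FALSE]
    dim(gS) <- c(dim(r$gx)[1:2], cache$skipUsed[[i]], dim(r$gx)[4])
    if (cfg@useASPP && !is.null(model$layers$aspp[[i]])) {
      a <- asppBw(model$layers$aspp[[i]], cache$asppC[[i]], cfg@asppRates, gS)
      grads$aspp[[i]] <- a$grads
      gS <- a$gx
    }
    gSkip[[i]] <- gS
    gy <- upsampleBw(cache$upC[[i]], gUp)   # gradient into the deeper level
  }
  # bottleneck
  r <- levelBw(model$layers$enc[[L]], cache$encC[[L]], gy)
  grads$enc[[L]] <- r$grads
  gy <- r$gx
  for (i in (L - 1):1) {
    g <- maxpoolBw(cache$poolC[[i]], gy) + gSkip[[i]]
    r <- levelBw(model$layers$enc[[i]], cache$encC[[i]], g)
    grads$enc[[i]] <- r$grads
    gy <- r$gx
  }
  grads
}
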