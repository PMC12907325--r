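# Layer primitives for the segmentation network.  Activations are numeric
# arrays in (H, W, C, N) layout; convolutions call the compiled kernels,
# everything else is vectorized R.  Each *Fw returns a list with the output
# and whatever the matching *Bw needs.

geluFw <- function(x) x * stats::pnorm(x)

geluBw <- function(x, gy) gy * (stats::pnorm(x) + x * stats::dnorm(x))

# ---- batch normalization (per channel over H, W, N) ----------------------

bnFw <- function(x, gamma, beta, rm, rv, training, momentum = 0.1,
                 eps = 1e-5) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  M <- matrix(x, nrow = H * W)                     # cols are (c, n) pairs
  colc <- rep(seq_len(C), N)
  if (training) {
    cm <- colMeans(M); cs <- colMeans(M * M)
    mu <- rowMeans(matrix(cm, C, N))
    var <- rowMeans(matrix(cs, C, N)) - mu^2
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * var
  } else {
    mu <- rm; var <- rv
  }
  istd <- 1 / sqrt(var + eps)
  xhat <- (M - rep(mu[colc], each = H * W)) * rep(istd[colc], each = H * W)
  y <- xhat * rep(gamma[colc], each = H * W) + rep(beta[colc], each = H * W)
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd, rm = rm, rv = rv, colc = colc)
}

bnBw <- function(cache, gamma, gy) {
  d <- dim(gy); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- H * W * N
  G <- matrix(gy, nrow = H * W)
  colc <- cache$colc
  gxhat <- G * rep(gamma[colc], each = H * W)
  sum1 <- rowSums(matrix(colSums(gxhat), C, N))                 # per channel
  sum2 <- rowSums(matrix(colSums(gxhat * cache$xhat), C, N))
  gx <- (gxhat - rep(sum1[colc] / m, each = H * W) -
         cache$xhat * rep(sum2[colc] / m, each = H * W)) *
        rep(cache$istd[colc], each = H * W)
  dim(gx) <- d
  ggamma <- rowSums(matrix(colSums(G * cache$xhat), C, N))
  gbeta <- rowSums(matrix(colSums(G), C, N))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# ---- 2x2 max pooling ------------------------------------------------------

maxpoolFw <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  ro <- seq(1, H, 2); re <- seq(2, H, 2); co <- seq(1, W, 2); ce <- seq(2, W, 2)
  a <- x[ro, co, , , drop = FALSE]; b <- x[ro, ce, , , drop = FALSE]
  cc <- x[re, co, , , drop = FALSE]; dd <- x[re, ce, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  # route gradients to the first maximal element in (a, b, c, d) order
  m1 <- a == y; m2 <- (b == y) & !m1; m3 <- (cc == y) & !m1 & !m2
  list(y = y, m1 = m1, m2 = m2, m3 = m3, dims = d)
}

maxpoolBw <- function(cache, gy) {
  d <- cache$dims
  gx <- array(0, d)
  ro <- seq(1, d[1], 2); re <- seq(2, d[1], 2)
  co <- seq(1, d[2], 2); ce <- seq(2, d[2], 2)
  m4 <- !(cache$m1 | cache$m2 | cache$m3)
  gx[ro, co, , ] <- gy * cache$m1
  gx[ro, ce, , ] <- gy * cache$m2
  gx[re, co, , ] <- gy * cache$m3
  gx[re, ce, , ] <- gy * m4
  gx
}

# ---- bilinear interpolation matrices -------------------------------------

# Dense (nOut x nIn) 1-D bilinear interpolation matrix, half-pixel-center
# convention with edge clamping.
interpMatrix <- function(nOut, nIn) {
  s <- ((seq_len(nOut) - 0.5) * nIn / nOut) - 0.5
  s <- clamp(s, 0, nIn - 1)
  i0 <- floor(s); f <- s - i0
  i1 <- pmin(i0 + 1, nIn - 1)
  M <- matrix(0, nOut, nIn)
  M[cbind(seq_len(nOut), i0 + 1)] <- M[cbind(seq_len(nOut), i0 + 1)] + (1 - f)
  M[cbind(seq_len(nOut), i1 + 1)] <- M[cbind(seq_len(nOut), i1 + 1)] + f
  M
}

# Apply row matrix Rr (H' x H) and column matrix Rc (W' x W) to an
# (H, W, C, N) array: separable bilinear resampling.
resampleArray <- function(x, Rr, Rc) {
  d <- dim(x)
  y1 <- Rr %*% matrix(x, d[1], prod(d[-1]))             # rows
  dim(y1) <- c(nrow(Rr), d[2], d[3], d[4])
  y1p <- aperm(y1, c(2, 1, 3, 4))
  y2 <- Rc %*% matrix(y1p, d[2], prod(dim(y1p)[-1]))    # cols
  dim(y2) <- c(nrow(Rc), nrow(Rr), d[3], d[4])
  aperm(y2, c(2, 1, 3, 4))
}

upsampleFw <- function(x) {
  d <- dim(x)
  Rr <- interpMatrix(2 * d[1], d[1]); Rc <- interpMatrix(2 * d[2], d[2])
  list(y = resampleArray(x, Rr, Rc), Rr = Rr, Rc = Rc)
}

upsampleBw <- function(cache, gy) {
  resampleArray(gy, t(cache$Rr), t(cache$Rc))
}

#' Bilinear image resize
#'
#' Anisotropic separable bilinear resampling (aspect ratio not preserved),
#' the resizing used to bring images to the network input resolution.
#'
#' @param image `H x W x 3` array (or `H x W` matrix).
#' @param newH,newW target size.
#' @return resized array/matrix.
#' @export
resizeBilinear <- function(image, newH, newW) {
  mat <- length(dim(image)) < 3L
  x <- if (mat) array(image, c(dim(image), 1, 1)) else
    array(image, c(dim(image)[1:2], dim(image)[3], 1))
  y <- resampleArray(x, interpMatrix(newH, dim(x)[1]),
                     interpMatrix(newW, dim(x)[2]))
  if (mat) y[, , 1, 1] else array(y, c(newH, newW, dim(x)[3]))
}

#' Nearest-neighbor label resize
#'
#' @param label integer matrix.
#' @param newH,newW target size.
#' @return resized integer matrix.
#' @export
resizeNearest <- function(label, newH, newW) {
  H <- nrow(label); W <- ncol(label)
  ri <- pmin(pmax(floor(((seq_len(newH) - 0.5) * H / newH) - 0.5 + 0.5), 0), H - 1) + 1
  ci <- pmin(pmax(floor(((seq_len(newW) - 0.5) * W / newW) - 0.5 + 0.5), 0), W - 1) + 1
  matrix(as.integer(label[ri, ci]), newH, newW)
}

# ---- softmax cross-entropy ------------------------------------------------

# logits: (H, W, K, N); labels: (H, W, N) integer array in 0..K-1.
softmaxCE <- function(logits, labels) {
  d <- dim(logits); K <- d[3]
  lp <- aperm(logits, c(1, 2, 4, 3))
  M <- matrix(lp, ncol = K)                    # rows = pixels, cols = classes
  mx <- do.call(pmax, lapply(seq_len(K), function(k) M[, k]))
  E <- exp(M - mx)
  Z <- rowSums(E)
  P <- E / Z
  lab <- as.integer(labels) + 1L
  n <- nrow(M)
  loss <- -mean(log(P[cbind(seq_len(n), lab)] + 1e-12))
  G <- P
  G[cbind(seq_len(n), lab)] <- G[cbind(seq_len(n), lab)] - 1
  G <- G / n
  dim(G) <- dim(lp)
  list(loss = loss, grad = aperm(G, c(1, 2, 4, 3)))
}
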