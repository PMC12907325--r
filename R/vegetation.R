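#' Excess Green vegetation index
#'
#' Per-pixel `ExG = 2G - R - B`, computed in signed arithmetic; values range
#' over `[-510, 510]` for 8-bit input.  Gray pixels score 0, saturated green
#' scores 510.
#'
#' @param image `H x W x 3` array in 0..255.
#' @return numeric `H x W` matrix.
#' @examples
#' img <- array(c(50, 120, 30), c(1, 1, 3))
#' excessGreen(img)  # 160
#' @export
excessGreen <- function(image) {
  checkImage(image)
  2 * channelMat(image, 2) - channelMat(image, 1) - channelMat(image, 3)
}

#' Otsu threshold of a scalar raster
#'
#' Rescales the raster min-max onto a 256-bin histogram, exhaustively
#' maximizes the between-class variance over all split points (the classic
#' 8-bit formulation), and maps the chosen split back to the original units.
#' When several splits tie (a plateau of empty bins between well-separated
#' modes) the plateau midpoint is used, placing the threshold centrally in
#' the inter-mode gap.
#'
#' @param values numeric vector or matrix with at least two distinct values.
#' @return scalar threshold in the units of `values`; binarize as
#'   `values > threshold`.
#' @export
otsuThreshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) stop("constant raster: no threshold exists")
  bins <- pmin(255L, as.integer(floor((v - rng[1]) / diff(rng) * 256)))
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                       # class-0 mass for split after bin t
  mu <- cumsum(p * (0:255))
  muT <- mu[256]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  sb <- sb[1:255]
  # empty bins between well-separated modes leave a plateau of equally
  # optimal splits; take its midpoint (ties within numerical tolerance)
  top <- which(sb >= max(sb) * (1 - 1e-12))
  t <- top[ceiling(length(top) / 2)] - 1L   # split: bins <= t vs > t
  rng[1] + (t + 0.5) / 255 * diff(rng)
}

#' Vegetation mask from the Excess Green index
#'
#' Vegetation is the high-ExG side of the Otsu split of the scene's ExG
#' raster.
#'
#' @param image `H x W x 3` array in 0..255.
#' @return logical `H x W` mask.
#' @export
binarizeExG <- function(image) {
  exg <- excessGreen(image)
  exg > otsuThreshold(exg)
}

#' CIE Lab a-channel of an RGB image
#'
#' sRGB transfer, D65 white point.  Green vegetation has low (negative) a;
#' soils and red mulch have high a.
#'
#' @param image `H x W x 3` array in 0..255.
#' @return numeric `H x W` matrix of a-channel values.
#' @export
rgbToLabA <- function(image) {
  checkImage(image)
  m <- cbind(as.numeric(image[, , 1]), as.numeric(image[, , 2]),
             as.numeric(image[, , 3])) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  matrix(lab[, 2], nrow(image), ncol(image))
}

#' Vegetation mask from the Lab a-channel
#'
#' Vegetation is the low-a side of the Otsu split of the a-channel (green is
#' the negative direction of the green-red opponent axis).
#'
#' @param image `H x W x 3` array in 0..255.
#' @return logical `H x W` mask.
#' @export
binarizeLabA <- function(image) {
  a <- rgbToLabA(image)
  a < otsuThreshold(a)
}

#' Select a vegetation binarization
#'
#' The Lab-a index is generally the more robust of the two, but it can fail
#' on unusual backgrounds; the ExG index then serves as the fallback.  The
#' `"auto"` policy accepts the Lab-a mask when its vegetation fraction lies
#' in `[0.02, 0.80]` (a plausible cover range for field imagery) and falls
#' back to ExG otherwise.  If the ExG fraction is also implausible the Lab-a
#' mask is returned with attribute `fallbackWarning = TRUE`.
#'
#' @param image `H x W x 3` array in 0..255.
#' @param policy `"auto"`, `"lab_a"` or `"exg"`.
#' @param fractionRange acceptable vegetation-cover range for `"auto"`.
#' @return logical mask with attributes `method` (index used) and
#'   `fallbackWarning`.
#' @export
selectBinary <- function(image, policy = c("auto", "lab_a", "exg"),
                         fractionRange = c(0.02, 0.80)) {
  policy <- match.arg(policy)
  tagged <- function(mask, method, warn = FALSE) {
    attr(mask, "method") <- method
    attr(mask, "fallbackWarning") <- warn
    mask
  }
  if (policy == "lab_a") return(tagged(binarizeLabA(image), "lab_a"))
  if (policy == "exg")   return(tagged(binarizeExG(image), "exg"))
  lab <- binarizeLabA(image)
  fLab <- mean(lab)
  if (fLab >= fractionRange[1] && fLab <= fractionRange[2])
    return(tagged(lab, "lab_a"))
  exg <- binarizeExG(image)
  fExg <- mean(exg)
  if (fExg >= fractionRange[1] && fExg <= fractionRange[2])
    return(tagged(exg, "exg"))
  warning("both vegetation indices produced implausible cover; returning Lab-a")
  tagged(lab, "lab_a", warn = TRUE)
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask logical matrix.
#' @param path file path.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}
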