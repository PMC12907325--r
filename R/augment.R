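#' Augmentation configuration
#'
#' Symmetric rotation bound and maximal lateral crop.  The defaults (40
#' degrees, 60 px) cover the plausible range of camera tilt and steering
#' offset during in-row driving; larger transforms would correspond to
#' deviations a vehicle would not encounter in normal operation.
#'
#' @param rotationRangeDeg symmetric rotation bound in degrees (>= 0).
#' @param lateralShiftMaxPx maximal columns cropped from one side (>= 0).
#' @param seed optional integer seed for [randomAugment()].
#' @return a list of class `AugmentConfig`.
#' @export
augmentConfig <- function(rotationRangeDeg = 40, lateralShiftMaxPx = 60,
                          seed = NULL) {
  if (rotationRangeDeg < 0 || lateralShiftMaxPx < 0)
    stop("augmentation bounds must be >= 0")
  structure(list(rotationRangeDeg = rotationRangeDeg,
                 lateralShiftMaxPx = lateralShiftMaxPx, seed = seed),
            class = "AugmentConfig")
}

# Inverse-mapped rotation about the pixel-grid center ((W-1)/2, (H-1)/2).
# interp = "bilinear" for images (border filled with `fill` per channel),
# "nearest" for labels (border fill 0).
warpRotate <- function(x, angleDeg, interp = c("bilinear", "nearest"),
                       fill = 0) {
  interp <- match.arg(interp)
  isImg <- length(dim(x)) == 3L
  H <- dim(x)[1]; W <- dim(x)[2]
  a <- angleDeg * pi / 180
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  X <- matrix(0:(W - 1), H, W, byrow = TRUE) - cx
  Y <- matrix(0:(H - 1), H, W) - cy
  sx <- cos(a) * X + sin(a) * Y + cx
  sy <- -sin(a) * X + cos(a) * Y + cy
  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix <= W - 1 & iy >= 0 & iy <= H - 1
    ix[!ok] <- 0; iy[!ok] <- 0
    out <- matrix(x[cbind(as.vector(iy) + 1, as.vector(ix) + 1)], H, W)
    out[!ok] <- 0L
    return(matrix(as.integer(out), H, W))
  }
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  fill <- rep(fill, length.out = 3)
  sample1 <- function(sl, yy, xx) {
    ok <- xx >= 0 & xx <= W - 1 & yy >= 0 & yy <= H - 1
    xs <- pmin(pmax(xx, 0), W - 1); ys <- pmin(pmax(yy, 0), H - 1)
    v <- matrix(sl[cbind(as.vector(ys) + 1, as.vector(xs) + 1)], H, W)
    list(v = v, ok = ok)
  }
  out <- array(0, dim(x))
  for (ch in seq_len(dim(x)[3])) {
    sl <- x[, , ch]
    p00 <- sample1(sl, y0, x0);     p01 <- sample1(sl, y0, x0 + 1)
    p10 <- sample1(sl, y0 + 1, x0); p11 <- sample1(sl, y0 + 1, x0 + 1)
    v <- (1 - fy) * ((1 - fx) * p00$v + fx * p01$v) +
         fy * ((1 - fx) * p10$v + fx * p11$v)
    outside <- !(p00$ok | p01$ok | p10$ok | p11$ok)
    # partial coverage at the border: blend with fill by replacing
    # out-of-frame taps with the fill value
    vfill <- (1 - fy) * ((1 - fx) * ifelse(p00$ok, p00$v, fill[ch]) +
                         fx * ifelse(p01$ok, p01$v, fill[ch])) +
             fy * ((1 - fx) * ifelse(p10$ok, p10$v, fill[ch]) +
                   fx * ifelse(p11$ok, p11$v, fill[ch]))
    vfill[outside] <- fill[ch]
    out[, , ch] <- vfill
  }
  out
}

#' Rotate a navigation line about the image center
#'
#' Applies the same rigid rotation as the image warp, analytically: two
#' points on the line are rotated and the line re-derived through them (no
#' pixel refit).
#'
#' @param line a [NavLine-class] (`xOnY` convention).
#' @param angleDeg rotation in degrees (positive rotates the +y axis toward
#'   +x on screen).
#' @param dim image size `c(H, W)` defining the rotation center.
#' @return rotated [NavLine-class].
#' @export
rotateLine <- function(line, angleDeg, dim) {
  stopifnot(line@axis == "xOnY")
  H <- dim[1]; W <- dim[2]
  a <- angleDeg * pi / 180
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  rot <- function(p) {
    d <- p - c(cx, cy)
    c(cos(a) * d[1] - sin(a) * d[2] + cx,
      sin(a) * d[1] + cos(a) * d[2] + cy)
  }
  p1 <- rot(c(line@b, 0))
  p2 <- rot(c(line@theta * (H - 1) + line@b, H - 1))
  dy <- p2[2] - p1[2]
  if (abs(dy) < 1e-9) stop("rotated line is horizontal; cannot represent as x = theta*y + b")
  theta <- (p2[1] - p1[1]) / dy
  navLine(theta = theta, b = p1[1] - theta * p1[2], axis = "xOnY")
}

#' Rotate an (image, label, line) triple consistently
#'
#' The image is rotated with bilinear interpolation (border filled with
#' `fill`, by default the image mean color so the border carries no fake
#' background cue), the label with nearest neighbor, and the line
#' analytically.  The row-band class is then re-rasterized from the rotated
#' line so its width stays exactly 15 px; rotated band pixels not covered by
#' the fresh band (a 1-px boundary effect) fall back to the vegetation
#' class.
#'
#' @param image `H x W x 3` array.
#' @param label integer label matrix.
#' @param line [NavLine-class].
#' @param angleDeg rotation angle in degrees.
#' @param fill border fill color (length 3); default = channel means.
#' @param widthPx band width for re-rasterization.
#' @return list with elements `image`, `label`, `line`.
#' @export
rotateTriple <- function(image, label, line, angleDeg, fill = NULL,
                         widthPx = 15L) {
  if (is.null(fill)) fill <- apply(image, 3, mean)
  if (angleDeg == 0)
    return(list(image = image, label = label, line = line))
  img <- warpRotate(image, angleDeg, "bilinear", fill)
  lab <- warpRotate(label, angleDeg, "nearest")
  newLine <- rotateLine(line, angleDeg, dim(label))
  band <- rasterizeLine(newLine, dim(label), widthPx)
  lab[lab == 2L] <- 1L
  lab[band] <- 2L
  list(image = img, label = lab, line = newLine)
}

#' Crop columns from one side of an (image, label, line) triple
#'
#' Emulates a lateral steering offset: `shiftPx` columns are removed from
#' the chosen side and the line translated accordingly (left crop:
#' `x <- x - shiftPx`).  The sample is rejected (error) if the central-row
#' band no longer intersects the cropped frame.
#'
#' @param image,label,line the triple.
#' @param shiftPx non-negative number of columns to remove (must be smaller
#'   than the image width).
#' @param side `"left"` or `"right"`.
#' @param widthPx band width used for the in-frame check.
#' @return list with elements `image`, `label`, `line`.
#' @export
lateralCropTriple <- function(image, label, line, shiftPx,
                              side = c("left", "right"), widthPx = 15L) {
  side <- match.arg(side)
  shiftPx <- as.integer(shiftPx)
  W <- ncol(label)
  if (shiftPx < 0 || shiftPx >= W) stop("shiftPx must be in [0, width)")
  if (shiftPx == 0)
    return(list(image = image, label = label, line = line))
  keep <- if (side == "left") (shiftPx + 1L):W else 1L:(W - shiftPx)
  img <- image[, keep, , drop = FALSE]
  lab <- label[, keep, drop = FALSE]
  newLine <- if (side == "left")
    navLine(line@theta, line@b - shiftPx, axis = "xOnY") else line
  if (!any(rasterizeLine(newLine, dim(lab), widthPx)))
    stop("central row cropped out of frame; sample rejected")
  list(image = img, label = lab, line = newLine)
}

#' Random rotation + lateral crop
#'
#' Draws a uniform angle in `[-rotationRangeDeg, rotationRangeDeg]`, a
#' uniform integer shift in `[0, lateralShiftMaxPx]` and a random side, and
#' applies rotation followed by cropping.  With a seeded configuration the
#' draw is reproducible; rejected samples (central row cropped out)
#' propagate as errors.
#'
#' @param image,label,line the triple.
#' @param cfg an [augmentConfig()].
#' @return list with `image`, `label`, `line` and a `params` data.frame
#'   recording the applied angle, shift and side.
#' @export
randomAugment <- function(image, label, line, cfg = augmentConfig()) {
  draw <- function() {
    list(angle = runif(1, -cfg$rotationRangeDeg, cfg$rotationRangeDeg),
         shift = sample.int(cfg$lateralShiftMaxPx + 1L, 1L) - 1L,
         side = c("left", "right")[sample.int(2L, 1L)])
  }
  p <- if (is.null(cfg$seed)) draw() else withLocalSeed(cfg$seed, draw())
  out <- rotateTriple(image, label, line, p$angle)
  out <- lateralCropTriple(out$image, out$label, out$line, p$shift, p$side)
  out$params <- data.frame(angle_deg = p$angle, shift_px = p$shift,
                           side = p$side)
  out
}
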