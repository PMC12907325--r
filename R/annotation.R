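#' Navigation line through the image edge midpoints
#'
#' Annotation convention: the central row is marked by the midpoint of the
#' row at the top image edge and the midpoint at the bottom edge; the
#' navigation line is the straight line through the two.
#'
#' @param topX x-coordinate (0-based pixel units) where the line crosses
#'   `y = 0`.
#' @param bottomX x-coordinate where the line crosses `y = height - 1`.
#' @param height image height in pixels (>= 2).
#' @return a [NavLine-class] in the `xOnY` convention.
#' @examples
#' lineFromEdgeMidpoints(120, 136, 480)  # slope 16/479
#' @export
lineFromEdgeMidpoints <- function(topX, bottomX, height) {
  stopifnotScalar(topX, "topX"); stopifnotScalar(bottomX, "bottomX")
  if (height < 2) stop("height must be >= 2")
  navLine(theta = (bottomX - topX) / (height - 1), b = topX, axis = "xOnY")
}

#' Perpendicular distance from pixel centers to a line
#'
#' @param line a [NavLine-class].
#' @param x,y numeric vectors/matrices of 0-based pixel coordinates.
#' @return distances, same shape as `x`.
#' @export
linePerpDistance <- function(line, x, y) {
  th <- line@theta
  if (line@axis == "xOnY") abs(x - th * y - line@b) / sqrt(1 + th^2)
  else                     abs(y - th * x - line@b) / sqrt(1 + th^2)
}

#' Rasterize a line as a fixed-width band
#'
#' A pixel `(x, y)` belongs to the band iff the perpendicular distance from
#' its center to the infinite line is at most `widthPx / 2`.  The
#' perpendicular-distance construction keeps the band width constant for
#' slanted lines, so a rotated annotation keeps exactly the same physical
#' width.
#'
#' @param line a [NavLine-class].
#' @param dim image size `c(H, W)`.
#' @param widthPx odd positive band width in pixels (default 15, the fixed
#'   annotation width used for every navigation-line label).
#' @return logical `H x W` matrix.
#' @export
rasterizeLine <- function(line, dim, widthPx = 15L) {
  if (widthPx <= 0 || widthPx %% 2 == 0)
    stop("widthPx must be odd and positive")
  H <- as.integer(dim[1]); W <- as.integer(dim[2])
  y <- matrix(0:(H - 1), H, W)
  x <- matrix(0:(W - 1), H, W, byrow = TRUE)
  linePerpDistance(line, x, y) <= widthPx / 2
}

#' Compose a semantic label mask
#'
#' Builds the pixel-wise ground truth from a vegetation mask and the
#' rasterized navigation-line band.  In the three-class scheme the classes
#' are 0 = background, 1 = vegetation, 2 = central crop row; the row band
#' overrides vegetation wherever the two overlap.  The two-class ablation
#' drops the vegetation class entirely (1 = central row, 0 = everything
#' else).
#'
#' @param veg logical vegetation mask.
#' @param lineMask logical navigation-line band (same shape).
#' @param nClasses 2 or 3.
#' @return integer label matrix.
#' @export
composeLabels <- function(veg, lineMask, nClasses = 3L) {
  if (!all(dim(veg) == dim(lineMask))) stop("shape mismatch")
  if (!nClasses %in% c(2L, 3L)) stop("nClasses must be 2 or 3")
  lab <- matrix(0L, nrow(veg), ncol(veg))
  if (nClasses == 3L) {
    lab[veg] <- 1L
    lab[lineMask] <- 2L
  } else {
    lab[lineMask] <- 1L
  }
  lab
}

#' Read / write label masks as grayscale PNG
#'
#' Labels are stored as single-channel 8-bit PNGs holding the literal class
#' index per pixel (0, 1, 2).  The encoding is lossless: a round trip
#' reproduces the in-memory label exactly.  [labelToRGB()] maps classes to
#' display colors (black / green / red).
#'
#' @param label integer label matrix.
#' @param path file path.
#' @return `readLabelPNG` returns an integer matrix; `writeLabelPNG` returns
#'   `path` invisibly.
#' @export
writeLabelPNG <- function(label, path) {
  png::writePNG(label / 255, target = path)
  invisible(path)
}

#' @rdname writeLabelPNG
#' @export
readLabelPNG <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
}

#' @rdname writeLabelPNG
#' @param palette class colors as an `n x 3` matrix in 0..255 (rows =
#'   classes, starting at class 0).
#' @export
labelToRGB <- function(label,
                       palette = rbind(c(0, 0, 0), c(0, 200, 0), c(220, 30, 30))) {
  out <- array(0, c(nrow(label), ncol(label), 3))
  for (k in seq_len(nrow(palette)))
    for (ch in 1:3)
      out[, , ch][label == (k - 1L)] <- palette[k, ch]
  out
}

#' Read / write RGB images as PNG
#'
#' Thin wrappers around the png package keeping the package-wide convention
#' of `H x W x 3` arrays with values in 0..255.
#' @param image `H x W x 3` array, 0..255.
#' @param path file path.
#' @export
writeImagePNG <- function(image, path) {
  checkImage(image)
  png::writePNG(clamp(image, 0, 255) / 255, target = path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2L) v <- array(rep(v, 3), c(dim(v), 3))
  v[, , 1:3, drop = FALSE] * 255
}
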