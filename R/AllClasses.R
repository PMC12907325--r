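#' Navigation line parameters
#'
#' A straight line in image coordinates.  Pixel centers sit at integer
#' positions, `x` grows rightward, `y` grows downward, both 0-based.  With
#' `axis = "xOnY"` (the default throughout the package) the line is
#' `x = theta * y + b`: this regresses the horizontal position on the row
#' index, which stays well conditioned for the near-vertical crop rows that
#' dominate guidance imagery.  `axis = "yOnX"` stores the textbook
#' `y = theta * x + b` form.  `angleDeg` is the line orientation in degrees in
#' `[0, 180)`, measured from the +x image axis; a vertical line has
#' `angleDeg = 90`.
#'
#' @slot theta numeric slope.
#' @slot b numeric intercept.
#' @slot axis `"xOnY"` or `"yOnX"`.
#' @slot angleDeg orientation in degrees, `[0, 180)`.
#' @export
setClass("NavLine",
  representation(theta = "numeric", b = "numeric", axis = "character",
                 angleDeg = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@axis %in% c("xOnY", "yOnX"))
      msg <- c(msg, "axis must be 'xOnY' or 'yOnX'")
    if (!is.finite(object@theta) || !is.finite(object@b))
      msg <- c(msg, "theta and b must be finite")
    if (length(msg) == 0L) {
      expected <- lineOrientation(object@theta, object@axis)
      d <- abs(object@angleDeg - expected) %% 180
      if (min(d, 180 - d) > 1e-6)
        msg <- c(msg, "angleDeg inconsistent with (theta, axis)")
    }
    if (length(msg)) msg else TRUE
  })

# Orientation in [0, 180) of a line with the given slope/axis convention.
lineOrientation <- function(theta, axis) {
  ang <- if (axis == "xOnY") atan2(1, theta) else atan2(theta, 1)
  (ang * 180 / pi) %% 180
}

#' Construct a navigation line
#'
#' @param theta slope (see [NavLine-class] for the axis convention).
#' @param b intercept.
#' @param axis `"xOnY"` (default, `x = theta*y + b`) or `"yOnX"`.
#' @return a [NavLine-class] object.
#' @examples
#' navLine(0, 128)              # vertical line through column 128
#' @export
navLine <- function(theta, b, axis = c("xOnY", "yOnX")) {
  axis <- match.arg(axis)
  stopifnotScalar(theta, "theta"); stopifnotScalar(b, "b")
  new("NavLine", theta = theta, b = b, axis = axis,
      angleDeg = lineOrientation(theta, axis))
}

#' @describeIn navLine slope accessor.
#' @param line a [NavLine-class].
#' @export
lineTheta <- function(line) line@theta

#' @describeIn navLine intercept accessor.
#' @export
lineIntercept <- function(line) line@b

#' @describeIn navLine orientation in degrees, `[0, 180)`.
#' @export
lineAngle <- function(line) line@angleDeg

#' @describeIn navLine axis convention accessor.
#' @export
lineAxis <- function(line) line@axis

setMethod("show", "NavLine", function(object) {
  cat(sprintf("NavLine: %s  theta = %.6g, b = %.6g, angle = %.3f deg\n",
              if (object@axis == "xOnY") "x = theta*y + b" else "y = theta*x + b",
              object@theta, object@b, object@angleDeg))
})

#' Generative parameters of a synthetic crop-field scene
#'
#' Describes one synthetic field image: parallel plant rows with an
#' always-present central row (hence `nRows` must be odd), quasi-circular
#' green plants at regular spacing along each row, off-row weeds, a textured
#' soil or mulch background, an optional multiplicative illumination ramp and
#' half-plane shadow.  All distances are in pixels of the rendered image.
#' Identical specs (including `seed`) render bit-identical scenes.
#'
#' @slot widthPx,heightPx image size in pixels.
#' @slot nRows odd number of rows (>= 1).
#' @slot rowSpacingPx lateral distance between adjacent row centerlines.
#' @slot centralOffsetPx signed lateral shift of the central row from the
#'   image center column at mid-height.
#' @slot rowAngleDeg row tilt from vertical, degrees (0 = vertical).
#' @slot plantSpacingPx distance between consecutive plants along a row.
#' @slot plantRadiusPx nominal plant disc radius.
#' @slot plantRadiusJitter fractional radius jitter in `[0, 1)`.
#' @slot missingPlantProb probability a plant position stays empty.
#' @slot weedDensity expected weeds per kilo-pixel of image area.
#' @slot weedRadiusPx nominal weed disc radius.
#' @slot soilRGB background color, length-3 in 0..255.
#' @slot plantHueJitter fractional per-plant greenness jitter.
#' @slot illuminationGradient multiplicative brightness ramp amplitude
#'   (0 = flat lighting).
#' @slot shadow add a half-plane brightness reduction (e.g. an operator's
#'   shadow).
#' @slot seed integer RNG seed.
#' @export
setClass("SceneSpec",
  representation(widthPx = "integer", heightPx = "integer", nRows = "integer",
                 rowSpacingPx = "numeric", centralOffsetPx = "numeric",
                 rowAngleDeg = "numeric", plantSpacingPx = "numeric",
                 plantRadiusPx = "numeric", plantRadiusJitter = "numeric",
                 missingPlantProb = "numeric", weedDensity = "numeric",
                 weedRadiusPx = "numeric", soilRGB = "numeric",
                 plantHueJitter = "numeric", illuminationGradient = "numeric",
                 shadow = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@widthPx < 16L || object@heightPx < 16L)
      msg <- c(msg, "image must be at least 16 x 16")
    if (object@nRows < 1L || object@nRows %% 2L == 0L)
      msg <- c(msg, "nRows must be an odd integer >= 1")
    for (s in c("rowSpacingPx", "plantSpacingPx", "plantRadiusPx", "weedRadiusPx"))
      if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
    for (s in c("missingPlantProb", "plantRadiusJitter", "plantHueJitter"))
      if (slot(object, s) < 0 || slot(object, s) > 1)
        msg <- c(msg, paste(s, "must be in [0, 1]"))
    if (object@weedDensity < 0) msg <- c(msg, "weedDensity must be >= 0")
    if (length(object@soilRGB) != 3L || any(object@soilRGB < 0 | object@soilRGB > 255))
      msg <- c(msg, "soilRGB must be 3 values in 0..255")
    if (object@illuminationGradient < 0 || object@illuminationGradient > 1)
      msg <- c(msg, "illuminationGradient must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Create a synthetic scene specification
#'
#' Defaults render a 256 x 256 scene with five straight rows spaced about a
#' fifth of the image width apart, 9-px plants every 22 px, light weed
#' clutter and a mild illumination ramp -- a plausible mid-season row-crop
#' scene at the network's working resolution.
#'
#' @param widthPx,heightPx image size in pixels.
#' @param nRows odd number of rows.
#' @param rowSpacingPx distance between adjacent row centerlines.
#' @param centralOffsetPx lateral shift of the central row at mid-height.
#' @param rowAngleDeg row tilt from vertical (degrees).
#' @param plantSpacingPx along-row plant spacing.
#' @param plantRadiusPx plant disc radius.
#' @param plantRadiusJitter fractional radius jitter.
#' @param missingPlantProb probability of a missing plant.
#' @param weedDensity weeds per kilo-pixel.
#' @param weedRadiusPx weed disc radius.
#' @param soilRGB background color (length 3, 0..255).
#' @param plantHueJitter per-plant greenness jitter fraction.
#' @param illuminationGradient multiplicative ramp amplitude.
#' @param shadow logical, add a half-plane shadow.
#' @param seed integer RNG seed.
#' @return a [SceneSpec-class] object.
#' @export
sceneSpec <- function(widthPx = 256L, heightPx = 256L, nRows = 5L,
                      rowSpacingPx = 52, centralOffsetPx = 0, rowAngleDeg = 0,
                      plantSpacingPx = 22, plantRadiusPx = 9,
                      plantRadiusJitter = 0.25, missingPlantProb = 0.05,
                      weedDensity = 0.4, weedRadiusPx = 4,
                      soilRGB = c(120, 85, 60), plantHueJitter = 0.15,
                      illuminationGradient = 0.25, shadow = FALSE, seed = 1L) {
  new("SceneSpec", widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      nRows = as.integer(nRows), rowSpacingPx = rowSpacingPx,
      centralOffsetPx = centralOffsetPx, rowAngleDeg = rowAngleDeg,
      plantSpacingPx = plantSpacingPx, plantRadiusPx = plantRadiusPx,
      plantRadiusJitter = plantRadiusJitter, missingPlantProb = missingPlantProb,
      weedDensity = weedDensity, weedRadiusPx = weedRadiusPx,
      soilRGB = as.numeric(soilRGB), plantHueJitter = plantHueJitter,
      illuminationGradient = illuminationGradient, shadow = shadow,
      seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(paste0("SceneSpec: %d x %d, %d rows (spacing %.1f px, angle %.1f deg, ",
                     "offset %.1f px), seed %d\n"),
              object@widthPx, object@heightPx, object@nRows, object@rowSpacingPx,
              object@rowAngleDeg, object@centralOffsetPx, object@seed))
})
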