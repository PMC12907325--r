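#' Largest connected component of a binary mask
#'
#' Keeps only the component with the most pixels.  Ties go to the component
#' whose lexicographically smallest `(y, x)` pixel comes first.  An empty
#' mask is returned unchanged.  Component analysis is the only screening
#' applied before line fitting: least squares is sensitive to outliers, and
#' restricting the fit to the dominant predicted region suppresses spurious
#' or fragmented detections without any tuned parameters.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8: diagonal pixel runs in slanted
#'   bands stay connected).
#' @return logical matrix containing only the largest component.
#' @export
largestComponent <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (!any(mask)) return(mask)
  lab <- .cc_label(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)      # first maximum = earliest component in scan
  lab == keep
}

#' Least-squares line fit to a pixel set
#'
#' Fits `theta` and `b` by ordinary least squares on the pixel-center
#' coordinates.  With `axis = "xOnY"` (the default) the horizontal position
#' is regressed on the row index, `x = theta*y + b`:
#' `theta = (sum(x*y) - n*xbar*ybar) / (sum(y^2) - n*ybar^2)`,
#' `b = xbar - theta*ybar`.  This stays well conditioned for the
#' near-vertical rows of guidance imagery, where the textbook `y`-on-`x`
#' regression (`axis = "yOnX"`, same formulas with x and y exchanged)
#' degenerates.
#'
#' @param points 2-column matrix of 0-based `(x, y)` pixel coordinates.
#' @param axis regression axis, `"xOnY"` (default) or `"yOnX"`.
#' @return a [NavLine-class].
#' @export
fitLineLsq <- function(points, axis = c("xOnY", "yOnX")) {
  axis <- match.arg(axis)
  if (!is.matrix(points) || ncol(points) != 2L || nrow(points) < 2L)
    stop("points must be an n x 2 matrix with n >= 2")
  x <- points[, 1]; y <- points[, 2]
  if (axis == "xOnY") { u <- y; v <- x } else { u <- x; v <- y }
  n <- length(u)
  denom <- sum(u^2) - n * mean(u)^2
  if (denom <= 1e-9 * max(1, n)) stop("degenerate point set")
  theta <- (sum(u * v) - n * mean(u) * mean(v)) / denom
  navLine(theta = theta, b = mean(v) - theta * mean(u), axis = axis)
}

#' Extract the navigation line from a label mask
#'
#' Selects the pixels of the row class, keeps the largest connected
#' component and fits the navigation line by least squares on the component
#' pixel centers.  Frames without a detection (empty or degenerate row
#' class) return `NULL` rather than raising.
#'
#' @param label integer label matrix.
#' @param lineClass class index of the row band (2 in the three-class
#'   scheme, 1 in the two-class ablation).
#' @param connectivity component connectivity (default 8).
#' @return a [NavLine-class], or `NULL` when no line can be fitted.
#' @export
extractNavLine <- function(label, lineClass = 2L, connectivity = 8L) {
  mask <- label == lineClass
  if (!any(mask)) return(NULL)
  comp <- largestComponent(mask, connectivity)
  idx <- which(comp, arr.ind = TRUE)
  points <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  tryCatch(fitLineLsq(points, axis = "xOnY"), error = function(e) NULL)
}

#' Acute angle between two lines
#'
#' Orientation difference modulo 180 degrees, folded into `[0, 90]`.
#'
#' @param pred,gt [NavLine-class] objects.
#' @return angle error in degrees.
#' @export
angleError <- function(pred, gt) {
  d <- abs(lineAngle(pred) - lineAngle(gt)) %% 180
  min(d, 180 - d)
}

#' Line IoU of two navigation lines
#'
#' Both lines are rasterized as fixed-width bands (15 px by default) on the
#' same canvas and compared with the standard intersection-over-union.  Two
#' parallel vertical bands whose centerlines sit 5 px apart overlap in 10 of
#' their 20 distinct columns, giving 0.5 -- the boundary of the "correct
#' navigation line" criterion.
#'
#' @param pred,gt [NavLine-class] objects.
#' @param dim canvas size `c(H, W)`.
#' @param widthPx band width (default 15).
#' @return IoU in `[0, 1]`.
#' @export
lineIoU <- function(pred, gt, dim, widthPx = 15L) {
  a <- rasterizeLine(pred, dim, widthPx)
  b <- rasterizeLine(gt, dim, widthPx)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Per-image navigation report
#'
#' @param pred predicted [NavLine-class] or `NULL` (missing detection).
#' @param gt ground-truth [NavLine-class].
#' @param dim canvas size `c(H, W)`.
#' @param widthPx band width for the line IoU.
#' @return one-row data.frame with `ae_deg`, `l_iou`, `detected`, `correct`.
#'   A line is correct iff `ae_deg < 5` and `l_iou > 0.5` (strict); missing
#'   detections are incorrect.
#' @export
navReport <- function(pred, gt, dim, widthPx = 15L) {
  if (is.null(pred))
    return(data.frame(ae_deg = NA_real_, l_iou = NA_real_,
                      detected = FALSE, correct = FALSE))
  ae <- angleError(pred, gt)
  li <- lineIoU(pred, gt, dim, widthPx)
  data.frame(ae_deg = ae, l_iou = li, detected = TRUE,
             correct = ae < 5 && li > 0.5)
}

#' Line accuracy over a set of navigation reports
#'
#' Fraction of frames whose fitted line satisfies `AE < 5` degrees and
#' `L_IoU > 0.5`; frames without a detection count as incorrect.
#'
#' @param reports data.frame with a logical `correct` column (rows from
#'   [navReport()]).
#' @return fraction in `[0, 1]`.
#' @export
lineAccuracy <- function(reports) {
  if (nrow(reports) == 0L) stop("empty report list")
  mean(reports$correct %in% TRUE)
}
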