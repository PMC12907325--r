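# Internal helpers shared across modules.

#' Run code with a temporary RNG state
#'
#' Seeds the R RNG, evaluates `expr`, and restores the previous RNG state so
#' that library calls never disturb the caller's random stream.
#' @noRd
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; keeps results < 2^31.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1009 * as.double(k)) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnotScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

# Validate an H x W x 3 numeric image with values in [0, 255].
checkImage <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  invisible(image)
}

imageDim <- function(image) dim(image)[1:2]

# channel k of an H x W x 3 image as a matrix (robust to 1-pixel images)
channelMat <- function(image, k)
  matrix(image[, , k], dim(image)[1], dim(image)[2])
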