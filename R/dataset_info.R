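#' Composition of the public central-crop-row benchmark
#'
#' Per-crop image counts of the published field dataset this package's
#' synthetic scenes emulate (eight crop species collected across diverse
#' environments), together with the size of its training split: 50 images
#' from each of eight environments, i.e. 400 images, with the remainder
#' reserved for zero-shot evaluation.
#'
#' @return data.frame with columns `crop` and `images`, with attributes
#'   `trainingImages` (400) and `trainingEnvironments` (8).
#' @export
datasetInventory <- function() {
  out <- data.frame(
    crop = c("maize", "eggplant", "soybean", "mung bean", "pepper",
             "scallion", "carrot", "tomato"),
    images = c(3324L, 798L, 1575L, 388L, 301L, 400L, 181L, 400L))
  attr(out, "trainingImages") <- 400L
  attr(out, "trainingEnvironments") <- 8L
  out
}
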