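# Small shared fixtures, built in code.

cleanSpec <- function(seed = 1L, ...) {
  args <- list(widthPx = 128L, heightPx = 128L, nRows = 3L, rowSpacingPx = 40,
               plantSpacingPx = 14, plantRadiusPx = 6, weedDensity = 0,
               missingPlantProb = 0, plantRadiusJitter = 0,
               illuminationGradient = 0, seed = seed)
  do.call(sceneSpec, utils::modifyList(args, list(...)))
}

# Tri-color scenes built so the Lab-a Otsu split isolates a small red
# minority (vegetation fraction ~0.97).  With a cyan background ExG still
# isolates the plants cleanly; with a green-dominated background ExG fails
# too (both-fail case).
triColorImage <- function(probs, bg = c(0, 120, 140)) {
  set.seed(99)
  H <- 64L; W <- 64L
  img <- array(0, c(H, W, 3))
  cls <- matrix(sample(1:3, H * W, TRUE, prob = probs), H, W)
  cols <- rbind(bg,
                c(30, 180, 30),    # plants: very low a, high ExG
                c(200, 60, 50))    # red clutter: high a, negative ExG
  for (ch in 1:3)
    img[, , ch] <- matrix(cols[cls, ch], H, W) + rnorm(H * W, 0, 2)
  clamp(img, 0, 255)
}

labAFailureImage <- function() triColorImage(c(0.90, 0.07, 0.03))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
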