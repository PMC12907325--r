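test_that("excess green follows 2G - R - B pointwise", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(excessGreen(px(0, 255, 0))[1, 1], 510)
  expect_equal(excessGreen(px(80, 80, 80))[1, 1], 0)
  expect_equal(excessGreen(px(50, 120, 30))[1, 1], 160)
  img <- renderScene(cleanSpec())@image
  e <- excessGreen(img)
  expect_identical(dim(e), dim(img)[1:2])
  perm <- sample(nrow(img))
  expect_identical(excessGreen(img[perm, , ]), e[perm, ])
  expect_error(excessGreen(matrix(1, 4, 4)), "H x W x 3")
})

test_that("Otsu threshold splits two-point and bimodal rasters correctly", {
  v <- c(rep(0, 50), rep(255, 50))
  t2 <- otsuThreshold(v)
  expect_gt(t2, 0); expect_lt(t2, 255)
  expect_identical(v > t2, v == 255)

  set.seed(31)
  bim <- c(rnorm(4000, 40, 10), rnorm(4000, 200, 10))
  tb <- otsuThreshold(bim)
  expect_gt(tb, 90); expect_lt(tb, 150)
  # independent oracle: exhaustive between-class variance over 256 bins
  rng <- range(bim)
  bins <- pmin(255, floor((bim - rng[1]) / diff(rng) * 256))
  h <- tabulate(bins + 1, 256); p <- h / sum(h)
  vv <- sapply(0:254, function(t) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    mu0 <- sum(p[1:(t + 1)] * (0:t)) / w0
    mu1 <- sum(p[(t + 2):256] * ((t + 1):255)) / w1
    w0 * w1 * (mu0 - mu1)^2
  })
  top <- which(vv >= max(vv) * (1 - 1e-12))
  bestT <- top[ceiling(length(top) / 2)] - 1
  expect_equal(tb, rng[1] + (bestT + 0.5) / 255 * diff(rng))

  one <- c(rep(10, 99), 200)
  t1 <- otsuThreshold(one)
  expect_identical(sum(one > t1), 1L)
  expect_error(otsuThreshold(rep(3, 10)), "constant")
})

test_that("Otsu agrees with the EBImage reference implementation", {
  skip_if_not_installed("EBImage")
  set.seed(8)
  x <- matrix(runif(64 * 64)^2, 64, 64)
  ours <- otsuThreshold(x)
  ref <- EBImage::otsu(EBImage::Image(x), range = range(x), levels = 256)
  # same split: both thresholds classify identically up to bin resolution
  expect_lt(mean((x > ours) != (x > ref)), 0.01)
})

test_that("Otsu threshold is affine-equivariant", {
  set.seed(5)
  v <- c(rnorm(500, 1, 0.3), rnorm(500, 4, 0.3))
  t0 <- otsuThreshold(v)
  expect_equal(otsuThreshold(2.5 * v + 7), 2.5 * t0 + 7, tolerance = 1e-10)
})

test_that("ExG binarization recovers clean synthetic vegetation", {
  gt <- renderScene(cleanSpec(seed = 6L))
  m <- binarizeExG(gt@image)
  expect_gt(sum(m & gt@vegMask) / sum(gt@vegMask), 0.95)
  expect_error(binarizeExG(array(128, c(8, 8, 3))), "constant")
  # pure discs on flat soil: masks agree except a thin blended boundary
  expect_gt(sum(m & gt@vegMask) / sum(m | gt@vegMask), 0.9)
})

test_that("Lab-a binarization marks the green side and rejects red mulch", {
  gt <- renderScene(cleanSpec(seed = 12L, soilRGB = c(150, 70, 55)))
  m <- binarizeLabA(gt@image)
  expect_gt(sum(m & gt@vegMask) / sum(gt@vegMask), 0.95)
  expect_lt(mean(m[!gt@vegMask]), 0.05)       # mulch background excluded
  e <- binarizeExG(gt@image)
  expect_gt(mean(m == e), 0.9)
})

test_that("binarization is idempotent on its own 0/255 rendering", {
  gt <- renderScene(cleanSpec(seed = 13L))
  m <- binarizeExG(gt@image)
  render <- matrix(m * 255, nrow(m), ncol(m))
  expect_identical(unname(render > otsuThreshold(render)), unname(m))
})

test_that("the selection policy prefers Lab-a and falls back on failure", {
  gt <- renderScene(cleanSpec(seed = 14L))
  direct <- binarizeLabA(gt@image)
  pol <- selectBinary(gt@image, "lab_a")
  expect_identical(as.vector(pol), as.vector(direct))
  auto <- selectBinary(gt@image, "auto")
  expect_identical(attr(auto, "method"), "lab_a")
  img <- labAFailureImage()
  res <- selectBinary(img, "auto")
  expect_identical(attr(res, "method"), "exg")
  # both indices implausible: warn and return Lab-a flagged
  flat <- triColorImage(c(0.05, 0.92, 0.03), bg = c(0, 120, 140))
  expect_warning(bad <- selectBinary(flat, "auto"), "implausible")
  expect_true(attr(bad, "fallbackWarning"))
})
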