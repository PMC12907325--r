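test_that("a single clean row keeps all vegetation near the central line", {
  spec <- cleanSpec(seed = 4L, nRows = 1L)
  gt <- renderScene(spec)
  idx <- which(gt@vegMask, arr.ind = TRUE)
  d <- linePerpDistance(gt@line, idx[, 2] - 1, idx[, 1] - 1)
  expect_true(all(d <= spec@plantRadiusPx + 1))
})

test_that("centered vertical scenes yield a central vertical band", {
  gt <- renderScene(sceneSpec(seed = 2L))
  fit <- fitLineLsq(cbind(which(gt@label == 2L, arr.ind = TRUE)[, 2] - 1,
                          which(gt@label == 2L, arr.ind = TRUE)[, 1] - 1))
  expect_lt(abs(lineTheta(fit)), 1e-9)
  expect_lt(abs(lineIntercept(fit) - 128), 0.5)
  # brute-force band size: pixels within 7.5 px of the center column
  count <- sum(abs(matrix(0:255, 256, 256, byrow = TRUE) - 128) <= 7.5)
  expect_identical(sum(gt@label == 2L), count)
  expect_identical(sum(gt@label == 2L), 15L * 256L)
})

test_that("band fraction matches 15 x centerline length for slanted rows", {
  for (ang in c(-25, 10, 35)) {
    gt <- renderScene(sceneSpec(rowAngleDeg = ang, seed = 5L))
    # oracle: brute-force perpendicular distance over every pixel center
    th <- tan(ang * pi / 180)
    b <- 128 - th * 128
    x <- matrix(0:255, 256, 256, byrow = TRUE); y <- matrix(0:255, 256, 256)
    oracle <- sum(abs(x - th * y - b) / sqrt(1 + th^2) <= 7.5)
    expect_identical(sum(gt@label == 2L), oracle)
    # in-image centerline length L: band area ~ 15 * L within 2%
    len <- 256 / cos(ang * pi / 180)          # crosses top/bottom edges
    expect_lt(abs(sum(gt@label == 2L) - 15 * len) / (15 * len), 0.02)
  }
})

test_that("rendering is deterministic in the spec and varies with the seed", {
  a <- renderScene(sceneSpec(seed = 7L, weedDensity = 1))
  b <- renderScene(sceneSpec(seed = 7L, weedDensity = 1))
  c <- renderScene(sceneSpec(seed = 8L, weedDensity = 1))
  expect_identical(a@image, b@image)
  expect_identical(a@label, b@label)
  expect_gt(sum(a@vegMask != c@vegMask), 0)
})

test_that("vegetation cover is monotone in weed density", {
  counts <- sapply(c(0, 0.3, 0.8, 1.5), function(d)
    sum(renderScene(sceneSpec(seed = 9L, weedDensity = d))@vegMask))
  expect_true(all(diff(counts) >= 0))
})

test_that("labels obey class structure and line priority", {
  gt <- renderScene(sceneSpec(seed = 10L, weedDensity = 0.6))
  expect_true(all(gt@label %in% 0:2))
  band <- rasterizeLine(gt@line, dim(gt@label))
  expect_identical(sum(gt@label == 2L), sum(band))
  expect_true(all(gt@vegMask[gt@label == 1L]))
})

test_that("specs whose central row misses the image are rejected", {
  expect_error(renderScene(sceneSpec(centralOffsetPx = 400)), "outside")
  expect_error(sceneSpec(nRows = 4L), "odd")
})

test_that("datasets round-trip losslessly and deterministically", {
  specs <- sampleSceneSpecs(4, seed = 3L, 64L, 64L)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  renderDataset(specs, d1)
  renderDataset(specs, d2)
  expect_length(list.files(file.path(d1, "images")), 4L)
  lines <- readLinesCSV(d1)
  expect_identical(nrow(lines), 4L)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  gt <- renderScene(specs[[2]])
  expect_identical(readLabelPNG(file.path(d1, "labels", "001.png")), gt@label)
  expect_equal(lines$theta[2], lineTheta(gt@line))
})
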