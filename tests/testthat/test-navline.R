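test_that("largest-component screening keeps the dominant region", {
  m <- matrix(FALSE, 20, 20); m[3:12, 4:13] <- TRUE
  expect_identical(largestComponent(m), m)
  m2 <- m; m2[16:17, 16:19] <- TRUE
  expect_identical(largestComponent(m2), m)
  # equal sizes: earliest (y, x) pixel wins
  tie <- matrix(FALSE, 10, 10); tie[2, 2:4] <- TRUE; tie[8, 2:4] <- TRUE
  keep <- largestComponent(tie)
  expect_identical(which(keep, arr.ind = TRUE)[, "row"], rep(2L, 3))
  expect_identical(largestComponent(matrix(FALSE, 4, 4)), matrix(FALSE, 4, 4))
  # diagonal chains connect under 8- but not 4-connectivity
  diagm <- diag(5) > 0
  expect_identical(sum(largestComponent(diagm, 8L)), 5L)
  expect_identical(sum(largestComponent(diagm, 4L)), 1L)
})

test_that("component labeling agrees with the EBImage reference at 4-connectivity", {
  skip_if_not_installed("EBImage")
  set.seed(44)
  for (i in 1:5) {
    m <- matrix(runif(40 * 40) < 0.35, 40, 40)
    ours <- centrow:::.cc_label(m, 4L)
    ref <- EBImage::bwlabel(m * 1)
    expect_identical(max(ours), as.integer(max(ref)))
    expect_identical(sort(tabulate(ours[ours > 0])),
                     sort(tabulate(ref[ref > 0])))
  }
})

test_that("least-squares fitting matches the closed-form normal equations", {
  y1 <- fitLineLsq(cbind(0:2, 0:2), axis = "yOnX")
  expect_equal(lineTheta(y1), 1); expect_equal(lineIntercept(y1), 0)
  y2 <- fitLineLsq(cbind(c(0, 1, 2), c(0, 1, 1)), axis = "yOnX")
  expect_equal(lineTheta(y2), 0.5)
  expect_equal(lineIntercept(y2), 1 / 6)
  band <- rasterizeLine(navLine(0, 40), c(64, 90), 15L)
  idx <- which(band, arr.ind = TRUE)
  v <- fitLineLsq(cbind(idx[, 2] - 1, idx[, 1] - 1))
  expect_equal(lineTheta(v), 0)
  expect_equal(lineIntercept(v), 40)
  expect_error(fitLineLsq(cbind(c(1, 2, 3), c(5, 5, 5))), "degenerate")
  expect_error(fitLineLsq(cbind(1, 1)), "n >= 2")
})

test_that("navigation line extraction recovers ground truth and screens blobs", {
  gt <- renderScene(sceneSpec(seed = 50L, rowAngleDeg = 8,
                              centralOffsetPx = -15))
  got <- extractNavLine(gt@label)
  expect_lt(angleError(got, gt@line), 0.5)
  lab2 <- gt@label
  lab2[3:7, 3:12] <- 2L                       # 50-px spurious blob
  got2 <- extractNavLine(lab2)
  expect_equal(lineTheta(got2), lineTheta(got))
  expect_equal(lineIntercept(got2), lineIntercept(got))
  expect_null(extractNavLine(matrix(0L, 10, 10)))
  expect_null(extractNavLine(matrix(c(2L, rep(0L, 99)), 10, 10)))  # degenerate
})

test_that("angle error is the acute orientation distance", {
  a <- navLine(0, 10)
  expect_equal(angleError(a, a), 0)
  mk <- function(deg) navLine(tan((90 - deg) * pi / 180), 0)
  expect_equal(angleError(mk(10), mk(170)), 20, tolerance = 1e-9)
  expect_equal(angleError(mk(30), mk(120)), 90, tolerance = 1e-9)
  # metric properties on sampled orientation triples
  set.seed(6)
  for (i in 1:25) {
    t3 <- runif(3, 0, 180)
    d <- function(i, j) angleError(mk(t3[i]), mk(t3[j]))
    expect_equal(d(1, 2), d(2, 1))
    expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-9)
    expect_gte(d(1, 2), 0); expect_lte(d(1, 2), 90)
  }
})

test_that("line IoU matches the lateral-offset geometry", {
  dimv <- c(256, 256)
  a <- navLine(0, 120)
  expect_equal(lineIoU(a, a, dimv), 1)
  expect_equal(lineIoU(a, navLine(0, 125), dimv), 0.5)   # 10 / 20 columns
  expect_equal(lineIoU(a, navLine(0, 135), dimv), 0)     # disjoint bands
  b <- navLine(0.2, 100)
  expect_equal(lineIoU(a, b, dimv), lineIoU(b, a, dimv))
  v <- lineIoU(a, b, dimv)
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("fit-refit on the rasterized band is idempotent", {
  ln <- lineFromEdgeMidpoints(40, 85, 128)
  idx <- which(rasterizeLine(ln, c(128, 128)), arr.ind = TRUE)
  refit <- fitLineLsq(cbind(idx[, 2] - 1, idx[, 1] - 1))
  idx2 <- which(rasterizeLine(refit, c(128, 128)), arr.ind = TRUE)
  refit2 <- fitLineLsq(cbind(idx2[, 2] - 1, idx2[, 1] - 1))
  expect_lt(abs(lineTheta(refit2) - lineTheta(refit)), 1e-6)
})

test_that("line accuracy applies the strict AE/L_IoU rule", {
  mk <- function(ae, li) data.frame(ae_deg = ae, l_iou = li, detected = TRUE,
                                    correct = ae < 5 & li > 0.5)
  all4 <- rbind(mk(0.2, 0.9), mk(1, 0.8), mk(2, 0.7), mk(3, 0.6))
  expect_equal(lineAccuracy(all4), 1)
  expect_equal(lineAccuracy(rbind(all4[-1, ], mk(7, 0.9))), 0.75)
  expect_equal(lineAccuracy(mk(5, 0.9)), 0)       # AE exactly 5 fails
  expect_equal(lineAccuracy(mk(1, 0.5)), 0)       # L_IoU exactly 0.5 fails
  miss <- navReport(NULL, navLine(0, 10), c(64, 64))
  expect_false(miss$correct)
  expect_error(lineAccuracy(all4[0, ]), "empty")
})

test_that("spurious components never perturb the fitted line", {
  set.seed(61)
  gt <- renderScene(sceneSpec(seed = 60L))
  base <- extractNavLine(gt@label)
  for (i in 1:10) {
    lab <- gt@label
    r0 <- sample(220:245, 1); c0 <- sample(5:40, 1)
    lab[r0:(r0 + 4), c0:(c0 + 5)] <- 2L          # 30-px clutter
    got <- extractNavLine(lab)
    expect_equal(lineTheta(got), lineTheta(base))
  }
})
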