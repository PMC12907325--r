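tinyCfg <- function(...) {
  netConfig(channels = c(8L, 16L, 24L, 24L), blocksPerLevel = 1L,
            asppBN = FALSE, asppBias = FALSE, inputHW = c(32L, 32L), ...)
}

test_that("block parameter counts match hand enumeration", {
  m <- withLocalSeed <- centrow:::withLocalSeed(1L,
    buildModel(tinyCfg(useDSC = TRUE, useASPP = FALSE)))
  blk <- m$layers$enc[[2]][[1]]          # DSC block 8 -> 16
  expect_identical(length(blk$wd), 72L)  # depthwise 3x3x8
  expect_identical(length(blk$wp), 128L) # pointwise 8x16
  expect_identical(length(blk$bn$gamma) + length(blk$bn$beta), 32L)
  expect_identical(length(blk$wd) + length(blk$wp) +
                   length(blk$bn$gamma) + length(blk$bn$beta), 232L)
  ma <- centrow:::withLocalSeed(1L,
    buildModel(netConfig(channels = c(8L, 8L, 8L, 8L), blocksPerLevel = 1L,
                         asppBN = FALSE, asppBias = FALSE)))
  ab <- ma$layers$aspp[[3]]              # ASPP on an 8-channel skip
  expect_identical(sum(lengths(ab$wd)), 4L * 72L)
  expect_identical(length(ab$wp), 32L * 8L)
  expect_identical(sum(lengths(ab$wd)) + length(ab$wp), 544L)
})

test_that("forward pass preserves shape and is deterministic in eval mode", {
  set.seed(2)
  m <- buildModel(tinyCfg())
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  f1 <- modelForward(m, x)
  expect_identical(dim(f1$logits), c(32L, 32L, 3L, 2L))
  expect_true(all(is.finite(f1$logits)))
  expect_identical(f1$logits, modelForward(m, x)$logits)
  expect_error(modelForward(m, array(0, c(30, 30, 3, 1))), "divisible")
})

test_that("counted parameters equal the analytic plan totals per variant", {
  plan <- centrow:::defaultChannelPlan()
  for (v in list(c(FALSE, FALSE), c(FALSE, TRUE), c(TRUE, FALSE),
                 c(TRUE, TRUE))) {
    cfg <- netConfig(useDSC = v[1], useASPP = v[2])
    m <- centrow:::withLocalSeed(1L, buildModel(cfg))
    expect_identical(countParameters(m),
                     as.integer(centrow:::countFromPlan(
                       plan$channels, v[1], v[2], plan$blocksPerLevel,
                       plan$asppBN, plan$asppBias)))
  }
})

test_that("architecture toggles move the budget in the published direction", {
  cfgs <- ablationConfigs()
  p <- sapply(cfgs, function(cfg)
    countParameters(centrow:::withLocalSeed(1L, buildModel(cfg))))
  expect_lt(p[["dsc"]], p[["base"]])          # DSC shrinks the model
  expect_gt(p[["full"]], p[["dsc"]])          # ASPP adds parameters
  expect_gt(p[["aspp"]], p[["base"]])
  # ASPP delta equals the ASPP blocks' own budget
  plan <- centrow:::defaultChannelPlan()
  ch <- plan$channels; L <- length(ch)
  asppSum <- sum(sapply(ch[(L - 3):(L - 1)], function(c)
    36 * c + 4 * c^2 + 2 * c + 5 * c))
  expect_identical(p[["full"]] - p[["dsc"]], as.integer(asppSum))
})

test_that("per-block budget breakdown sums to the total", {
  cfg <- tinyCfg()
  tab <- paramBudget(cfg)
  expect_identical(attr(tab, "total"), sum(tab$params))
  m <- centrow:::withLocalSeed(1L, buildModel(cfg))
  expect_identical(attr(tab, "total"), countParameters(m))
})

test_that("channel-plan search recovers a planted budget exactly", {
  planted <- c(8L, 12L, 16L, 20L)
  toy <- c(base = centrow:::countFromPlan(planted, FALSE, FALSE),
           dsc = centrow:::countFromPlan(planted, TRUE, FALSE),
           full = centrow:::countFromPlan(planted, TRUE, TRUE))
  got <- solveChannelPlan(toy, maxWidth = 32L, levels = 4L)
  expect_identical(got$totalResidual, 0)
  expect_identical(got$channels, planted)
  expect_false(got$asppBN); expect_false(got$asppBias)
  got2 <- solveChannelPlan(toy, maxWidth = 32L, levels = 4L)
  expect_identical(got, got2)                  # deterministic
  expect_true(all(got$residuals >= 0))
  expect_true(!is.unsorted(got$residuals))
})

test_that("the network is translation-covariant away from borders", {
  set.seed(9)
  m <- buildModel(tinyCfg(useASPP = FALSE))
  x <- array(runif(128 * 128 * 3), c(128, 128, 3, 1))
  shift <- 16L                                  # multiple of the total stride
  x2 <- array(0, dim(x))
  x2[, (shift + 1):128, , ] <- x[, 1:(128 - shift), , ]
  f1 <- modelForward(m, x)$logits
  f2 <- modelForward(m, x2)$logits
  rows <- 49:80; cols <- 49:80                  # clear of both borders
  expect_lt(max(abs(f2[rows, cols + shift, , ] - f1[rows, cols, , ])), 1e-8)
})

test_that("gradients reach every layer after one training step", {
  set.seed(3)
  m <- buildModel(tinyCfg(useASPP = TRUE))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  y <- array(sample(0:2, 32 * 32, TRUE), c(32, 32, 1))
  fw <- modelForward(m, x, training = TRUE)
  ce <- centrow:::softmaxCE(fw$logits, y)
  gr <- modelBackward(m, fw, ce$grad)
  expect_true(is.finite(ce$loss) && ce$loss > 0)
  leafSums <- c()
  centrow:::walkParams(gr, NULL, function(p, g) {
    leafSums <<- c(leafSums, sum(abs(p))); p
  })
  expect_gt(min(leafSums[leafSums > 0]), 0)
  expect_gt(mean(leafSums > 0), 0.95)           # nearly all leaves touched
})
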