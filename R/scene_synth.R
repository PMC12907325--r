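#' Rendered synthetic scene with exact ground truth
#'
#' Holds the rendered RGB image, the three-class label, the true central-row
#' navigation line and the exact vegetation mask (disc membership, not a
#' color threshold).  The class-2 pixels of `label` are exactly the 15-px
#' rasterization of `line`; every class-1 pixel is a vegetation pixel, and
#' the row band overrides vegetation where they overlap.
#'
#' @slot image `H x W x 3` array, 0..255.
#' @slot label integer `H x W` matrix over `{0, 1, 2}`.
#' @slot line true central-row [NavLine-class].
#' @slot vegMask logical `H x W` matrix.
#' @slot spec the generating [SceneSpec-class].
#' @export
setClass("SceneGT",
  representation(image = "array", label = "matrix", line = "NavLine",
                 vegMask = "matrix", spec = "SceneSpec"))

setMethod("show", "SceneGT", function(object) {
  d <- dim(object@label)
  cat(sprintf("SceneGT: %d x %d, %.1f%% vegetation, %d row-band pixels, row angle %.2f deg\n",
              d[1], d[2], 100 * mean(object@vegMask), sum(object@label == 2L),
              object@line@angleDeg))
})

# Central-row line of a spec, in the xOnY convention.  The image center is
# (W/2, H/2) in 0-based pixel-center coordinates, so for even sizes the
# default line sits on an integer column and the 15-px band covers exactly
# 15 columns.
sceneCentralLine <- function(spec) {
  phi <- spec@rowAngleDeg * pi / 180
  th <- tan(phi)
  cx <- spec@widthPx / 2; cy <- spec@heightPx / 2
  navLine(theta = th, b = cx + spec@centralOffsetPx - th * cy, axis = "xOnY")
}

# Draw a shaded green disc onto image/vegMask (both modified and returned).
drawDisc <- function(image, vegMask, cx, cy, r, colorRGB) {
  H <- nrow(vegMask); W <- ncol(vegMask)
  r0 <- max(1L, floor(cy - r) + 1L); r1 <- min(H, ceiling(cy + r) + 1L)
  c0 <- max(1L, floor(cx - r) + 1L); c1 <- min(W, ceiling(cx + r) + 1L)
  if (r0 > r1 || c0 > c1) return(list(image = image, vegMask = vegMask))
  ys <- (r0:r1) - 1; xs <- (c0:c1) - 1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  inside <- d2 <= r^2
  if (!any(inside)) return(list(image = image, vegMask = vegMask))
  sigma <- r / 2
  alpha <- (0.65 + 0.35 * exp(-d2 / (2 * sigma^2))) * inside
  for (ch in 1:3) {
    sub <- image[r0:r1, c0:c1, ch]
    image[r0:r1, c0:c1, ch] <- (1 - alpha) * sub + alpha * colorRGB[ch]
  }
  vegMask[r0:r1, c0:c1] <- vegMask[r0:r1, c0:c1] | inside
  list(image = image, vegMask = vegMask)
}

#' Render a synthetic crop-field scene
#'
#' Deterministically renders the scene described by `spec`: textured soil,
#' `nRows` parallel rows of Gaussian-shaded green plant discs, off-row weed
#' discs, an optional illumination ramp and half-plane shadow.  Plants are
#' isotropic discs because the downstream method relies only on spatial
#' layout and greenness, not leaf morphology.  Rows are straight lines; the
#' central row passes through the image center column shifted by
#' `centralOffsetPx` at mid-height with tilt `rowAngleDeg` from vertical.
#'
#' Two independent RNG streams are derived from `seed`: one for soil texture
#' and row/plant layout, one for weeds.  Weeds are drawn sequentially from
#' their stream, so raising `weedDensity` extends the weed set without
#' moving existing weeds (vegetation cover is monotone in density).
#'
#' @param spec a [SceneSpec-class].
#' @return a [SceneGT-class].
#' @export
renderScene <- function(spec) {
  validObject(spec)
  H <- spec@heightPx; W <- spec@widthPx
  central <- sceneCentralLine(spec)
  if (!any(rasterizeLine(central, c(H, W), 15L)))
    stop("central row lies entirely outside the image")

  phi <- spec@rowAngleDeg * pi / 180
  dirv <- c(sin(phi), cos(phi))          # along-row unit vector (x, y)
  p0 <- c(W / 2 + spec@centralOffsetPx, H / 2)
  kmax <- (spec@nRows - 1L) %/% 2L
  tHalf <- sqrt(H^2 + W^2) / 2 + spec@plantSpacingPx

  image <- array(0, c(H, W, 3))
  vegMask <- matrix(FALSE, H, W)

  withLocalSeed(spec@seed, {
    # soil with mild texture noise
    noise <- matrix(rnorm(H * W, 0, 6), H, W)
    for (ch in 1:3) image[, , ch] <- clamp(spec@soilRGB[ch] + noise, 0, 255)
    # rows of plants
    for (k in -kmax:kmax) {
      bk <- p0 + k * spec@rowSpacingPx * c(cos(phi), -sin(phi))
      phase <- runif(1, 0, spec@plantSpacingPx)
      for (t in seq(-tHalf + phase, tHalf, by = spec@plantSpacingPx)) {
        miss <- runif(1) < spec@missingPlantProb
        rj <- 1 + runif(1, -spec@plantRadiusJitter, spec@plantRadiusJitter)
        lat <- runif(1, -1, 1)           # bounded 1-px lateral jitter
        hue <- runif(1, -spec@plantHueJitter, spec@plantHueJitter)
        if (miss) next
        ctr <- bk + t * dirv + lat * c(cos(phi), -sin(phi))
        col <- clamp(c(45 * (1 + hue), 135 * (1 + hue), 55) , 0, 255)
        res <- drawDisc(image, vegMask, ctr[1], ctr[2],
                        spec@plantRadiusPx * rj, col)
        image <- res$image; vegMask <- res$vegMask
      }
    }
  })

  nWeeds <- ceiling(spec@weedDensity * H * W / 1000)
  if (nWeeds > 0) {
    margin <- spec@plantRadiusPx + spec@weedRadiusPx
    withLocalSeed(deriveSeed(spec@seed, 1L), {
      for (i in seq_len(nWeeds)) {
        wx <- runif(1, 0, W - 1); wy <- runif(1, 0, H - 1)
        rj <- 1 + runif(1, -0.3, 0.3)
        hue <- runif(1, -spec@plantHueJitter, spec@plantHueJitter)
        # keep weeds off-row: reject centers close to any row centerline
        dmin <- Inf
        for (k in -kmax:kmax) {
          bk <- p0 + k * spec@rowSpacingPx * c(cos(phi), -sin(phi))
          dmin <- min(dmin, abs((wx - bk[1]) * cos(phi) - (wy - bk[2]) * sin(phi)))
        }
        if (dmin <= margin) next
        col <- clamp(c(70 * (1 + hue), 150 * (1 + hue), 60), 0, 255)
        res <- drawDisc(image, vegMask, wx, wy, spec@weedRadiusPx * rj, col)
        image <- res$image; vegMask <- res$vegMask
      }
    })
  }

  if (spec@illuminationGradient > 0) {
    ramp <- 1 + spec@illuminationGradient * ((0:(W - 1)) / (W - 1) - 0.5)
    for (ch in 1:3) image[, , ch] <- image[, , ch] * rep(ramp, each = H)
  }
  if (spec@shadow) {
    a <- 35 * pi / 180
    xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
    ys <- matrix(0:(H - 1), H, W)
    half <- (xs - W / 2) * cos(a) + (ys - H / 2) * sin(a) > 0
    for (ch in 1:3) {
      sl <- image[, , ch]; sl[half] <- sl[half] * 0.6; image[, , ch] <- sl
    }
  }
  image <- clamp(image, 0, 255)

  label <- composeLabels(vegMask, rasterizeLine(central, c(H, W), 15L), 3L)
  new("SceneGT", image = image, label = label, line = central,
      vegMask = vegMask, spec = spec)
}

#' Sample random scene specifications
#'
#' Draws `n` specs emulating the variation seen across row-crop guidance
#' imagery: 3 or 5 rows, row tilt within +/-12 degrees, central-row offset
#' within +/-8% of the image width, variable plant size and spacing, weed
#' densities from clean to cluttered, three soil/mulch palettes, variable
#' illumination and occasional shadows.  All geometric parameters scale with
#' the image width so the same distribution is usable at any working
#' resolution.
#'
#' @param n number of specs.
#' @param seed base seed; scene `i` uses a seed derived from `seed` and `i`.
#' @param widthPx,heightPx rendered image size.
#' @return list of [SceneSpec-class] objects.
#' @export
sampleSceneSpecs <- function(n, seed = 1L, widthPx = 256L, heightPx = 256L) {
  W <- widthPx
  soils <- list(c(120, 85, 60), c(95, 75, 55), c(150, 70, 55))
  withLocalSeed(deriveSeed(seed, 7L), {
    lapply(seq_len(n), function(i) {
      sceneSpec(widthPx = widthPx, heightPx = heightPx,
                nRows = sample(c(3L, 5L), 1),
                rowSpacingPx = runif(1, 0.18, 0.24) * W,
                centralOffsetPx = runif(1, -0.08, 0.08) * W,
                rowAngleDeg = runif(1, -12, 12),
                plantSpacingPx = runif(1, 0.07, 0.10) * W,
                plantRadiusPx = runif(1, 0.030, 0.045) * W,
                weedDensity = runif(1, 0, 0.5),
                weedRadiusPx = 0.016 * W,
                soilRGB = soils[[sample.int(3, 1)]],
                illuminationGradient = runif(1, 0, 0.3),
                shadow = runif(1) < 0.2,
                seed = deriveSeed(seed, i))
    })
  })
}

#' Render a dataset to disk
#'
#' Writes `images/NNN.png`, `labels/NNN.png` (grayscale PNGs holding class
#' indices), `lines.csv` (`id,theta,b,angle_deg`) and `manifest.yaml`.
#'
#' @param specs list of [SceneSpec-class] objects.
#' @param outDir output directory (created if missing).
#' @return the manifest (invisibly), as a list.
#' @export
renderDataset <- function(specs, outDir) {
  dir.create(file.path(outDir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "labels"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(specs))
  files <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    id <- sprintf("%03d", i - 1L)
    gt <- renderScene(specs[[i]])
    writeImagePNG(gt@image, file.path(outDir, "images", paste0(id, ".png")))
    writeLabelPNG(gt@label, file.path(outDir, "labels", paste0(id, ".png")))
    rows[[i]] <- data.frame(id = id, theta = gt@line@theta, b = gt@line@b,
                            angle_deg = gt@line@angleDeg)
    files[[i]] <- list(id = id, image = file.path("images", paste0(id, ".png")),
                       label = file.path("labels", paste0(id, ".png")),
                       seed = specs[[i]]@seed)
  }
  lines <- do.call(rbind, rows)
  utils::write.csv(lines, file.path(outDir, "lines.csv"), row.names = FALSE)
  manifest <- list(n_scenes = length(specs), files = files,
                   lines_csv = "lines.csv")
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a rendered dataset's navigation lines
#'
#' @param dir dataset directory written by [renderDataset()].
#' @return data.frame with columns `id`, `theta`, `b`, `angle_deg`.
#' @export
readLinesCSV <- function(dir) {
  utils::read.csv(file.path(dir, "lines.csv"),
                  colClasses = c(id = "character"))
}
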