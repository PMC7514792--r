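# Seeded synthetic fundus generator: a bright circular aperture on a dark
# surround containing vessel-like random-walk polylines radiating from a
# bright optic-disk blob and a darker macular blob, degraded by defocus
# blur (Gaussian, px) and vignetting (radial multiplicative falloff). The
# two severities define the ground-truth quality label.

#' Scene parameters for the synthetic fundus generator
#'
#' @param height,width canvas size in pixels.
#' @param fovCenterRow,fovCenterCol,fovRadius aperture geometry (radius must
#'   stay below half the smaller canvas dimension).
#' @param baseColor RGB retina background color (0-255).
#' @param vesselCount number of vessel polylines; @param vesselWidthRange
#'   min/max stamp radius in pixels.
#' @param odOffset optic-disk center offset from the FOV center (pixels,
#'   along the horizontal axis); @param odRadius,odBrightness disk geometry
#'   and added brightness; @param maculaRadius,maculaDarkness macular blob.
#' @param blurSigma defocus blur (Gaussian sd, px, >= 0).
#' @param vignetteStrength radial falloff strength in \[0, 1\].
#' @param noiseSd additive Gaussian sensor noise sd (gray levels).
#' @param blurLimit,vignetteLimit severities up to which an image is labeled
#'   adequate.
#' @param seed RNG seed making the scene reproducible.
#' @return named list of class `"SceneParams"`.
#' @export
sceneParams <- function(height = 450, width = 450,
                        fovCenterRow = height / 2 + 0.5,
                        fovCenterCol = width / 2 + 0.5,
                        fovRadius = 205,
                        baseColor = c(185, 95, 40),
                        vesselCount = 9, vesselWidthRange = c(2, 4),
                        odOffset = 0.55, odRadius = 0.14,
                        odBrightness = 60,
                        maculaRadius = 0.18, maculaDarkness = 35,
                        blurSigma = 0, vignetteStrength = 0, noiseSd = 2,
                        blurLimit = 2.0, vignetteLimit = 0.4, seed = 1) {
  p <- list(height = height, width = width, fovCenterRow = fovCenterRow,
            fovCenterCol = fovCenterCol, fovRadius = fovRadius,
            baseColor = baseColor, vesselCount = vesselCount,
            vesselWidthRange = vesselWidthRange, odOffset = odOffset,
            odRadius = odRadius, odBrightness = odBrightness,
            maculaRadius = maculaRadius, maculaDarkness = maculaDarkness,
            blurSigma = blurSigma, vignetteStrength = vignetteStrength,
            noiseSd = noiseSd, blurLimit = blurLimit,
            vignetteLimit = vignetteLimit, seed = seed)
  if (fovRadius <= 0 || fovRadius >= min(height, width) / 2)
    stop("fovRadius must lie in (0, min(height, width) / 2)")
  if (blurSigma < 0 || vignetteStrength < 0 || vignetteStrength > 1 ||
      noiseSd < 0)
    stop("degradation severities out of range")
  class(p) <- "SceneParams"
  p
}

# Separable Gaussian blur (reflect padding); sigma in pixels.
gaussBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  hw <- max(1, ceiling(3 * sigma))
  g <- exp(-(seq(-hw, hw))^2 / (2 * sigma^2))
  g <- g / sum(g)
  xp <- padReflect(x, hw, hw)
  tmp <- matrix(0, nrow(x), ncol(xp))
  for (i in seq_along(g))
    tmp <- tmp + g[i] * xp[(i - 1) + seq_len(nrow(x)), , drop = FALSE]
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_along(g))
    out <- out + g[j] * tmp[, (j - 1) + seq_len(ncol(x)), drop = FALSE]
  out
}

# Smooth low-frequency texture field on [−1, 1] from a coarse random grid.
smoothField <- function(H, W, cells = 7) {
  g <- matrix(runif(cells^2, -1, 1), cells, cells)
  resizeTo(g, H, W)
}

#' Generate one synthetic fundus image
#'
#' Deterministic for a fixed seed. The label is adequate (1) iff
#' `blurSigma <= blurLimit` and `vignetteStrength <= vignetteLimit`.
#'
#' @param params a [sceneParams()] object.
#' @return list with `image` (H x W x 3 integer-valued array, 0-255),
#'   `label` (1 adequate / 0 inadequate) and `params`.
#' @export
generateFundus <- function(params) {
  stopifnot(inherits(params, "SceneParams"))
  p <- params
  H <- p$height; W <- p$width
  R <- p$fovRadius
  cr <- p$fovCenterRow; cc <- p$fovCenterCol
  img <- withSeed(p$seed, {
    rows <- seq_len(H); cols <- seq_len(W)
    d2 <- outer((rows - cr)^2, (cols - cc)^2, "+")
    inside <- d2 <= R^2

    # retina background with mild low-frequency mottling
    tex <- smoothField(H, W) * 10
    ch <- list()
    for (k in 1:3) ch[[k]] <- matrix(p$baseColor[k], H, W) + tex

    # optic disk: bright Gaussian blob right of center
    odr <- p$odRadius * R
    odRow <- cr + rnorm(1, 0, 2)
    odCol <- cc + p$odOffset * R * sample(c(-1, 1), 1)
    odD2 <- outer((rows - odRow)^2, (cols - odCol)^2, "+")
    odBump <- exp(-odD2 / (2 * (0.7 * odr)^2))
    for (k in 1:3) ch[[k]] <- ch[[k]] + p$odBrightness * odBump

    # macula: darker blob opposite the disk
    mRow <- cr; mCol <- 2 * cc - odCol
    mD2 <- outer((rows - mRow)^2, (cols - mCol)^2, "+")
    mBump <- exp(-mD2 / (2 * (0.7 * p$maculaRadius * R)^2))
    ch[[1]] <- ch[[1]] - 0.6 * p$maculaDarkness * mBump
    ch[[2]] <- ch[[2]] - p$maculaDarkness * mBump

    # vessels: random walks radiating from the optic disk
    vmask <- matrix(0, H, W)
    for (v in seq_len(p$vesselCount)) {
      ang <- runif(1, 0, 2 * pi)
      pos <- c(odRow, odCol)
      wdt <- runif(1, p$vesselWidthRange[1], p$vesselWidthRange[2])
      steps <- round(1.6 * R)
      offs <- which(outer((-5:5)^2, (-5:5)^2, "+") <= wdt^2, arr.ind = TRUE) - 6
      for (s in seq_len(steps)) {
        ang <- ang + rnorm(1, 0, 0.12)
        pos <- pos + c(sin(ang), cos(ang))
        pr <- round(pos[1] + offs[, 1]); pc <- round(pos[2] + offs[, 2])
        ok <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
        vmask[cbind(pr[ok], pc[ok])] <- 1
        if ((pos[1] - cr)^2 + (pos[2] - cc)^2 > (1.05 * R)^2) break
      }
    }
    vfac <- 1 - vmask * runif(1, 0.25, 0.4)
    for (k in 1:3) ch[[k]] <- ch[[k]] * vfac

    # vignetting: radial multiplicative falloff
    if (p$vignetteStrength > 0) {
      vig <- 1 - p$vignetteStrength * d2 / R^2
      vig[vig < 0] <- 0
      for (k in 1:3) ch[[k]] <- ch[[k]] * vig
    }

    # aperture: near-black surround
    for (k in 1:3) ch[[k]] <- ch[[k]] * inside + 3 * !inside

    # defocus blur + sensor noise, quantized to 8 bits
    out <- array(0, c(H, W, 3))
    for (k in 1:3) {
      x <- gaussBlur(ch[[k]], p$blurSigma)
      x <- x + matrix(rnorm(H * W, 0, p$noiseSd), H, W)
      out[, , k] <- pmin(pmax(round(x), 0), 255)
    }
    out
  })
  label <- as.integer(p$blurSigma <= p$blurLimit &
                      p$vignetteStrength <= p$vignetteLimit)
  list(image = img, label = label, params = p)
}

#' Generate a labeled synthetic dataset manifest
#'
#' Draws per-image degradation severities: adequate images get mild defocus
#' (U(0, 1.5) px) and vignetting (U(0, 0.3)); inadequate images are
#' degraded along one or both axes (blur U(3, 6) px, vignetting
#' U(0.55, 0.9)), mirroring clinically rejected captures. The manifest
#' records every scene parameter; images are materialized on demand with
#' [generateFundus()] (or eagerly with `materialize = TRUE`).
#'
#' @param n number of images (>= 4); @param adequateFraction fraction of
#'   adequate-quality images; @param seed master seed.
#' @param materialize if TRUE also return the generated images as a list.
#' @param ... overrides passed to [sceneParams()].
#' @return list with `manifest` (data.frame, one row per image incl. label
#'   and per-image seed), `labels`, and optionally `images`.
#' @export
generateFundusDataset <- function(n, adequateFraction = 0.86, seed = 1,
                                  materialize = FALSE, ...) {
  if (n < 4) stop("need at least 4 images")
  nAde <- round(n * adequateFraction)
  labels <- c(rep(1L, nAde), rep(0L, n - nAde))
  seeds <- spawnSeeds(seed, n)
  rows <- withSeed(seed, {
    lapply(seq_len(n), function(i) {
      if (labels[i] == 1) {
        blur <- runif(1, 0, 1.5)
        vig <- runif(1, 0, 0.3)
      } else {
        axis <- sample(c("blur", "vignette", "both"), 1)
        blur <- if (axis %in% c("blur", "both")) runif(1, 3, 6) else
          runif(1, 0, 1.5)
        vig <- if (axis %in% c("vignette", "both")) runif(1, 0.55, 0.9) else
          runif(1, 0, 0.3)
      }
      data.frame(id = i, blurSigma = blur, vignetteStrength = vig,
                 noiseSd = runif(1, 1, 3), seed = seeds[i])
    })
  })
  manifest <- do.call(rbind, rows)
  manifest$label <- labels
  out <- list(manifest = manifest, labels = labels)
  if (materialize)
    out$images <- lapply(seq_len(n), function(i)
      generateFundus(manifestScene(manifest[i, ], ...))$image)
  out
}

#' Scene parameters from a manifest row
#'
#' @param row one row of a [generateFundusDataset()] manifest.
#' @param ... further overrides passed to [sceneParams()].
#' @export
manifestScene <- function(row, ...) {
  sceneParams(blurSigma = row$blurSigma,
              vignetteStrength = row$vignetteStrength,
              noiseSd = row$noiseSd, seed = row$seed, ...)
}

#' Write a dataset to disk as PNGs plus a manifest CSV
#'
#' @param ds result of [generateFundusDataset()]; @param dir output
#'   directory; @param ... overrides passed to [sceneParams()].
#' @return the directory, invisibly.
#' @export
writeFundusDataset <- function(ds, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(ds$manifest))) {
    im <- generateFundus(manifestScene(ds$manifest[i, ], ...))$image
    writeFundus(im, file.path(dir, sprintf("img_%04d.png", i)))
  }
  write.csv(ds$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
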