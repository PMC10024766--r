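# Seeded synthetic (image, mask) generators. Two regimes:
#  - "blob": 1-3 smooth random shapes on a textured background, a stand-in
#    for generic salient-object scenes;
#  - "xray": a dark field with a brighter soft-tissue region containing a
#    low-contrast elongated curved bone ridge (optionally branched), the
#    statistical stand-in for pig-leg X-ray images. The mask is the exact
#    bone tube. No radiographic physics is modeled.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Synthetic dataset configuration
#'
#' Defaults encode the intended difficulty of each regime: blob scenes get
#' moderate contrast (0.6) and pixel noise 0.05; X-ray scenes get low bone
#' contrast (0.15) over the soft tissue and noise 0.03, below half the
#' contrast so the bone stays statistically detectable.
#'
#' @param nImages number of (image, mask) pairs.
#' @param imageSize side length in pixels (at least 32).
#' @param mode \code{"blob"} or \code{"xray"}.
#' @param contrast foreground-background intensity separation in (0, 1].
#' @param noiseSigma Gaussian pixel noise standard deviation.
#' @param seed base seed; image i uses \code{seed + i}.
#' @return A validated configuration list.
#' @export
synthConfig <- function(nImages = 1L, imageSize = 224L,
                        mode = c("blob", "xray"), contrast = NULL,
                        noiseSigma = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (nImages < 1L) stop("nImages must be at least 1")
  if (imageSize < 32L) stop("imageSize must be at least 32")
  if (is.null(contrast)) contrast <- if (mode == "blob") 0.6 else 0.15
  if (is.null(noiseSigma)) noiseSigma <- if (mode == "blob") 0.05 else 0.03
  if (contrast <= 0 || contrast > 1) stop("contrast must be in (0, 1]")
  if (noiseSigma < 0) stop("noiseSigma must be non-negative")
  list(nImages = as.integer(nImages), imageSize = as.integer(imageSize),
       mode = mode, contrast = contrast, noiseSigma = noiseSigma,
       seed = as.integer(seed))
}

# Smooth value noise: coarse Gaussian grid bilinearly upsampled, clipped.
valueNoise <- function(S, cells = 28L, sd = 1) {
  g <- array(stats::rnorm(cells * cells, 0, sd), c(cells, cells, 1L, 1L))
  m <- cppBilinearForward(g, S, S)
  dim(m) <- c(S, S)
  m
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Wobbly ellipse membership for a pixel grid.
insideBlob <- function(S, cx, cy, r0, aspect, rot, amps, phases) {
  xs <- matrix(rep(seq_len(S), each = S), S)   # column index
  ys <- matrix(rep(seq_len(S), S), S)          # row index
  dx <- (xs - cx) * cos(rot) + (ys - cy) * sin(rot)
  dy <- -(xs - cx) * sin(rot) + (ys - cy) * cos(rot)
  th <- atan2(dy, dx / aspect)
  rr <- sqrt((dx / aspect)^2 + dy^2)
  wob <- 1 + amps[1] * sin(th + phases[1]) + amps[2] * sin(2 * th + phases[2]) +
    amps[3] * sin(3 * th + phases[3])
  rr <= r0 * wob
}

#' Generate one blob scene
#'
#' Draws 1-3 smooth random shapes (wobbly rotated ellipses, possibly touching
#' the border) on a textured background; the mask is the union of the shapes.
#' The foreground fraction is kept within \[0.02, 0.6\].
#'
#' @param cfg configuration from \code{\link{synthConfig}} (mode
#'   \code{"blob"}).
#' @param seed seed fully determining the sample.
#' @return list with \code{image} (S x S x 3 in \[0, 1\]), binary
#'   \code{mask} (S x S) and generator \code{meta}.
#' @export
genBlobScene <- function(cfg = synthConfig(mode = "blob"), seed = cfg$seed) {
  S <- cfg$imageSize
  withSeed(seed, {
    mask <- NULL
    shapes <- list()
    for (try in 1:25) {
      k <- sample.int(3L, 1L)
      shapes <- lapply(seq_len(k), function(j) {
        list(cx = stats::runif(1, 0.08, 0.92) * S,
             cy = stats::runif(1, 0.08, 0.92) * S,
             r0 = stats::runif(1, 0.10, 0.26) * S,
             aspect = stats::runif(1, 0.6, 1.5),
             rot = stats::runif(1, 0, pi),
             amps = stats::rnorm(3, 0, 0.06),
             phases = stats::runif(3, 0, 2 * pi))
      })
      mask <- Reduce(`|`, lapply(shapes, function(s) {
        insideBlob(S, s$cx, s$cy, s$r0, s$aspect, s$rot, s$amps, s$phases)
      }))
      frac <- mean(mask)
      if (frac >= 0.02 && frac <= 0.6) break
    }
    base <- stats::runif(3, 0.2, 0.45)
    tex <- pmin(pmax(valueNoise(S, 28L, 1), -2.5), 2.5) * 0.06
    fgTint <- stats::rnorm(3, 0, 0.03)
    img <- array(0, c(S, S, 3L))
    for (c in 1:3) {
      bg <- base[c] + tex
      fg <- base[c] + cfg$contrast * 0.5 + fgTint[c] + 0.3 * tex
      ch <- bg
      ch[mask] <- fg[mask]
      img[, , c] <- ch
    }
    if (cfg$noiseSigma > 0) {
      img <- img + stats::rnorm(length(img), 0, cfg$noiseSigma)
    }
    list(image = clip01(img), mask = mask * 1,
         meta = list(mode = "blob", seed = seed, nShapes = length(shapes),
                     contrast = cfg$contrast, noiseSigma = cfg$noiseSigma))
  })
}

bezierPoints <- function(p0, p1, p2, n = 300L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
}

# Distance (per pixel) to a densely sampled curve, via the exact EDT of the
# rasterized curve points.
curveDistance <- function(S, pts) {
  r <- pmin(pmax(round(pts[, 2]), 1), S)
  c <- pmin(pmax(round(pts[, 1]), 1), S)
  fg <- matrix(FALSE, S, S)
  fg[cbind(r, c)] <- TRUE
  cppDistanceTransform(fg)$dist
}

#' Generate one X-ray style bone scene
#'
#' A dark field with a brighter smooth soft-tissue region (random closed
#' contour) containing an elongated curved bone ridge (quadratic spline
#' tube, branched at one end with probability 1/2) whose intensity exceeds
#' the tissue by \code{contrast}. The mask is exactly the bone tube, which
#' is constructed strictly inside the tissue region.
#'
#' @param cfg configuration from \code{\link{synthConfig}} (mode
#'   \code{"xray"}).
#' @param seed seed fully determining the sample.
#' @return list with \code{image}, \code{mask}, \code{meta} as in
#'   \code{\link{genBlobScene}}.
#' @export
genXrayLeg <- function(cfg = synthConfig(mode = "xray"), seed = cfg$seed) {
  S <- cfg$imageSize
  withSeed(seed, {
    cx <- S / 2 + stats::rnorm(1, 0, 0.04 * S)
    cy <- S / 2 + stats::rnorm(1, 0, 0.04 * S)
    R0 <- stats::runif(1, 0.30, 0.36) * S
    amps <- stats::rnorm(4, 0, 0.05)
    phases <- stats::runif(4, 0, 2 * pi)
    rho <- function(th) {
      R0 * (1 + amps[1] * cos(th + phases[1]) + amps[2] * cos(2 * th + phases[2]) +
              amps[3] * cos(3 * th + phases[3]) + amps[4] * cos(4 * th + phases[4]))
    }
    xs <- matrix(rep(seq_len(S), each = S), S)
    ys <- matrix(rep(seq_len(S), S), S)
    thPix <- atan2(ys - cy, xs - cx)
    rPix <- sqrt((xs - cx)^2 + (ys - cy)^2)
    tissue <- rPix <= rho(thPix)

    mask <- NULL
    width <- NA
    for (try in 1:25) {
      phi <- stats::runif(1, 0, 2 * pi)
      radAt <- function(a) 0.62 * rho(a)
      p0 <- c(cx + radAt(phi + pi) * cos(phi + pi),
              cy + radAt(phi + pi) * sin(phi + pi))
      p2 <- c(cx + radAt(phi) * cos(phi), cy + radAt(phi) * sin(phi))
      perp <- c(-sin(phi), cos(phi))
      p1 <- c(cx, cy) + perp * stats::rnorm(1, 0, 0.22 * R0)
      pts <- bezierPoints(p0, p1, p2)
      width <- stats::runif(1, 0.030, 0.050) * S
      tube <- curveDistance(S, pts) <= width
      if (stats::runif(1) < 0.5) {   # branch near one end
        tEnd <- pts[round(0.85 * nrow(pts)), ]
        bAng <- phi + stats::runif(1, 0.5, 0.9) * sample(c(-1, 1), 1)
        bLen <- 0.35 * R0
        b2 <- tEnd + bLen * c(cos(bAng), sin(bAng))
        bmid <- (tEnd + b2) / 2 + stats::rnorm(2, 0, 0.03 * R0)
        bpts <- bezierPoints(tEnd, bmid, b2, 120L)
        tube <- tube | (curveDistance(S, bpts) <= 0.7 * width)
      }
      # containment guarantee: keep only tube pixels with tissue margin
      depth <- cppDistanceTransform(!tissue)$dist
      mask <- tube & (depth > width / 2 + 2)
      frac <- mean(mask)
      if (frac >= 0.02 && frac <= 0.6) break
    }

    grad <- stats::rnorm(2, 0, 1)
    grad <- grad / sqrt(sum(grad^2))
    shade <- 0.06 * (grad[1] * (xs - cx) + grad[2] * (ys - cy)) / S
    img <- matrix(0.05, S, S) + 0.02 * valueNoise(S, 20L)
    tissueVal <- 0.35 + shade + 0.03 * valueNoise(S, 24L)
    img[tissue] <- tissueVal[tissue]
    img[mask] <- tissueVal[mask] + cfg$contrast
    if (cfg$noiseSigma > 0) {
      img <- img + stats::rnorm(length(img), 0, cfg$noiseSigma)
    }
    img <- clip01(img)
    list(image = array(rep(img, 3L), c(S, S, 3L)), mask = mask * 1,
         meta = list(mode = "xray", seed = seed, width = width,
                     contrast = cfg$contrast, noiseSigma = cfg$noiseSigma))
  })
}

#' Generate one sample of either regime
#'
#' @param cfg configuration from \code{\link{synthConfig}}.
#' @param seed seed fully determining the sample.
#' @return list with \code{image}, \code{mask}, \code{meta}.
#' @export
genSample <- function(cfg, seed = cfg$seed) {
  if (cfg$mode == "blob") genBlobScene(cfg, seed) else genXrayLeg(cfg, seed)
}

#' Write a synthetic dataset to disk
#'
#' Creates \code{out/images/NNN.png}, \code{out/masks/NNN.png} (masks stored
#' as 0/255 8-bit PNG) and \code{out/manifest.json} with the seed and
#' per-image generator metadata. Regeneration with the same configuration is
#' byte-identical.
#'
#' @param cfg configuration from \code{\link{synthConfig}}.
#' @param out output directory (created if needed).
#' @return The dataset index from \code{\link{loadDatasetDir}}, invisibly.
#' @export
genDataset <- function(cfg, out) {
  dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "masks"), recursive = TRUE, showWarnings = FALSE)
  meta <- vector("list", cfg$nImages)
  for (i in seq_len(cfg$nImages)) {
    s <- genSample(cfg, cfg$seed + i)
    stem <- sprintf("%03d", i)
    png::writePNG(s$image, file.path(out, "images", paste0(stem, ".png")))
    png::writePNG(s$mask, file.path(out, "masks", paste0(stem, ".png")))
    meta[[i]] <- c(list(stem = stem), s$meta)
  }
  jsonlite::write_json(
    list(mode = cfg$mode, nImages = cfg$nImages, imageSize = cfg$imageSize,
         contrast = cfg$contrast, noiseSigma = cfg$noiseSigma,
         seed = cfg$seed, images = meta),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(loadDatasetDir(out))
}
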