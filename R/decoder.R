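# Decoder: pyramid pooling over the deepest encoder feature, then four
# full-scale skip-connection stages. Each stage concatenates four
# quarter-channel-reduced, resized source maps (encoder maps at the same or
# finer scale, decoder maps / pyramid feature at coarser scale), passes the
# concatenation through a 3x3 conv-BN-ReLU, and adds the resized, projected
# carried feature (residual form). A 3x3 prediction head plus 2x bilinear
# upsampling and a sigmoid produce the coarse saliency map at 224x224.

#' Full-scale skip-connection wiring table
#'
#' Which features feed each decoder stage: four concatenated sources plus the
#' carried (residually added) feature. \code{"P"} is the pyramid-pooled
#' feature, \code{"en<i>"} / \code{"de<i>"} are encoder / decoder stage
#' outputs.
#'
#' @return A data.frame with columns \code{stage}, \code{carried},
#'   \code{src1}..\code{src4}.
#' @export
scmWiring <- function() {
  data.frame(
    stage = c(4L, 3L, 2L, 1L),
    carried = c("P", "de4", "de3", "de2"),
    src1 = c("en4", "P", "P", "P"),
    src2 = c("en3", "en3", "de4", "de4"),
    src3 = c("en2", "en2", "en2", "de3"),
    src4 = c("en1", "en1", "en1", "en1"),
    stringsAsFactors = FALSE
  )
}

buildPPM <- function(store, ctx, C = 128L, bins = c(1L, 2L, 3L, 6L)) {
  nb <- length(bins)
  cb <- max(1L, C %/% nb)
  branchConvs <- lapply(seq_len(nb), function(i) {
    convBnRelu(store, sprintf("dec.ppm.bin%d", bins[i]), C, cb, k = 1L,
               ctx = ctx)
  })
  proj <- convBnRelu(store, "dec.ppm.proj", C + nb * cb, C, k = 1L, ctx = ctx)
  fwd <- function(x) {
    d <- dim(x$v)
    if (any(bins > min(d[1], d[2]))) {
      stop("pyramid bin larger than spatial size")
    }
    pieces <- c(list(x), lapply(seq_len(nb), function(i) {
      tBilinear(branchConvs[[i]]$fwd(tAdaptiveAvg(x, bins[i], bins[i])),
                d[1], d[2])
    }))
    proj$fwd(tConcatC(pieces))
  }
  list(fwd = fwd)
}

# Bilinear resize to a target spatial size plus 1x1 channel projection.
buildResizeAdjust <- function(store, tag, cin, cout) {
  proj <- convLayer(store, tag, cin, cout, k = 1L, bias = TRUE)
  list(
    proj = proj,
    fwd = function(x, th, tw) proj$fwd(tBilinear(x, th, tw))
  )
}

#' Resize-and-adjust operation
#'
#' Bilinear resize of a feature map to a target spatial size followed by a
#' 1x1 convolution projecting to a target channel count, the shape-matching
#' operation applied to every skip-connection source and carried feature.
#'
#' @param x numeric array (H, W, C) or (H, W, C, N).
#' @param targetHW integer vector of length 2, target (height, width).
#' @param weights optional (1, 1, C, Cout) projection kernel; defaults to a
#'   seeded random projection to \code{targetC} channels.
#' @param targetC target channel count (ignored when \code{weights} given).
#' @param bias optional numeric bias of length Cout (default zeros).
#' @return numeric array (targetH, targetW, Cout, N).
#' @export
resizeAdjust <- function(x, targetHW, weights = NULL, targetC = NULL,
                         bias = NULL) {
  x <- as4d(x)
  if (length(targetHW) != 2L || any(targetHW < 1)) {
    stop("invalid target size")
  }
  C <- dim(x)[3]
  if (is.null(weights)) {
    if (is.null(targetC) || targetC < 1) stop("invalid target channels")
    weights <- kaimingUniform(1L, 1L, C, as.integer(targetC))
  }
  if (is.null(bias)) bias <- numeric(dim(weights)[4])
  r <- cppBilinearForward(x, as.integer(targetHW[1]),
                          as.integer(targetHW[2]))
  y <- cppConvForward(r, weights, 1L, 1L, 0L, 0L, 1L, 1L)
  y + rep(bias, each = dim(y)[1] * dim(y)[2])
}

buildDecoder <- function(store, ctx, encChannels, stageChannels,
                         ppmBins, reduceFraction = 0.25) {
  ppm <- buildPPM(store, ctx, C = encChannels[5], bins = ppmBins)
  wiring <- scmWiring()
  # widths indexed by decoder stage number (1..4)
  widthOf <- function(name, P = encChannels[5]) {
    if (name == "P") return(P)
    i <- as.integer(substring(name, 3))
    if (startsWith(name, "en")) encChannels[i] else stageChannels[5L - i]
  }
  stagesSpec <- vector("list", 4L)
  for (r in seq_len(4L)) {
    i <- wiring$stage[r]
    W <- stageChannels[5L - i]     # stageChannels is ordered de4..de1
    q <- max(1L, as.integer(floor(W * reduceFraction)))
    srcNames <- unlist(wiring[r, paste0("src", 1:4)], use.names = FALSE)
    reduces <- lapply(seq_along(srcNames), function(k) {
      convBnRelu(store, sprintf("dec.s%d.reduce%d", i, k),
                 widthOf(srcNames[k]), q, k = 1L, ctx = ctx)
    })
    fuse <- convBnRelu(store, sprintf("dec.s%d.fuse", i), 4L * q, W,
                       ctx = ctx)
    adj <- buildResizeAdjust(store, sprintf("dec.s%d.adjust", i),
                             widthOf(wiring$carried[r]), W)
    stagesSpec[[r]] <- list(i = i, W = W, q = q, srcNames = srcNames,
                            carried = wiring$carried[r], reduces = reduces,
                            fuse = fuse, adj = adj)
  }
  head <- convLayer(store, "dec.head", stageChannels[4], 1L, k = 3L,
                    bias = TRUE)

  fwd <- function(encMaps) {
    if (length(encMaps) != 5L) stop("decoder expects 5 encoder maps")
    P <- ppm$fwd(encMaps[[5]])
    pool <- list(P = P, en1 = encMaps[[1]], en2 = encMaps[[2]],
                 en3 = encMaps[[3]], en4 = encMaps[[4]])
    deOut <- list()
    for (sp in stagesSpec) {
      th <- dim(encMaps[[sp$i]]$v)[1]
      tw <- dim(encMaps[[sp$i]]$v)[2]
      reduced <- lapply(seq_len(4L), function(k) {
        tBilinear(sp$reduces[[k]]$fwd(pool[[sp$srcNames[k]]]), th, tw)
      })
      fused <- sp$fuse$fwd(tConcatC(reduced))
      carried <- sp$adj$fwd(pool[[sp$carried]], th, tw)
      out <- tAdd(fused, carried)
      nm <- paste0("de", sp$i)
      pool[[nm]] <- out
      deOut[[nm]] <- out
    }
    x1 <- deOut[["de1"]]
    d1 <- dim(x1$v)
    logits <- tBilinear(head$fwd(x1), 2L * d1[1], 2L * d1[2])
    list(ppm = P, stages = deOut, logits = logits)
  }
  list(fwd = fwd, stagesSpec = stagesSpec, ppm = ppm)
}

#' Pyramid-pool the terminal encoder feature
#'
#' Multi-bin average pooling of the deepest (7x7x128) encoder feature with
#' per-bin 1x1 projections, upsampling, concatenation with the input and a
#' 1x1 projection back to 128 channels; the global-context feature feeding
#' every decoder stage.
#'
#' @param model a \code{SODModel}.
#' @param x5 terminal encoder feature, array (7, 7, 128) or (7, 7, 128, N).
#' @return Array of the same shape as \code{x5}.
#' @export
pyramidPool <- function(model, x5) {
  x5 <- as4d(x5)
  checkActivations(x5)
  model@engine$decoder$ppm$fwd(tnode(x5))$v
}
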