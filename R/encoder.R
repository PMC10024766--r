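# Encoder: five stride-2 stages ending in a multiscale attention module
# (MAM). Each MAM runs a shared conv-BN-ReLU, three dilated branches at 2x /
# 1x / 0.5x spatial scale, fuses them by element-wise sum, derives per-branch
# channel and spatial self-attention weights from the sum, normalizes the
# three branch gates with a softmax, and adds the fused, gated sum back onto
# the module input (residual form).

#' Multiscale attention module (MAM)
#'
#' Builds the per-stage attention block of the encoder for feature maps with
#' \code{C} channels. The three scale branches are: bilinear upsample 2x then
#' dilated conv; dilated conv at native scale; 2x average pool then dilated
#' conv. Branch outputs are resized back to the native scale, summed, and
#' gated by per-branch channel (x) spatial attention weights normalized with
#' a softmax across the three branches; a 1x1 fuse convolution and a residual
#' addition of the module input close the block.
#'
#' @param C number of channels of the stage feature map.
#' @param dilations integer vector of length 3, dilation rate per branch.
#' @param reduction channel-attention bottleneck reduction.
#' @param store optional shared parameter store.
#' @param tag parameter tag prefix.
#' @param ctx optional context environment with a logical \code{training}.
#' @return An object of class \code{sodMAM}; run it with
#'   \code{\link{mamForward}}.
#' @export
newMAM <- function(C, dilations = c(1L, 2L, 4L), reduction = 4L,
                   store = NULL, tag = "mam", ctx = NULL, strict = TRUE) {
  if (length(dilations) != 3L) stop("MAM requires exactly 3 branch dilations")
  if (is.null(store)) store <- newStore()
  if (is.null(ctx)) {
    ctx <- new.env(parent = emptyenv())
    ctx$training <- TRUE
  }
  shared <- convBnRelu(store, paste0(tag, ".shared"), C, C, ctx = ctx)
  branches <- lapply(1:3, function(i) {
    convBnRelu(store, paste0(tag, ".branch", i), C, C,
               dilation = as.integer(dilations[i]), ctx = ctx)
  })
  catts <- lapply(1:3, function(i) {
    newChannelAttention(C, reduction, store, paste0(tag, ".catt", i))
  })
  satts <- lapply(1:3, function(i) {
    newSpatialAttention(store, paste0(tag, ".satt", i))
  })
  fuse <- convLayer(store, paste0(tag, ".fuse"), C, C, k = 1L, bias = TRUE)

  fwdNode <- function(I) {
    d <- dim(I$v)
    H <- d[1]; W <- d[2]
    if (strict && (H %% 2L != 0L || W %% 2L != 0L)) {
      stop("stage resolution not divisible")
    }
    # half-scale branch: ceil halving so the terminal 7x7 stage is defined
    X <- shared$fwd(I)
    f1 <- tBilinear(branches[[1]]$fwd(tBilinear(X, 2L * H, 2L * W)), H, W)
    f2 <- branches[[2]]$fwd(X)
    f3 <- tBilinear(branches[[3]]$fwd(tAdaptiveAvg(X, (H + 1L) %/% 2L,
                                                   (W + 1L) %/% 2L)),
                    H, W)
    fs <- list(f1, f2, f3)
    fsum <- tAdd(tAdd(f1, f2), f3)
    logits <- lapply(1:3, function(i) {
      tOuterCS(catts[[i]]$fwd(fsum), satts[[i]]$fwd(fsum))
    })
    S <- tSoftmax3(logits)
    gated <- tAdd(tAdd(tMul(fs[[1]], S[[1]]), tMul(fs[[2]], S[[2]])),
                  tMul(fs[[3]], S[[3]]))
    out <- tAdd(fuse$fwd(gated), I)
    list(out = out, branchWeights = S)
  }

  structure(list(store = store, ctx = ctx, C = C, fwdNode = fwdNode),
            class = "sodMAM")
}

#' Run a multiscale attention module
#'
#' @param mam module from \code{\link{newMAM}}.
#' @param x numeric array (H, W, C) or (H, W, C, N); H and W must be even so
#'   the half-scale branch is defined.
#' @param withWeights if \code{TRUE}, also return the three softmax branch
#'   weight arrays (they sum to one at every pixel/channel position).
#' @return The output array, same shape as the input; with
#'   \code{withWeights = TRUE} a list with elements \code{out} and
#'   \code{weights}.
#' @export
mamForward <- function(mam, x, withWeights = FALSE) {
  x <- as4d(x)
  checkActivations(x)
  r <- mam$fwdNode(tnode(x))
  if (withWeights) {
    list(out = r$out$v, weights = lapply(r$branchWeights, function(s) s$v))
  } else {
    r$out$v
  }
}

buildEncoder <- function(store, ctx, stageChannels, blocksPerStage,
                         dilations, reduction, inChannels = 3L) {
  nStage <- length(stageChannels)
  stages <- vector("list", nStage)
  cin <- inChannels
  for (s in seq_len(nStage)) {
    C <- stageChannels[s]
    tag <- sprintf("enc.s%d", s)
    entry <- convBnRelu(store, paste0(tag, ".entry"), cin, C, stride = 2L,
                        ctx = ctx)
    extra <- list()
    if (blocksPerStage[s] > 1L) {
      extra <- lapply(seq_len(blocksPerStage[s] - 1L), function(b) {
        convBnRelu(store, sprintf("%s.block%d", tag, b), C, C, ctx = ctx)
      })
    }
    mam <- newMAM(C, dilations, reduction, store, paste0(tag, ".mam"), ctx,
                  strict = FALSE)
    stages[[s]] <- list(entry = entry, extra = extra, mam = mam)
    cin <- C
  }
  fwd <- function(x) {
    out <- vector("list", nStage)
    h <- x
    for (s in seq_len(nStage)) {
      st <- stages[[s]]
      h <- st$entry$fwd(h)
      for (blk in st$extra) h <- blk$fwd(h)
      h <- st$mam$fwdNode(h)$out
      out[[s]] <- h
    }
    out
  }
  list(stages = stages, fwd = fwd)
}
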