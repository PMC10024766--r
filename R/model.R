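# Model assembly: encoder + pyramid-pooled full-scale skip decoder + residual
# refinement, with deterministic seeded initialization.

#' Encoder configuration constructor
#'
#' Defaults follow the lightweight design: limited channel growth
#' (16-32-64-96-128, ending at the 7x7x128 terminal shape for 224x224
#' inputs), dilation rates 1/2/4 for the three attention branches, and a
#' block schedule chosen so the assembled default network's trainable
#' parameters round to 2.1 M.
#'
#' @param stageChannels channels per encoder stage (non-decreasing, last 128).
#' @param blocksPerStage conv blocks per stage.
#' @param dilationRates three branch dilation rates.
#' @param attentionReduction channel-attention bottleneck factor.
#' @return An \code{EncoderConfig}.
#' @export
encoderConfig <- function(stageChannels = c(16L, 32L, 64L, 96L, 128L),
                          blocksPerStage = c(1L, 1L, 1L, 3L, 3L),
                          dilationRates = c(1L, 2L, 4L),
                          attentionReduction = 4L) {
  new("EncoderConfig",
      stageChannels = as.integer(stageChannels),
      blocksPerStage = as.integer(blocksPerStage),
      dilationRates = as.integer(dilationRates),
      attentionReduction = as.integer(attentionReduction))
}

#' Decoder configuration constructor
#'
#' @param stageChannels widths of decoder stages 4..1 (mirror of the encoder).
#' @param ppmBins pyramid pooling bin sizes.
#' @param reduceFraction per-source channel reduction before concatenation.
#' @return A \code{DecoderConfig}.
#' @export
decoderConfig <- function(stageChannels = c(96L, 64L, 32L, 16L),
                          ppmBins = c(1L, 2L, 3L, 6L),
                          reduceFraction = 1 / 4) {
  new("DecoderConfig",
      stageChannels = as.integer(stageChannels),
      ppmBins = as.integer(ppmBins),
      reduceFraction = reduceFraction)
}

#' Model configuration constructor
#'
#' @param encoder an \code{EncoderConfig}.
#' @param decoder a \code{DecoderConfig}.
#' @param rfmFilters refinement-module filter schedule (4, 8, 16, 24, 36).
#' @param seed initialization seed.
#' @return A \code{SODModelConfig}.
#' @export
sodModelConfig <- function(encoder = encoderConfig(),
                           decoder = decoderConfig(),
                           rfmFilters = c(4L, 8L, 16L, 24L, 36L),
                           seed = 1L) {
  new("SODModelConfig", encoder = encoder, decoder = decoder,
      rfmFilters = as.integer(rfmFilters), seed = as.integer(seed))
}

#' Assemble the saliency detection network
#'
#' Builds the full network (encoder with multiscale attention, pyramid-pooled
#' full-scale skip decoder, residual refinement module) with seeded
#' Kaiming-uniform weight initialization (batch-norm gamma 1, beta 0).
#'
#' @param config a \code{SODModelConfig}.
#' @return A \code{SODModel}.
#' @examples
#' cfg <- sodModelConfig(seed = 7L)
#' model <- sodModel(cfg)
#' countParameters(model)
#' @export
sodModel <- function(config = sodModelConfig()) {
  validObject(config)
  validObject(config@encoder)
  validObject(config@decoder)
  engine <- new.env(parent = emptyenv())
  engine$store <- newStore()
  ctx <- new.env(parent = emptyenv())
  ctx$training <- FALSE
  engine$ctx <- ctx
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(config@seed)
  enc <- config@encoder
  engine$encoder <- buildEncoder(engine$store, ctx, enc@stageChannels,
                                 enc@blocksPerStage, enc@dilationRates,
                                 enc@attentionReduction)
  dec <- config@decoder
  engine$decoder <- buildDecoder(engine$store, ctx, enc@stageChannels,
                                 dec@stageChannels, dec@ppmBins,
                                 dec@reduceFraction)
  engine$rfm <- buildRFM(engine$store, ctx, config@rfmFilters)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  new("SODModel", config = config, engine = engine)
}

checkImageInput <- function(x) {
  x <- as4d(x)
  d <- dim(x)
  if (d[1] != 224L || d[2] != 224L) stop("expected 224x224")
  if (d[3] == 1L) x <- x[, , c(1L, 1L, 1L), , drop = FALSE]
  if (dim(x)[3] != 3L) stop("expected 1 or 3 channels")
  checkActivations(x)
  x
}

# Full forward pass on the tape; returns the nodes (used by training).
modelForwardNodes <- function(model, x) {
  xT <- tnode(x)
  feats <- model@engine$encoder$fwd(xT)
  dec <- model@engine$decoder$fwd(feats)
  coarse <- tSigmoid(dec$logits)
  residual <- model@engine$rfm$fwd(coarse)
  refineLogits <- tAdd(dec$logits, residual)
  refined <- tSigmoid(refineLogits)
  list(feats = feats, dec = dec, coarseLogits = dec$logits, coarse = coarse,
       residual = residual, refineLogits = refineLogits, refined = refined)
}

#' Run the encoder
#'
#' @param model a \code{SODModel}.
#' @param image numeric array 224x224x3 (or 224x224, replicated to 3
#'   channels), values typically in \[0, 1\]; an optional 4th batch
#'   dimension is accepted.
#' @return List of 5 stage feature arrays at spatial sizes 112, 56, 28, 14, 7.
#' @export
encoderForward <- function(model, image) {
  x <- checkImageInput(image)
  feats <- model@engine$encoder$fwd(tnode(x))
  lapply(feats, function(f) f$v)
}

#' Run the decoder on encoder features
#'
#' @param model a \code{SODModel}.
#' @param image input image as in \code{\link{encoderForward}}.
#' @return List with the pyramid-pooled feature \code{ppm}, the four stage
#'   outputs \code{de4}..\code{de1} and the coarse prediction \code{logits}
#'   at 224x224.
#' @export
decoderForward <- function(model, image) {
  x <- checkImageInput(image)
  feats <- model@engine$encoder$fwd(tnode(x))
  dec <- model@engine$decoder$fwd(feats)
  list(ppm = dec$ppm$v,
       stages = lapply(dec$stages, function(s) s$v),
       logits = dec$logits$v)
}

#' Run the refinement module on a coarse saliency map
#'
#' @param model a \code{SODModel}.
#' @param coarse a \code{SaliencyMap} in probability space, or a 224x224
#'   numeric matrix in \[0, 1\].
#' @return A \code{SaliencyMap} in logit space holding the residual.
#' @export
rfmForward <- function(model, coarse) {
  m <- if (is(coarse, "SaliencyMap")) {
    if (coarse@space != "probability") stop("coarse map must be probability")
    coarse@data
  } else coarse
  if (!identical(dim(m), c(224L, 224L))) stop("expected 224x224")
  x <- array(m, c(224L, 224L, 1L, 1L))
  res <- model@engine$rfm$fwd(tnode(x))
  saliencyMap(matrix(res$v, 224L, 224L), space = "logit")
}

#' Predict coarse and refined saliency maps
#'
#' The refined map is formed in logit space: the refinement residual is added
#' to the coarse prediction logits before the final sigmoid, so a zeroed
#' refinement module leaves the coarse map exactly unchanged and the output
#' always stays in \[0, 1\].
#'
#' @param model a \code{SODModel}.
#' @param image input image as in \code{\link{encoderForward}} (single image).
#' @return List of two \code{SaliencyMap}s, \code{coarse} and \code{refined}.
#' @export
predictSaliency <- function(model, image) {
  x <- checkImageInput(image)
  if (dim(x)[4] != 1L) stop("predictSaliency takes a single image")
  r <- modelForwardNodes(model, x)
  list(coarse = saliencyMap(matrix(r$coarse$v, 224L, 224L)),
       refined = saliencyMap(matrix(r$refined$v, 224L, 224L)))
}

#' Count trainable parameters
#'
#' @param model a \code{SODModel}.
#' @param units \code{"millions"} (rounded to one decimal) or \code{"raw"}.
#' @return Parameter count.
#' @export
countParameters <- function(model, units = c("millions", "raw")) {
  units <- match.arg(units)
  n <- storeParamCount(model@engine$store)
  if (units == "millions") round(n / 1e6, 1) else n
}

setMethod("show", "SODModel", function(object) {
  enc <- object@config@encoder
  cat("SODModel (lightweight salient-object detection network)\n")
  cat("  encoder stages:",
      paste(enc@stageChannels, collapse = "-"),
      sprintf("(blocks %s, dilations %s)\n",
              paste(enc@blocksPerStage, collapse = "/"),
              paste(enc@dilationRates, collapse = "/")))
  cat("  decoder stages:",
      paste(object@config@decoder@stageChannels, collapse = "-"),
      sprintf("(pyramid bins %s)\n",
              paste(object@config@decoder@ppmBins, collapse = "/")))
  cat("  refinement filters:",
      paste(object@config@rfmFilters, collapse = "-"), "\n")
  cat(sprintf("  trainable parameters: %d (%.1f M)\n",
              as.integer(countParameters(object, "raw")),
              countParameters(object)))
})

#' Extract the model configuration
#'
#' @param model a \code{SODModel}.
#' @return The \code{SODModelConfig}.
#' @export
modelConfig <- function(model) model@config
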