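#' @import methods
NULL

#' Encoder configuration
#'
#' Five-stage encoder widths and depths plus the multiscale-attention branch
#' dilations. Stage widths must be non-decreasing and end at 128 so the
#' terminal feature map of a 224x224 input is 7x7x128; exactly three branch
#' dilations are required (the 2x / 1x / 0.5x scale branches).
#'
#' @slot stageChannels integer(5), channels per stage.
#' @slot blocksPerStage integer(5), conv blocks per stage (the documented
#'   knob for the trainable-parameter budget).
#' @slot dilationRates integer(3), dilation per attention branch.
#' @slot attentionReduction integer(1), channel-attention bottleneck factor.
#' @export
setClass("EncoderConfig", representation(
  stageChannels = "integer",
  blocksPerStage = "integer",
  dilationRates = "integer",
  attentionReduction = "integer"
))

setValidity("EncoderConfig", function(object) {
  sc <- object@stageChannels
  msg <- character()
  if (length(sc) != 5L || any(sc < 1L)) {
    msg <- c(msg, "stageChannels must be 5 positive integers")
  } else {
    if (is.unsorted(sc)) msg <- c(msg, "stageChannels must be non-decreasing")
    if (sc[5] != 128L) msg <- c(msg, "final stage must have 128 channels")
  }
  if (length(object@blocksPerStage) != 5L || any(object@blocksPerStage < 1L)) {
    msg <- c(msg, "blocksPerStage must be 5 positive integers")
  }
  if (length(object@dilationRates) != 3L || any(object@dilationRates < 1L)) {
    msg <- c(msg, "dilationRates must be 3 positive integers")
  }
  if (object@attentionReduction < 1L) {
    msg <- c(msg, "attentionReduction must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Decoder configuration
#'
#' @slot stageChannels integer(4), widths of decoder stages 4..1.
#' @slot ppmBins integer vector of pyramid pooling bin sizes.
#' @slot reduceFraction numeric(1), channel reduction applied to each
#'   skip-connection source before concatenation (default 1/4).
#' @export
setClass("DecoderConfig", representation(
  stageChannels = "integer",
  ppmBins = "integer",
  reduceFraction = "numeric"
))

setValidity("DecoderConfig", function(object) {
  msg <- character()
  if (length(object@stageChannels) != 4L || any(object@stageChannels < 1L)) {
    msg <- c(msg, "stageChannels must be 4 positive integers")
  }
  if (length(object@ppmBins) < 1L || any(object@ppmBins < 1L)) {
    msg <- c(msg, "ppmBins must be positive integers")
  }
  if (object@reduceFraction <= 0 || object@reduceFraction > 1) {
    msg <- c(msg, "reduceFraction must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Full model configuration
#'
#' @slot encoder an \code{EncoderConfig}.
#' @slot decoder a \code{DecoderConfig}.
#' @slot rfmFilters integer(5), refinement-module encoder filter schedule.
#' @slot seed integer(1), seed for weight initialization.
#' @export
setClass("SODModelConfig", representation(
  encoder = "EncoderConfig",
  decoder = "DecoderConfig",
  rfmFilters = "integer",
  seed = "integer"
))

setValidity("SODModelConfig", function(object) {
  msg <- character()
  if (length(object@rfmFilters) != 5L || any(object@rfmFilters < 1L)) {
    msg <- c(msg, "rfmFilters must be 5 positive integers")
  }
  if (length(object@seed) != 1L) msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Assembled saliency detection model
#'
#' Holds the configuration and the compute engine (parameter store, forward
#' closures). Create with \code{\link{sodModel}}.
#'
#' @slot config the \code{SODModelConfig} the network was built from.
#' @slot engine environment with the parameter store and forward closures.
#' @export
setClass("SODModel", representation(
  config = "SODModelConfig",
  engine = "environment"
))

#' Single-channel saliency map
#'
#' @slot data numeric matrix; in \code{"probability"} space values lie in
#'   \[0, 1\], in \code{"logit"} space they are unbounded.
#' @slot space either \code{"probability"} or \code{"logit"}.
#' @export
setClass("SaliencyMap", representation(
  data = "matrix",
  space = "character"
))

setValidity("SaliencyMap", function(object) {
  msg <- character()
  if (!object@space %in% c("probability", "logit")) {
    msg <- c(msg, "space must be 'probability' or 'logit'")
  }
  if (!all(is.finite(object@data))) msg <- c(msg, "non-finite map values")
  if (identical(object@space, "probability") &&
      (min(object@data) < 0 || max(object@data) > 1)) {
    msg <- c(msg, "probability-space values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Per-image and aggregate saliency metrics
#'
#' @slot perImage data.frame with columns \code{id}, \code{fbetaMax},
#'   \code{fWeighted}, \code{mae}.
#' @slot aggregate named numeric vector of column means.
#' @slot unmatched character vector of stems excluded for missing pairs.
#' @export
setClass("MetricReport", representation(
  perImage = "data.frame",
  aggregate = "numeric",
  unmatched = "character"
))

#' @describeIn SaliencyMap construct a saliency map.
#' @param data numeric matrix.
#' @param space value space of \code{data}.
#' @export
saliencyMap <- function(data, space = c("probability", "logit")) {
  new("SaliencyMap", data = as.matrix(data), space = match.arg(space))
}

#' @describeIn SaliencyMap map values.
#' @param x a \code{SaliencyMap}.
#' @export
mapData <- function(x) x@data

#' @describeIn SaliencyMap value space.
#' @export
mapSpace <- function(x) x@space

setMethod("show", "SaliencyMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("SaliencyMap %dx%d (%s space), range [%.3f, %.3f]\n",
              d[1], d[2], object@space, min(object@data), max(object@data)))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: %d image(s)\n", nrow(object@perImage)))
  ag <- object@aggregate
  cat(sprintf("  mean maxF: %.4f  mean wF: %.4f  mean MAE: %.4f\n",
              ag[["fbetaMax"]], ag[["fWeighted"]], ag[["mae"]]))
  if (length(object@unmatched)) {
    cat("  unmatched stems:", paste(object@unmatched, collapse = ", "), "\n")
  }
})
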