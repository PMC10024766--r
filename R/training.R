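# Training: Adam with a cosine-annealed learning rate stepped per epoch,
# paired random horizontal flipping, and binary cross-entropy supervision on
# both the coarse and the refined prediction.

#' Training configuration
#'
#' Defaults follow the training recipe: Adam with initial learning rate
#' 3e-4, cosine annealing to zero over 60 epochs, random horizontal flipping
#' with probability 1/2. Batch size 16 and equal coarse/refine loss weights
#' are the package's own choices.
#'
#' @param lr0 initial learning rate.
#' @param epochs number of training epochs.
#' @param batchSize minibatch size.
#' @param flipProb probability of flipping an (image, mask) pair.
#' @param seed seed controlling initialization-independent training
#'   randomness (shuffling, flips).
#' @param lossWeights named numeric vector, weights of the coarse and
#'   refined BCE terms.
#' @return A validated configuration list.
#' @export
trainConfig <- function(lr0 = 3e-4, epochs = 60L, batchSize = 16L,
                        flipProb = 0.5, seed = 1L,
                        lossWeights = c(coarse = 1, refine = 1)) {
  if (lr0 <= 0) stop("lr0 must be positive")
  if (epochs < 1L) stop("epochs must be at least 1")
  if (batchSize < 1L) stop("batchSize must be at least 1")
  if (flipProb < 0 || flipProb > 1) stop("flipProb must lie in [0, 1]")
  if (length(lossWeights) != 2L) stop("lossWeights must have two entries")
  list(lr0 = lr0, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), flipProb = flipProb,
       seed = as.integer(seed),
       lossWeights = c(coarse = unname(lossWeights[1]),
                       refine = unname(lossWeights[2])))
}

#' Cosine-annealed learning rate
#'
#' \eqn{lr(e) = lr_0 \cdot \tfrac12 (1 + \cos(\pi e / E))}: starts at
#' \code{lr0} and decays to 0 at epoch \code{E}.
#'
#' @param epoch epoch number in \code{0..epochs}.
#' @param cfg configuration from \code{\link{trainConfig}}.
#' @return The learning rate.
#' @export
cosineLR <- function(epoch, cfg = trainConfig()) {
  if (epoch < 0 || epoch > cfg$epochs) stop("epoch out of range")
  cfg$lr0 * 0.5 * (1 + cos(pi * epoch / cfg$epochs))
}

#' Paired random horizontal flip
#'
#' With probability \code{prob} mirrors image and mask together (columns
#' reversed); otherwise returns them unchanged. Draws one uniform variate
#' from the current RNG stream.
#'
#' @param image array (H, W, C).
#' @param mask matrix (H, W).
#' @param prob flip probability.
#' @return list with \code{image}, \code{mask} and logical \code{flipped}.
#' @export
augmentFlip <- function(image, mask, prob = 0.5) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2])) {
    stop("image/mask shape mismatch")
  }
  flipped <- stats::runif(1) < prob
  if (flipped) {
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  list(image = image, mask = mask, flipped = flipped)
}

#' Binary cross-entropy supervision on coarse and refined maps
#'
#' \code{w_c BCE(coarse, y) + w_r BCE(refine, y)} with predictions clipped to
#' \code{[eps, 1 - eps]}. Zero (up to the clipping floor) iff both
#' predictions equal a binary target.
#'
#' @param coarse,refine predicted maps in \[0, 1\] (matrix or
#'   \code{SaliencyMap}).
#' @param y binary target of the same shape.
#' @param weights coarse/refine term weights.
#' @param eps clipping floor.
#' @return The scalar loss.
#' @export
bceLoss <- function(coarse, refine, y, weights = c(coarse = 1, refine = 1),
                    eps = 1e-7) {
  coarse <- asMapMatrix(coarse)
  refine <- asMapMatrix(refine)
  if (!identical(dim(coarse), dim(y)) || !identical(dim(refine), dim(y))) {
    stop("prediction/target shape mismatch")
  }
  bce <- function(p) {
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  unname(weights[1]) * bce(coarse) + unname(weights[2]) * bce(refine)
}

newAdam <- function(beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$beta1 <- beta1
  opt$beta2 <- beta2
  opt$eps <- eps
  opt
}

adamStep <- function(opt, params, lr) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(p$m)) {
      p$m <- g * 0
      p$u <- g * 0
    }
    p$m <- opt$beta1 * p$m + (1 - opt$beta1) * g
    p$u <- opt$beta2 * p$u + (1 - opt$beta2) * g * g
    p$v <- p$v - lr * (p$m / c1) / (sqrt(p$u / c2) + opt$eps)
    p$grad <- NULL
  }
  invisible(opt)
}

resolveSamples <- function(dataset) {
  if (inherits(dataset, "sodDatasetIndex")) {
    lapply(seq_len(nrow(dataset$pairs)), function(i) getSample(dataset, i))
  } else if (is.list(dataset) &&
             all(vapply(dataset, function(s) {
               is.list(s) && !is.null(s$image) && !is.null(s$mask)
             }, logical(1)))) {
    dataset
  } else {
    stop("dataset must be a sodDatasetIndex or a list of image/mask pairs")
  }
}

#' Train the model
#'
#' Runs \code{epochs} passes of minibatch Adam over the dataset with the
#' cosine learning-rate schedule evaluated per epoch and paired random
#' flipping. Fully deterministic given the configuration seeds. Logs the
#' learning rate, mean loss and training-set MAE (refined map, training-mode
#' forward) per epoch.
#'
#' @param model a \code{SODModel} (modified in place and returned).
#' @param dataset a \code{sodDatasetIndex} or list of samples with
#'   \code{$image} (224 x 224 x 3) and \code{$mask} (224 x 224, binary).
#' @param cfg configuration from \code{\link{trainConfig}}.
#' @param checkpointPath optional path for the final checkpoint.
#' @param verbose print a line per epoch.
#' @param maxSteps optional cap on the total number of optimizer steps.
#' @param stopAtTrainMAE optional early-stop target on the epoch-mean
#'   training MAE.
#' @return list with the trained \code{model}, the per-epoch \code{log}
#'   (data.frame epoch / lr / meanLoss / trainMAE) and \code{checkpoint}
#'   (path or NULL).
#' @export
trainModel <- function(model, dataset, cfg = trainConfig(),
                       checkpointPath = NULL, verbose = FALSE,
                       maxSteps = NULL, stopAtTrainMAE = NULL) {
  samples <- resolveSamples(dataset)
  n <- length(samples)
  if (n == 0L) stop("empty dataset")
  engine <- model@engine
  params <- engine$store$params
  opt <- newAdam()
  logRows <- vector("list", cfg$epochs)
  steps <- 0L
  done <- FALSE
  withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      if (done) break
      lr <- cosineLR(epoch, cfg)
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batchSize)
      losses <- numeric(0)
      maes <- numeric(0)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + cfg$batchSize - 1L, n)]
        B <- length(idx)
        xb <- array(0, c(224L, 224L, 3L, B))
        yb <- array(0, c(224L, 224L, 1L, B))
        for (b in seq_len(B)) {
          sm <- samples[[idx[b]]]
          a <- augmentFlip(sm$image, sm$mask, cfg$flipProb)
          xb[, , , b] <- a$image
          yb[, , 1, b] <- a$mask
        }
        engine$ctx$training <- TRUE
        fw <- modelForwardNodes(model, xb)
        lossC <- tBceLogits(fw$coarseLogits, yb)
        lossR <- tBceLogits(fw$refineLogits, yb)
        loss <- tAddScalarOf(tScale(lossC, cfg$lossWeights[["coarse"]]),
                             tScale(lossR, cfg$lossWeights[["refine"]]))
        if (!is.finite(loss$v)) {
          stop(sprintf("non-finite loss at epoch %d (coarse %.4g, refine %.4g)",
                       epoch, lossC$v, lossR$v))
        }
        backwardPass(loss, seed = 1)
        adamStep(opt, params, lr)
        losses <- c(losses, loss$v)
        maes <- c(maes, mean(abs(fw$refined$v - yb)))
        steps <- steps + 1L
        rm(fw, loss, lossC, lossR)
        invisible(gc(FALSE))   # the tape is large; keep the heap flat
        if (!is.null(maxSteps) && steps >= maxSteps) {
          done <- TRUE
          break
        }
      }
      engine$ctx$training <- FALSE
      logRows[[epoch + 1L]] <- data.frame(
        epoch = epoch, lr = lr, meanLoss = mean(losses),
        trainMAE = mean(maes))
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  mae %.4f",
                        epoch, lr, mean(losses), mean(maes)))
      }
      if (!is.null(stopAtTrainMAE) && mean(maes) < stopAtTrainMAE) {
        done <- TRUE
      }
    }
  })
  log <- do.call(rbind, logRows)
  ckpt <- NULL
  if (!is.null(checkpointPath)) {
    ckpt <- saveCheckpoint(model, checkpointPath)
  }
  list(model = model, log = log, checkpoint = ckpt)
}

#' Mean absolute error of the model on a set of samples
#'
#' Evaluation-mode forward (batch-norm running statistics) on each sample.
#'
#' @param model a \code{SODModel}.
#' @param samples list of samples with \code{$image} and \code{$mask}.
#' @param which \code{"refined"} or \code{"coarse"} map.
#' @return Mean MAE over the samples.
#' @export
modelMAE <- function(model, samples, which = c("refined", "coarse")) {
  which <- match.arg(which)
  samples <- resolveSamples(samples)
  mean(vapply(samples, function(s) {
    p <- predictSaliency(model, s$image)[[which]]
    saliencyMAE(p, s$mask)
  }, numeric(1)))
}
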