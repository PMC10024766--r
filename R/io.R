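# Image and dataset I/O: PNG readers/writers, DUTS-style directory pairing
# (images/ + masks/ matched by filename stem), and single-file checkpoints.

#' Read an image file as a 224x224x3 array in \[0, 1\]
#'
#' Alpha channels are dropped, grayscale images are replicated to three
#' channels, and the image is bilinearly resized to the network input size.
#'
#' @param path PNG file path.
#' @param size target side length (default 224).
#' @return numeric array (size, size, 3).
#' @export
loadImage <- function(path, size = 224L) {
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) img <- img[, , 1L, drop = FALSE]  # gray + alpha
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  d <- dim(img)
  if (d[1] != size || d[2] != size) {
    dim(img) <- c(d[1], d[2], 3L, 1L)
    img <- cppBilinearForward(img, size, size)
    dim(img) <- c(size, size, 3L)
  }
  img
}

#' Read a ground-truth mask PNG as a binary matrix
#'
#' Grayscale values of at least 128/255 become foreground (benchmark masks
#' are often anti-aliased). Resizing, when needed, is nearest-neighbor so the
#' mask stays binary.
#'
#' @param path PNG file path.
#' @param size optional target side length; \code{NULL} keeps the native size.
#' @return matrix over \{0, 1\}.
#' @export
loadMask <- function(path, size = NULL) {
  img <- png::readPNG(path)
  if (!is.matrix(img)) img <- img[, , 1L]
  if (!is.null(size) && (nrow(img) != size || ncol(img) != size)) {
    ri <- pmin(pmax(ceiling(seq_len(size) / size * nrow(img)), 1L), nrow(img))
    ci <- pmin(pmax(ceiling(seq_len(size) / size * ncol(img)), 1L), ncol(img))
    img <- img[ri, ci]
  }
  (img >= 128 / 255) * 1
}

#' Read a saliency prediction PNG as a matrix in \[0, 1\]
#'
#' @param path PNG file path (8-bit grayscale).
#' @return numeric matrix in \[0, 1\].
#' @export
loadSaliencyMap <- function(path) {
  img <- png::readPNG(path)
  if (!is.matrix(img)) img <- img[, , 1L]
  img
}

#' Write a saliency map as an 8-bit grayscale PNG
#'
#' Pixel values are \code{round(255 p)}, so a save/load round trip is exact
#' for binary maps and within 1/255 per pixel otherwise.
#'
#' @param m a \code{SaliencyMap} in probability space or a matrix in \[0, 1\].
#' @param path output file path.
#' @export
saveSaliencyMap <- function(m, path) {
  m <- asMapMatrix(m)
  if (min(m) < 0 || max(m) > 1) stop("map must lie in [0, 1]")
  png::writePNG(round(255 * m) / 255, path)
  invisible(path)
}

#' Index a paired image/mask dataset directory
#'
#' Expects \code{root/images/} and \code{root/masks/}; pairs files by
#' filename stem, sorted lexicographically. Orphan stems are excluded with a
#' warning and listed in the result.
#'
#' @param root dataset directory.
#' @return A list with \code{pairs} (data.frame of stem, imagePath,
#'   maskPath), \code{unmatched} and \code{root}, class \code{sodDatasetIndex}.
#' @export
loadDatasetDir <- function(root) {
  imgDir <- file.path(root, "images")
  mskDir <- file.path(root, "masks")
  if (!dir.exists(imgDir) || !dir.exists(mskDir)) {
    stop("dataset root must contain images/ and masks/")
  }
  lst <- function(d) {
    f <- sort(list.files(d, pattern = "\\.(png|PNG|jpg|jpeg|JPG)$"))
    stats::setNames(file.path(d, f), sub("\\.[^.]+$", "", f))
  }
  imgs <- lst(imgDir)
  msks <- lst(mskDir)
  common <- sort(intersect(names(imgs), names(msks)))
  unmatched <- sort(setdiff(union(names(imgs), names(msks)), common))
  if (length(unmatched)) {
    warning("unmatched stems excluded: ", paste(unmatched, collapse = ", "))
  }
  if (anyDuplicated(names(imgs)) || anyDuplicated(names(msks))) {
    stop("duplicate stems in dataset")
  }
  structure(list(
    pairs = data.frame(stem = common,
                       imagePath = unname(imgs[common]),
                       maskPath = unname(msks[common]),
                       stringsAsFactors = FALSE),
    unmatched = unmatched,
    root = root
  ), class = "sodDatasetIndex")
}

#' Load one indexed sample as network-ready arrays
#'
#' @param index a \code{sodDatasetIndex}.
#' @param i sample number.
#' @param size network input side length.
#' @return list with \code{image} (size x size x 3) and \code{mask}
#'   (size x size binary matrix).
#' @export
getSample <- function(index, i, size = 224L) {
  list(image = loadImage(index$pairs$imagePath[i], size),
       mask = loadMask(index$pairs$maskPath[i], size))
}

#' Save model weights to a single checkpoint file
#'
#' The checkpoint stores the model configuration, every trainable parameter
#' (tagged, in construction order) and the batch-norm running statistics.
#'
#' @param model a \code{SODModel}.
#' @param path output file.
#' @export
saveCheckpoint <- function(model, path) {
  store <- model@engine$store
  cfg <- model@config
  obj <- list(
    format = "liteSOD-checkpoint-1",
    config = list(
      encoder = list(stageChannels = cfg@encoder@stageChannels,
                     blocksPerStage = cfg@encoder@blocksPerStage,
                     dilationRates = cfg@encoder@dilationRates,
                     attentionReduction = cfg@encoder@attentionReduction),
      decoder = list(stageChannels = cfg@decoder@stageChannels,
                     ppmBins = cfg@decoder@ppmBins,
                     reduceFraction = cfg@decoder@reduceFraction),
      rfmFilters = cfg@rfmFilters,
      seed = cfg@seed
    ),
    tags = store$tags,
    params = lapply(store$params, function(p) p$v),
    bn = lapply(store$bnStates, function(st) list(rm = st$rm, rv = st$rv))
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Restore a model from a checkpoint file
#'
#' @param path checkpoint written by \code{\link{saveCheckpoint}}.
#' @return A \code{SODModel} with the stored weights.
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "liteSOD-checkpoint-1")) {
    stop("not a liteSOD checkpoint")
  }
  cfg <- sodModelConfig(
    encoder = encoderConfig(obj$config$encoder$stageChannels,
                            obj$config$encoder$blocksPerStage,
                            obj$config$encoder$dilationRates,
                            obj$config$encoder$attentionReduction),
    decoder = decoderConfig(obj$config$decoder$stageChannels,
                            obj$config$decoder$ppmBins,
                            obj$config$decoder$reduceFraction),
    rfmFilters = obj$config$rfmFilters,
    seed = obj$config$seed
  )
  model <- sodModel(cfg)
  store <- model@engine$store
  if (!identical(store$tags, obj$tags)) stop("checkpoint/model tag mismatch")
  for (i in seq_along(store$params)) {
    p <- store$params[[i]]
    v <- obj$params[[i]]
    if (length(p$v) != length(v)) stop("checkpoint parameter size mismatch")
    dim(v) <- dim(p$v)
    p$v <- v
  }
  for (tag in names(obj$bn)) {
    st <- store$bnStates[[tag]]
    if (is.null(st)) stop("checkpoint batch-norm state mismatch")
    st$rm <- obj$bn[[tag]]$rm
    st$rv <- obj$bn[[tag]]$rv
  }
  model
}
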