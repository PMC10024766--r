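# Saliency evaluation metrics: MAE, threshold-swept maximum F-measure, and
# the weighted F-measure that discounts errors by their spatial dependency on
# the foreground (Gaussian-smoothed error inside the object, distance-decayed
# importance outside it).

#' Metric configuration
#'
#' @param beta2F beta^2 of the plain F-measure (default 0.3, the saliency
#'   convention emphasizing precision).
#' @param beta2W beta^2 of the weighted F-measure (default 1).
#' @param nThresholds number of evenly spaced binarization thresholds for the
#'   maximum F-measure sweep.
#' @param sigmaW standard deviation (pixels) of the 7x7 Gaussian dependency
#'   kernel of the weighted F-measure.
#' @param alphaW decay constant of the background importance weighting
#'   \code{2 - exp(alphaW * d)}; default \code{log(0.5)/5} halves the
#'   discount five pixels from the object.
#' @return A list of validated metric settings.
#' @export
metricConfig <- function(beta2F = 0.3, beta2W = 1.0, nThresholds = 256L,
                         sigmaW = 5.0, alphaW = log(0.5) / 5) {
  if (beta2F <= 0 || beta2W <= 0) stop("beta2 values must be positive")
  if (nThresholds < 2L) stop("need at least 2 thresholds")
  list(beta2F = beta2F, beta2W = beta2W, nThresholds = as.integer(nThresholds),
       sigmaW = sigmaW, alphaW = alphaW)
}

checkPair <- function(p, y) {
  if (!identical(dim(p), dim(y))) stop("prediction/mask shape mismatch")
  if (!all(y %in% c(0, 1))) stop("mask must be binary")
  invisible(NULL)
}

asMapMatrix <- function(p) {
  if (is(p, "SaliencyMap")) {
    if (p@space != "probability") stop("map must be in probability space")
    p@data
  } else {
    as.matrix(p)
  }
}

#' Mean absolute error between a saliency map and a binary mask
#'
#' @param p predicted map (matrix in \[0, 1\] or \code{SaliencyMap}).
#' @param y binary ground-truth matrix of the same shape.
#' @return MAE in \[0, 1\].
#' @examples
#' saliencyMAE(matrix(c(0.5, 1, 0.25, 0), 2), matrix(c(1, 1, 0, 0), 2))
#' @export
saliencyMAE <- function(p, y) {
  p <- asMapMatrix(p)
  checkPair(p, y)
  mean(abs(p - y))
}

#' F-measure from precision and recall
#'
#' \eqn{F = (1 + \beta^2) P R / (\beta^2 P + R)}; returns 0 when the
#' denominator vanishes.
#'
#' @param precision,recall values in \[0, 1\].
#' @param beta2 positive weight \eqn{\beta^2} (0.3 emphasizes precision).
#' @return The F value.
#' @export
fMeasure <- function(precision, recall, beta2 = 0.3) {
  if (beta2 <= 0) stop("beta2 must be positive")
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1)) {
    stop("precision and recall must lie in [0, 1]")
  }
  den <- beta2 * precision + recall
  ifelse(den == 0, 0, (1 + beta2) * precision * recall / den)
}

#' Maximum F-measure over binarization thresholds
#'
#' Binarizes the prediction at \code{nThresholds} evenly spaced thresholds in
#' \[0, 1\] (strict \code{>}), computes precision/recall against the mask at
#' each, and returns the maximum F-measure.
#'
#' @inheritParams saliencyMAE
#' @param cfg settings from \code{\link{metricConfig}}.
#' @param adaptive if \code{TRUE}, use the single adaptive threshold
#'   (twice the map mean, clipped to 1) instead of the sweep.
#' @return Maximum (or adaptive) F-measure in \[0, 1\].
#' @export
maxFMeasure <- function(p, y, cfg = metricConfig(), adaptive = FALSE) {
  p <- asMapMatrix(p)
  checkPair(p, y)
  nPos <- sum(y)
  if (nPos == 0) stop("undefined recall")
  thr <- if (adaptive) {
    min(2 * mean(p), 1)
  } else {
    seq(0, 1, length.out = cfg$nThresholds)
  }
  best <- 0
  for (t in thr) {
    pred <- p > t
    tp <- sum(pred & y == 1)
    npred <- sum(pred)
    prec <- if (npred == 0) 0 else tp / npred
    rec <- tp / nPos
    f <- fMeasure(prec, rec, cfg$beta2F)
    if (f > best) best <- f
  }
  best
}

gaussianKernel <- function(size = 7L, sigma = 5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Weighted F-measure
#'
#' Error-map based F-measure that corrects the interpolation, dependency and
#' equal-importance flaws of the plain measure: the absolute error map is
#' smoothed within the foreground by a Gaussian dependency kernel (7x7,
#' standard deviation \code{sigmaW}), background errors are discounted by
#' \code{2 - exp(alphaW * d)} with \code{d} the Euclidean distance to the
#' nearest foreground pixel, and weighted precision/recall are combined with
#' \code{beta2W}.
#'
#' @inheritParams maxFMeasure
#' @return Weighted F-measure in \[0, 1\].
#' @export
weightedFbeta <- function(p, y, cfg = metricConfig()) {
  p <- asMapMatrix(p)
  checkPair(p, y)
  fg <- y == 1
  if (!any(fg)) stop("undefined recall")
  E <- abs(p - y)
  bg <- !fg
  dt <- cppDistanceTransform(fg)
  Et <- E
  Et[bg] <- E[dt$index[bg]]      # carry the nearest foreground error outward
  EA <- cppFilter2Zero(Et, gaussianKernel(7L, cfg$sigmaW))
  minE <- E
  sel <- fg & (EA < E)
  minE[sel] <- EA[sel]
  B <- matrix(1, nrow(y), ncol(y))
  B[bg] <- 2 - exp(cfg$alphaW * dt$dist[bg])
  Ew <- minE * B
  eps <- .Machine$double.eps
  TPw <- sum(fg) - sum(Ew[fg])
  FPw <- sum(Ew[bg])
  R <- 1 - mean(Ew[fg])
  P <- TPw / (TPw + FPw + eps)
  if (R < 0) R <- 0
  if (P < 0) P <- 0
  (1 + cfg$beta2W) * P * R / (cfg$beta2W * P + R + eps)
}

#' Evaluate a directory of predictions against ground-truth masks
#'
#' Pairs files by filename stem (sorted lexicographically), computes the
#' maximum F-measure, weighted F-measure and MAE per image, and aggregates
#' them by arithmetic mean. Unmatched stems are reported and excluded with a
#' warning.
#'
#' @param predDir directory of 8-bit grayscale prediction PNGs.
#' @param maskDir directory of ground-truth mask PNGs (thresholded at 128).
#' @param cfg settings from \code{\link{metricConfig}}.
#' @return A \code{MetricReport}.
#' @export
evaluateDataset <- function(predDir, maskDir, cfg = metricConfig()) {
  stemsOf <- function(d) {
    f <- sort(list.files(d, pattern = "\\.(png|PNG)$"))
    stats::setNames(file.path(d, f), sub("\\.[^.]+$", "", f))
  }
  preds <- stemsOf(predDir)
  masks <- stemsOf(maskDir)
  common <- sort(intersect(names(preds), names(masks)))
  unmatched <- sort(setdiff(union(names(preds), names(masks)), common))
  if (length(unmatched)) {
    warning("unmatched stems excluded: ", paste(unmatched, collapse = ", "))
  }
  if (!length(common)) stop("no matched prediction/mask pairs")
  rows <- lapply(common, function(s) {
    p <- loadSaliencyMap(preds[[s]])
    y <- loadMask(masks[[s]])
    data.frame(id = s,
               fbetaMax = maxFMeasure(p, y, cfg),
               fWeighted = weightedFbeta(p, y, cfg),
               mae = saliencyMAE(p, y),
               stringsAsFactors = FALSE)
  })
  perImage <- do.call(rbind, rows)
  agg <- c(fbetaMax = mean(perImage$fbetaMax),
           fWeighted = mean(perImage$fWeighted),
           mae = mean(perImage$mae))
  new("MetricReport", perImage = perImage, aggregate = agg,
      unmatched = unmatched)
}

#' Arithmetic mean of benchmark table values
#'
#' Convenience for averaging a row of per-dataset scores, reported to three
#' decimals as benchmark tables print them.
#'
#' @param values non-empty numeric vector.
#' @return The mean rounded to 3 decimals.
#' @examples
#' tableAverage(c(0.699, 0.864, 0.752, 0.854, 0.726, 0.754))
#' @export
tableAverage <- function(values) {
  if (!length(values)) stop("empty value list")
  round(mean(values), 3)
}

#' Published benchmark scores of lightweight and classical saliency models
#'
#' Per-dataset weighted F-measure and MAE of representative salient-object
#' detection methods on six public benchmarks (SOD, ECSSD, PASCAL-S, HKU-IS,
#' DUT-OMRON, DUTS-TE), together with each model's trainable-parameter count
#' in millions, as reported by the respective publications. Used for
#' parameter/accuracy trade-off arithmetic.
#'
#' @return A data.frame with one row per method, columns \code{method},
#'   \code{params} and \code{<dataset>.fw} / \code{<dataset>.mae}.
#' @export
benchmarkTable <- function() {
  datasets <- c("SOD", "ECSSD", "PASCALS", "HKUIS", "DUTOMRON", "DUTSTE")
  fw <- rbind(
    RFCN    = c(0.581, 0.698, 0.624, 0.680, 0.524, 0.585),
    DSS     = c(0.698, 0.835, 0.718, 0.821, 0.643, 0.701),
    PiCANet = c(0.721, 0.865, 0.781, 0.847, 0.691, 0.748),
    BASNet  = c(0.728, 0.903, 0.792, 0.889, 0.750, 0.802),
    U2Net   = c(0.748, 0.910, 0.797, 0.890, 0.757, 0.804),
    HVPNet  = c(0.687, 0.852, 0.742, 0.837, 0.696, 0.727),
    SAMNet  = c(0.686, 0.855, 0.734, 0.837, 0.699, 0.729),
    Ours    = c(0.699, 0.864, 0.752, 0.854, 0.726, 0.754))
  mae <- rbind(
    RFCN    = c(0.168, 0.107, 0.132, 0.089, 0.110, 0.090),
    DSS     = c(0.118, 0.052, 0.080, 0.039, 0.074, 0.064),
    PiCANet = c(0.108, 0.047, 0.088, 0.042, 0.068, 0.054),
    BASNet  = c(0.114, 0.037, 0.076, 0.032, 0.056, 0.047),
    U2Net   = c(0.108, 0.033, 0.074, 0.031, 0.054, 0.044),
    HVPNet  = c(0.123, 0.053, 0.090, 0.045, 0.064, 0.057),
    SAMNet  = c(0.123, 0.053, 0.092, 0.045, 0.065, 0.058),
    Ours    = c(0.122, 0.050, 0.089, 0.041, 0.061, 0.054))
  params <- c(RFCN = 134.69, DSS = 62.23, PiCANet = 32.85, BASNet = 87.06,
              U2Net = 41.97, HVPNet = 1.23, SAMNet = 1.33, Ours = 2.1)
  out <- data.frame(method = rownames(fw), params = params[rownames(fw)],
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(fw) <- paste0(datasets, ".fw")
  colnames(mae) <- paste0(datasets, ".mae")
  cbind(out, as.data.frame(fw, row.names = FALSE),
        as.data.frame(mae, row.names = FALSE))
}
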