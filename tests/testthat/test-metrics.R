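# Saliency metrics: hand-computed cases, algebraic identities, brute-force
# oracles and aggregation.

test_that("MAE matches hand evaluation and its boundary cases", {
  y <- matrix(c(1, 1, 0, 0), 2)
  p <- matrix(c(0.5, 1, 0.25, 0), 2)
  expect_equal(saliencyMAE(p, y), 0.1875)
  expect_equal(saliencyMAE(y, y), 0)
  expect_equal(saliencyMAE(matrix(1, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(saliencyMAE(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("MAE is symmetric under complement and invariant under paired shuffles", {
  set.seed(1)
  for (r in 1:5) {
    p <- matrix(runif(48), 6)
    y <- matrix(round(runif(48)), 6)
    expect_equal(saliencyMAE(p, y), saliencyMAE(1 - p, 1 - y))
    perm <- sample(48)
    expect_equal(saliencyMAE(p, y),
                 saliencyMAE(matrix(p[perm], 6), matrix(y[perm], 6)))
  }
})

test_that("the F-measure obeys its algebraic identities", {
  for (b2 in c(0.03, 0.3, 1)) {
    for (x in c(0.2, 0.5, 0.9)) {
      expect_equal(fMeasure(x, x, b2), x)
    }
    expect_equal(fMeasure(1, 0, b2), 0)
    expect_equal(fMeasure(0, 1, b2), 0)
  }
  expect_equal(fMeasure(0.8, 0.6, 0.3), 0.742857, tolerance = 1e-6)
  expect_error(fMeasure(0.5, 0.5, 0), "positive")
  expect_error(fMeasure(1.2, 0.5), "\\[0, 1\\]")
})

test_that("the maximum F-measure matches the exhaustive sweep oracle and its fixed points", {
  set.seed(2)
  y <- matrix(0, 3, 3); y[1:2, 2:3] <- 1
  p <- matrix(runif(9), 3)
  expect_equal(maxFMeasure(p, y), oracleMaxF(p, y), tolerance = 1e-12)
  expect_equal(maxFMeasure(y, y), 1)
  expect_equal(maxFMeasure(1 - y, y), 0)
  expect_error(maxFMeasure(p, matrix(0, 3, 3)), "undefined recall")
  # invariance under strictly monotone rescaling (p -> p^2)
  pc <- matrix(sample(seq(0.1, 0.9, by = 0.2), 36, replace = TRUE), 6)
  yc <- matrix(round(runif(36)), 6)
  if (!any(yc == 1)) yc[1] <- 1
  expect_equal(maxFMeasure(pc, yc), maxFMeasure(pc^2, yc), tolerance = 1e-12)
})

test_that("the weighted F-measure reproduces the dense dependency-matrix oracle", {
  set.seed(3)
  y <- matrix(0, 5, 5)
  y[2:4, 2:3] <- 1
  for (r in 1:4) {
    p <- matrix(runif(25), 5)
    expect_equal(weightedFbeta(p, y), oracleWFb(p, y), tolerance = 1e-10)
  }
  # a larger irregular mask, still brute-forced
  y2 <- matrix(0, 7, 6)
  y2[cbind(c(2, 3, 3, 4, 5, 6), c(2, 2, 3, 4, 4, 5))] <- 1
  p2 <- matrix(runif(42), 7)
  expect_equal(weightedFbeta(p2, y2), oracleWFb(p2, y2), tolerance = 1e-10)
})

test_that("the weighted F-measure is 1 iff the prediction equals the mask", {
  y <- matrix(0, 6, 6); y[2:4, 3:5] <- 1
  expect_equal(weightedFbeta(y, y), 1)
  u <- weightedFbeta(matrix(0.5, 6, 6), y)
  expect_true(u > 0 && u < 1)
  nearly <- y; nearly[1, 1] <- 1
  expect_lt(weightedFbeta(nearly, y), 1)
  expect_error(weightedFbeta(matrix(0.5, 6, 6), matrix(0, 6, 6)),
               "undefined recall")
})

test_that("dataset evaluation aggregates exact means and reports orphans", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "pred")); dir.create(file.path(td, "gt"))
  set.seed(4)
  ys <- ps <- list()
  for (i in 1:3) {
    y <- matrix(0, 16, 16); y[4:9, (2 + i):(8 + i)] <- 1
    p <- pmin(pmax(y * 0.8 + matrix(runif(256, 0, 0.2), 16), 0), 1)
    p <- round(255 * p) / 255            # quantize so disk and memory agree
    saveSaliencyMap(p, file.path(td, "pred", sprintf("s%d.png", i)))
    saveSaliencyMap(y, file.path(td, "gt", sprintf("s%d.png", i)))
    ys[[i]] <- y; ps[[i]] <- p
  }
  saveSaliencyMap(matrix(0.5, 8, 8), file.path(td, "pred", "orphan.png"))
  expect_warning(rep <- evaluateDataset(file.path(td, "pred"),
                                        file.path(td, "gt")),
                 "orphan")
  expect_identical(rep@unmatched, "orphan")
  expect_identical(nrow(rep@perImage), 3L)
  manual <- vapply(1:3, function(i) c(maxFMeasure(ps[[i]], ys[[i]]),
                                      weightedFbeta(ps[[i]], ys[[i]]),
                                      saliencyMAE(ps[[i]], ys[[i]])),
                   numeric(3))
  expect_equal(unname(rep@aggregate),
               unname(rowMeans(manual)), tolerance = 1e-12)
  expect_equal(rep@perImage$mae, manual[3, ], tolerance = 1e-12)
})

test_that("a perfect single pair scores (1, 1, 0)", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "pred")); dir.create(file.path(td, "gt"))
  y <- matrix(0, 12, 12); y[3:7, 4:9] <- 1
  saveSaliencyMap(y, file.path(td, "pred", "a.png"))
  saveSaliencyMap(y, file.path(td, "gt", "a.png"))
  rep <- evaluateDataset(file.path(td, "pred"), file.path(td, "gt"))
  expect_equal(unname(rep@aggregate), c(1, 1, 0))
})

test_that("table averaging reproduces the printed benchmark row means", {
  expect_equal(tableAverage(c(0.699, 0.864, 0.752, 0.854, 0.726, 0.754)),
               0.775)
  expect_equal(tableAverage(c(0.748, 0.910, 0.797, 0.890, 0.757, 0.804)),
               0.818)
  expect_equal(tableAverage(0.5), 0.5)
  expect_error(tableAverage(numeric(0)), "empty")
  tab <- benchmarkTable()
  ours <- unlist(tab[tab$method == "Ours", grepl("\\.fw$", names(tab))])
  expect_equal(tableAverage(ours), 0.775)
})
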