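# Decoder: pyramid pooling, resize-adjust, full-scale skip wiring, residual
# pass-through and the prediction head.

test_that("resize-adjust honors shape targets, identity projections and bilinear values", {
  set.seed(1)
  x <- array(rnorm(7 * 7 * 8), c(7L, 7L, 8L))
  y <- resizeAdjust(x, c(14L, 14L), targetC = 3L)
  expect_identical(dim(y), c(14L, 14L, 3L, 1L))
  # identity 1x1 projection at the native size leaves the input unchanged
  eye <- array(0, c(1L, 1L, 8L, 8L))
  for (c in 1:8) eye[1, 1, c, c] <- 1
  expect_equal(resizeAdjust(x, c(7L, 7L), weights = eye),
               array(x, c(7L, 7L, 8L, 1L)), tolerance = 1e-14)
  # 2x2 -> 4x4 upsample against the loop interpolation oracle
  x2 <- array(c(1, 3, 2, 8), c(2L, 2L, 1L, 1L))
  one <- array(1, c(1L, 1L, 1L, 1L))
  expect_equal(resizeAdjust(x2, c(4L, 4L), weights = one),
               oracleBilinear(x2, 4L, 4L), tolerance = 1e-12)
  expect_error(resizeAdjust(x, c(0L, 4L), targetC = 2L), "invalid target")
})

test_that("pyramid pooling preserves shape, keeps constants constant and rejects oversized bins", {
  set.seed(2)
  st <- liteSOD:::newStore()
  ctx <- new.env(); ctx$training <- TRUE
  ppm <- liteSOD:::buildPPM(st, ctx, C = 8L, bins = c(1L, 2L))
  x <- array(rnorm(4 * 4 * 8), c(4L, 4L, 8L, 1L))
  y <- ppm$fwd(liteSOD:::tnode(x))
  expect_identical(dim(y$v), c(4L, 4L, 8L, 1L))
  xc <- array(rep(rnorm(8), each = 16), c(4L, 4L, 8L, 1L))
  yc <- ppm$fwd(liteSOD:::tnode(xc))$v
  for (c in 1:8) expect_lt(diff(range(yc[, , c, 1])), 1e-9)
  ppm3 <- liteSOD:::buildPPM(st, ctx, C = 8L, bins = c(1L, 3L))
  tiny <- array(rnorm(2 * 2 * 8), c(2L, 2L, 8L, 1L))
  expect_error(ppm3$fwd(liteSOD:::tnode(tiny)), "bin larger")
})

test_that("every encoder stage feeds the decoder and the pyramid feature reaches every stage", {
  w <- scmWiring()
  srcs <- unlist(w[, c("src1", "src2", "src3", "src4")])
  for (en in c("en1", "en2", "en3", "en4")) expect_true(en %in% srcs)
  feeds <- apply(w, 1, function(r) "P" %in% c(r[["carried"]], r[["src1"]],
                                              r[["src2"]], r[["src3"]],
                                              r[["src4"]]))
  expect_true(all(feeds))
  expect_identical(nrow(w), 4L)
})

test_that("concatenated width equals the stage width exactly (quarter-channel economy)", {
  model <- sodModel(sodModelConfig())
  for (sp in model@engine$decoder$stagesSpec) {
    expect_identical(4L * sp$q, sp$W)
  }
})

test_that("decoder stages sit at 14/28/56/112 and the head predicts 224x224", {
  set.seed(3)
  model <- sodModel(tinyModelConfig())
  x <- array(runif(224 * 224 * 3), c(224L, 224L, 3L))
  dec <- decoderForward(model, x)
  expect_identical(dim(dec$ppm)[1:2], c(7L, 7L))
  res <- vapply(dec$stages[c("de4", "de3", "de2", "de1")],
                function(s) dim(s)[1], integer(1))
  expect_identical(unname(res), c(14L, 28L, 56L, 112L))
  expect_identical(dim(dec$logits)[1:2], c(224L, 224L))
  x5 <- encoderForward(model, x)[[5]]
  P <- pyramidPool(model, x5)
  expect_identical(dim(P), c(7L, 7L, 128L, 1L))
})

test_that("a zeroed fusion path reduces each stage to its resized carried feature", {
  set.seed(4)
  model <- sodModel(tinyModelConfig())
  st <- model@engine$store
  liteSOD:::zeroParamsByTag(st, "^dec\\.s[1-4]\\.(reduce|fuse)")
  x <- array(runif(224 * 224 * 3), c(224L, 224L, 3L))
  dec <- decoderForward(model, x)
  aw <- paramByTag(st, "dec.s4.adjust.w")$v
  ab <- paramByTag(st, "dec.s4.adjust.b")$v
  want <- resizeAdjust(dec$ppm, c(14L, 14L), weights = aw, bias = ab)
  expect_equal(dec$stages$de4, want, tolerance = 1e-12)
  aw3 <- paramByTag(st, "dec.s3.adjust.w")$v
  ab3 <- paramByTag(st, "dec.s3.adjust.b")$v
  expect_equal(dec$stages$de3,
               resizeAdjust(dec$stages$de4, c(28L, 28L), weights = aw3,
                            bias = ab3),
               tolerance = 1e-12)
})

test_that("a zeroed prediction head yields the all-0.5 coarse map (sigmoid of zero)", {
  set.seed(5)
  model <- sodModel(tinyModelConfig())
  liteSOD:::zeroParamsByTag(model@engine$store, "^dec\\.head")
  p <- predictSaliency(model, array(runif(224 * 224 * 3), c(224L, 224L, 3L)))
  expect_true(all(mapData(p$coarse) == 0.5))
})

# Independent replay of a small decoder (pyramid pooler + one fusion stage)
# with the loop primitives.
test_that("a toy decoder forward matches the loop-oracle replay", {
  set.seed(6)
  st <- liteSOD:::newStore()
  ctx <- new.env(); ctx$training <- TRUE
  encC <- c(2L, 2L, 2L, 2L, 4L)
  dec <- liteSOD:::buildDecoder(st, ctx, encC, c(4L, 4L, 4L, 4L),
                                ppmBins = c(1L, 2L))
  sizes <- c(32L, 16L, 8L, 4L, 2L)
  maps <- lapply(seq_len(5L), function(i) {
    liteSOD:::tnode(array(rnorm(sizes[i]^2 * encC[i]),
                          c(sizes[i], sizes[i], encC[i], 1L)))
  })
  got <- dec$fwd(maps)

  # oracle pyramid pooler
  x5 <- maps[[5]]$v
  pieces <- list(x5)
  for (b in c(1L, 2L)) {
    pooled <- oracleAdaptiveAvg(x5, b, b)
    red <- oracleConvBnRelu(st, sprintf("dec.ppm.bin%d", b), pooled)
    pieces <- c(pieces, list(oracleBilinear(red, 2L, 2L)))
  }
  cat5 <- array(0, c(2L, 2L, 4L + 2L * 2L, 1L))
  off <- 0L
  for (pc in pieces) {
    cat5[, , off + seq_len(dim(pc)[3]), ] <- pc
    off <- off + dim(pc)[3]
  }
  P <- oracleConvBnRelu(st, "dec.ppm.proj", cat5)
  expect_equal(got$ppm$v, P, tolerance = 1e-5)

  # oracle stage 4: reduce+resize the four encoder sources, fuse, add carried
  srcs <- list(maps[[4]]$v, maps[[3]]$v, maps[[2]]$v, maps[[1]]$v)
  reduced <- lapply(seq_len(4L), function(k) {
    oracleBilinear(oracleConvBnRelu(st, sprintf("dec.s4.reduce%d", k),
                                    srcs[[k]]), 4L, 4L)
  })
  cat4 <- array(0, c(4L, 4L, 4L, 1L))
  for (k in seq_len(4L)) cat4[, , k, ] <- reduced[[k]]
  fused <- oracleConvBnRelu(st, "dec.s4.fuse", cat4)
  aw <- paramByTag(st, "dec.s4.adjust.w")$v
  ab <- paramByTag(st, "dec.s4.adjust.b")$v
  carried <- oracleConv(oracleBilinear(P, 4L, 4L), aw, ab)
  expect_equal(got$stages$de4$v, fused + carried, tolerance = 1e-5)
})
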