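# Residual refinement module and full-model assembly.

test_that("a zeroed refinement module leaves the coarse map exactly unchanged", {
  set.seed(1)
  model <- sodModel(tinyModelConfig())
  liteSOD:::zeroParamsByTag(model@engine$store, "^rfm")
  x <- array(runif(224 * 224 * 3), c(224L, 224L, 3L))
  p <- predictSaliency(model, x)
  expect_identical(mapData(p$refined), mapData(p$coarse))
})

test_that("a zeroed output layer alone already silences the residual", {
  set.seed(2)
  model <- sodModel(tinyModelConfig())
  liteSOD:::zeroParamsByTag(model@engine$store, "^rfm\\.out")
  res <- rfmForward(model, matrix(runif(224 * 224), 224L))
  expect_true(all(mapData(res) == 0))
  expect_identical(mapSpace(res), "logit")
})

test_that("the refinement module follows the printed 4-8-16-24-36 filter schedule", {
  model <- sodModel(sodModelConfig())
  expect_identical(model@engine$rfm$filters, c(4L, 8L, 16L, 24L, 36L))
  expect_identical(model@engine$rfm$decFilters, c(36L, 24L, 16L, 8L, 4L))
  expect_error(rfmForward(model, matrix(0.5, 100L, 100L)), "224")
})

test_that("refinement parameters equal the layer-by-layer hand count", {
  model <- sodModel(sodModelConfig())
  st <- model@engine$store
  got <- sum(vapply(which(grepl("^rfm", st$tags)),
                    function(i) length(st$params[[i]]$v), numeric(1)))
  f <- c(4L, 8L, 16L, 24L, 36L)
  cin <- c(1L, f[-5])
  hand <- sum(9L * cin * f + 2L * f)            # encoder convs + batch norms
  dIn <- c(36L, 36L, 24L, 16L, 8L)
  dOut <- c(36L, 24L, 16L, 8L, 4L)
  hand <- hand + sum(9L * dIn * dOut + 2L * dOut)  # decoder convs + norms
  hand <- hand + 9L * 4L * 1L + 1L                 # residual output conv
  expect_identical(as.integer(got), as.integer(hand))
})

test_that("a reduced-depth toy refinement forward matches the loop-oracle replay", {
  set.seed(3)
  st <- liteSOD:::newStore()
  ctx <- new.env(); ctx$training <- TRUE
  filters <- c(2L, 3L, 4L, 5L, 6L)
  rfm <- liteSOD:::buildRFM(st, ctx, filters)
  x <- array(runif(32 * 32), c(32L, 32L, 1L, 1L))
  got <- rfm$fwd(liteSOD:::tnode(x))$v

  h <- x
  for (s in 1:5) {
    h <- oracleConvBnRelu(st, sprintf("rfm.enc%d", s), h)
    if (s < 5) h <- oracleMaxPool2(h)
  }
  for (s in 1:5) {
    h <- oracleConvBnRelu(st, sprintf("rfm.dec%d", s), h)
    if (s < 5) h <- oracleBilinear(h, 2L * dim(h)[1], 2L * dim(h)[2])
  }
  w <- paramByTag(st, "rfm.out.w")$v
  b <- paramByTag(st, "rfm.out.b")$v
  want <- oracleConv(h, w, b, 1L, 1L, 1L)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("both output maps stay in [0, 1] for random inputs and the forward is seed-reproducible", {
  model <- sodModel(tinyModelConfig(seed = 9L))
  for (s in 1:3) {
    set.seed(100 + s)
    x <- array(runif(224 * 224 * 3, -1, 2), c(224L, 224L, 3L))
    p <- predictSaliency(model, x)
    expect_true(all(mapData(p$coarse) >= 0 & mapData(p$coarse) <= 1))
    expect_true(all(mapData(p$refined) >= 0 & mapData(p$refined) <= 1))
  }
  m2 <- sodModel(tinyModelConfig(seed = 9L))
  set.seed(123)
  x <- array(runif(224 * 224 * 3), c(224L, 224L, 3L))
  expect_identical(mapData(predictSaliency(model, x)$refined),
                   mapData(predictSaliency(m2, x)$refined))
})

test_that("a full-model single-image forward completes within the second-scale bound", {
  model <- sodModel(sodModelConfig())
  x <- array(runif(224 * 224 * 3), c(224L, 224L, 3L))
  invisible(predictSaliency(model, x))  # warm up allocator and caches
  times <- vapply(1:3, function(i) {
    t0 <- Sys.time()
    invisible(predictSaliency(model, x))
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }, numeric(1))
  expect_lt(min(times), 1.0)
})
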