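# Encoder: attention heads, the multiscale attention module and the
# five-stage resolution/channel schedule.

test_that("channel attention returns one weight per channel in [0, 1]", {
  set.seed(1)
  att <- newChannelAttention(64L, reduction = 4L)
  x <- array(rnorm(28 * 28 * 64), c(28L, 28L, 64L))
  w <- applyChannelAttention(att, x)
  expect_identical(dim(w), c(1L, 1L, 64L, 1L))
  expect_true(all(w >= 0 & w <= 1))
  # zeroed output layer: sigmoid(0) = 0.5 for every channel
  liteSOD:::zeroParamsByTag(att$store, "fc2")
  w0 <- applyChannelAttention(att, x)
  expect_true(all(w0 == 0.5))
  expect_error(applyChannelAttention(att, x * NA), "invalid activations")
})

test_that("channel attention equals the explicit pool-affine-sigmoid computation", {
  set.seed(2)
  att <- newChannelAttention(2L, reduction = 1L)
  x <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2L, 2L, 2L, 1L))
  expect_equal(applyChannelAttention(att, x),
               oracleChannelAttention(att$store, "catt", x),
               tolerance = 1e-12)
})

test_that("spatial attention gives one weight per location, constant for constant input", {
  set.seed(3)
  att <- newSpatialAttention()
  x <- array(rnorm(14 * 14 * 96), c(14L, 14L, 96L))
  w <- applySpatialAttention(att, x)
  expect_identical(dim(w), c(14L, 14L, 1L, 1L))
  expect_true(all(w >= 0 & w <= 1))
  xc <- array(0.7, c(6L, 6L, 4L))
  wc <- applySpatialAttention(att, xc)
  expect_lt(diff(range(wc[2:5, 2:5, 1, 1])), 1e-12)  # away from padding
  x2 <- array(rnorm(2 * 2 * 1), c(2L, 2L, 1L, 1L))
  expect_equal(applySpatialAttention(att, x2),
               oracleSpatialAttention(att$store, "satt", x2),
               tolerance = 1e-12)
})

test_that("the MAM preserves shape, normalizes branch weights and errors on odd sizes", {
  set.seed(4)
  for (dims in list(c(4L, 4L, 2L), c(6L, 6L, 4L), c(8L, 4L, 3L))) {
    mam <- newMAM(dims[3])
    x <- array(rnorm(prod(dims)), dims)
    r <- mamForward(mam, x, withWeights = TRUE)
    expect_identical(dim(r$out), c(dims, 1L))
    wsum <- r$weights[[1]] + r$weights[[2]] + r$weights[[3]]
    expect_true(all(abs(wsum - 1) < 1e-6))
    expect_true(all(vapply(r$weights, function(w) all(w >= 0), logical(1))))
  }
  mam <- newMAM(2L)
  expect_error(mamForward(mam, array(1, c(5L, 4L, 2L))),
               "stage resolution not divisible")
  expect_error(newMAM(2L, dilations = c(1L, 2L)), "3 branch dilations")
})

test_that("zeroing all MAM parameters reduces the module to the identity", {
  set.seed(5)
  mam <- newMAM(3L, store = liteSOD:::newStore(), tag = "mam")
  liteSOD:::zeroParamsByTag(mam$store, "^mam")
  x <- array(rnorm(6 * 6 * 3), c(6L, 6L, 3L))
  expect_identical(mamForward(mam, x), array(x, c(6L, 6L, 3L, 1L)))
})

test_that("the vectorized MAM forward matches the straight-line oracle", {
  set.seed(6)
  for (cse in list(c(4L, 4L, 2L), c(6L, 6L, 4L))) {
    mam <- newMAM(cse[3])
    x <- array(rnorm(prod(cse)), c(cse, 1L))
    expect_equal(mamForward(mam, x), oracleMAM(mam, x), tolerance = 1e-5)
  }
})

test_that("the encoder follows the 224-112-56-28-14-7 schedule and ends at 128 channels", {
  model <- sodModel(tinyModelConfig())
  x <- array(runif(224 * 224 * 3), c(224L, 224L, 3L))
  feats <- encoderForward(model, x)
  expect_length(feats, 5L)
  sizes <- vapply(feats, function(f) dim(f)[1], integer(1))
  expect_identical(sizes, c(112L, 56L, 28L, 14L, 7L))
  expect_identical(dim(feats[[5]])[3], 128L)
  expect_true(all(vapply(feats, function(f) all(is.finite(f)), logical(1))))
  expect_error(encoderForward(model, array(0, c(128L, 128L, 3L))),
               "expected 224x224")
})

test_that("encoder configs reject width schedules that break the contract", {
  expect_error(encoderConfig(stageChannels = c(16L, 32L, 64L, 96L, 64L)),
               "128")
  expect_error(encoderConfig(stageChannels = c(32L, 16L, 64L, 96L, 128L)),
               "non-decreasing")
  expect_error(encoderConfig(dilationRates = c(1L, 2L, 3L, 4L)), "3 positive")
})
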