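# The compiled tensor kernels against straight-line loop oracles, and the
# tape gradients against numeric differentiation.

tnode <- liteSOD:::tnode

test_that("convolution forward matches the loop oracle over strides, padding and dilation", {
  set.seed(42)
  cases <- list(
    list(hw = c(6L, 6L), cin = 3L, cout = 2L, k = 3L, s = 1L, p = 1L, d = 1L, n = 2L),
    list(hw = c(6L, 4L), cin = 2L, cout = 4L, k = 3L, s = 2L, p = 1L, d = 1L, n = 1L),
    list(hw = c(6L, 6L), cin = 2L, cout = 2L, k = 3L, s = 1L, p = 2L, d = 2L, n = 2L),
    list(hw = c(5L, 5L), cin = 1L, cout = 3L, k = 1L, s = 1L, p = 0L, d = 1L, n = 1L),
    list(hw = c(6L, 6L), cin = 2L, cout = 1L, k = 3L, s = 1L, p = 4L, d = 4L, n = 1L))
  for (cs in cases) {
    x <- array(rnorm(prod(cs$hw) * cs$cin * cs$n), c(cs$hw, cs$cin, cs$n))
    w <- array(rnorm(cs$k^2 * cs$cin * cs$cout), c(cs$k, cs$k, cs$cin, cs$cout))
    got <- liteSOD:::cppConvForward(x, w, cs$s, cs$s, cs$p, cs$p, cs$d, cs$d)
    want <- oracleConv(x, w, NULL, cs$s, cs$p, cs$d)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("bilinear resize, adaptive pooling, max pooling and batch norm match loop oracles", {
  set.seed(7)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6L, 6L, 3L, 2L))
  expect_equal(liteSOD:::cppBilinearForward(x, 4L, 9L), oracleBilinear(x, 4L, 9L),
               tolerance = 1e-12)
  expect_equal(liteSOD:::cppBilinearForward(x, 12L, 12L), oracleBilinear(x, 12L, 12L),
               tolerance = 1e-12)
  expect_equal(liteSOD:::cppAdaptiveAvgForward(x, 2L, 3L), oracleAdaptiveAvg(x, 2L, 3L),
               tolerance = 1e-12)
  expect_equal(liteSOD:::cppMaxPool2Forward(x)$y, oracleMaxPool2(x),
               tolerance = 1e-12)
  gamma <- runif(3, 0.5, 1.5)
  beta <- rnorm(3)
  got <- liteSOD:::cppBnForward(x, gamma, beta, 1e-5)$y
  expect_equal(got, oracleBNTrain(x, gamma, beta), tolerance = 1e-10)
})

numGrad <- function(f, arr, i, eps = 1e-6) {
  a1 <- arr; a1[i] <- a1[i] + eps
  a2 <- arr; a2[i] <- a2[i] - eps
  (f(a1) - f(a2)) / (2 * eps)
}

test_that("tape gradients agree with central differences for every operation", {
  set.seed(99)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4L, 4L, 2L, 2L))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3L, 3L, 2L, 3L)) * 0.3
  b <- rnorm(3) * 0.1
  y <- array(round(runif(4 * 4 * 3 * 2)), c(4L, 4L, 3L, 2L))

  lossOf <- function(xa, wa, ba) {
    xt <- tnode(xa); wt <- tnode(wa); bt <- tnode(ba)
    out <- liteSOD:::tConv(xt, wt, bt, stride = 1L, pad = 1L, dilation = 1L)
    liteSOD:::tBceLogits(out, y)$v
  }
  xt <- tnode(x); wt <- tnode(w); bt <- tnode(b)
  for (p in list(xt, wt, bt)) p$param <- TRUE
  out <- liteSOD:::tConv(xt, wt, bt, stride = 1L, pad = 1L, dilation = 1L)
  liteSOD:::backwardPass(liteSOD:::tBceLogits(out, y))
  for (i in c(1L, 7L, 30L)) {
    expect_equal(xt$grad[i], numGrad(function(a) lossOf(a, w, b), x, i),
                 tolerance = 1e-5)
    expect_equal(wt$grad[i], numGrad(function(a) lossOf(x, a, b), w, i),
                 tolerance = 1e-5)
  }
  expect_equal(bt$grad[2], numGrad(function(a) lossOf(x, w, a), b, 2),
               tolerance = 1e-5)

  # composite: bilinear + batch norm + pooling + attention product + softmax
  gamma <- runif(2, 0.5, 1.5); beta <- rnorm(2) * 0.1
  wsq <- array(rnorm(2), c(1L, 1L, 2L, 1L)) * 0.4   # channel squeeze to 1
  mixGraph <- function(xt) {
    up <- liteSOD:::tBilinear(xt, 8L, 8L)
    r <- liteSOD:::cppBnForward(up$v, gamma, beta, 1e-5)
    bn <- liteSOD:::tnode(r$y, list(up), function(g) {
      cb <- liteSOD:::cppBnBackward(up$v, gamma, r$mean, r$invstd, g)
      list(cb$gx)
    })
    pooled <- liteSOD:::tAdaptiveAvg(bn, 4L, 4L)
    mp <- liteSOD:::tMaxPool2(pooled)
    sq <- liteSOD:::tChannelSqueeze(mp)
    cw <- liteSOD:::tSigmoid(liteSOD:::tGlobalAvg(mp))          # (1,1,2,1)
    sw <- liteSOD:::tSigmoid(
      liteSOD:::tConv(sq, tnode(wsq), stride = 1L, pad = 0L,
                      dilation = 1L))                            # (2,2,1,1)
    outer <- liteSOD:::tOuterCS(cw, sw)
    sm <- liteSOD:::tSoftmax3(list(mp, liteSOD:::tScale(mp, 0.5),
                                   liteSOD:::tMul(mp, mp)))
    mix <- liteSOD:::tAdd(liteSOD:::tMul(mp, outer),
                          liteSOD:::tMul(sm[[1]], sm[[2]]))
    liteSOD:::tBceLogits(mix, array(0.3, dim(mix$v)))
  }
  mixLoss <- function(xa) mixGraph(tnode(xa))$v
  x2 <- array(rnorm(4 * 4 * 2), c(4L, 4L, 2L, 1L)) * 0.5
  xt2 <- tnode(x2); xt2$param <- TRUE
  liteSOD:::backwardPass(mixGraph(xt2))
  for (i in c(2L, 11L, 25L)) {
    expect_equal(xt2$grad[i], numGrad(mixLoss, x2, i), tolerance = 1e-4)
  }
})

test_that("the distance transform returns exact distances and nearest indices", {
  set.seed(3)
  for (rep in 1:5) {
    fg <- matrix(runif(9 * 11) < 0.15, 9, 11)
    if (!any(fg)) fg[5, 6] <- TRUE
    dt <- liteSOD:::cppDistanceTransform(fg)
    idx <- which(fg)
    rc <- arrayInd(idx, dim(fg))
    for (i in 1:9) for (j in 1:11) {
      d2 <- (rc[, 1] - i)^2 + (rc[, 2] - j)^2
      expect_equal(dt$dist[i, j], sqrt(min(d2)), tolerance = 1e-12)
      near <- arrayInd(dt$index[i, j], dim(fg))
      expect_equal((near[1] - i)^2 + (near[2] - j)^2, min(d2))
      expect_true(fg[near[1], near[2]])
    }
  }
})
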