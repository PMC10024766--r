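# Straight-line reference implementations used as independent oracles.
# Everything here is plain R loops over small arrays; none of it calls the
# package's compiled kernels.

paramByTag <- function(store, tag) {
  i <- match(tag, store$tags)
  if (is.na(i)) stop("no parameter tagged ", tag)
  store$params[[i]]
}

oracleConv <- function(x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kd <- dim(w); KH <- kd[1]; KW <- kd[2]; Cout <- kd[4]
  OH <- (H + 2 * pad - dilation * (KH - 1) - 1) %/% stride + 1L
  OW <- (W + 2 * pad - dilation * (KW - 1) - 1) %/% stride + 1L
  y <- array(0, c(OH, OW, Cout, N))
  for (n in seq_len(N)) for (co in seq_len(Cout)) {
    for (oh in seq_len(OH)) for (ow in seq_len(OW)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(C)) for (kh in seq_len(KH)) for (kw in seq_len(KW)) {
        hy <- (oh - 1L) * stride - pad + (kh - 1L) * dilation + 1L
        wy <- (ow - 1L) * stride - pad + (kw - 1L) * dilation + 1L
        if (hy >= 1L && hy <= H && wy >= 1L && wy <= W) {
          acc <- acc + x[hy, wy, ci, n] * w[kh, kw, ci, co]
        }
      }
      y[oh, ow, co, n] <- acc
    }
  }
  y
}

oracleBilinear <- function(x, OH, OW) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  y <- array(0, c(OH, OW, C, N))
  for (n in seq_len(N)) for (c in seq_len(C)) {
    for (i in seq_len(OH)) for (j in seq_len(OW)) {
      sy <- min(max((i - 0.5) * H / OH - 0.5, 0), H - 1)
      sx <- min(max((j - 0.5) * W / OW - 0.5, 0), W - 1)
      h0 <- floor(sy); w0 <- floor(sx)
      h1 <- min(h0 + 1, H - 1); w1 <- min(w0 + 1, W - 1)
      a <- sy - h0; bb <- sx - w0
      y[i, j, c, n] <-
        x[h0 + 1, w0 + 1, c, n] * (1 - a) * (1 - bb) +
        x[h1 + 1, w0 + 1, c, n] * a * (1 - bb) +
        x[h0 + 1, w1 + 1, c, n] * (1 - a) * bb +
        x[h1 + 1, w1 + 1, c, n] * a * bb
    }
  }
  y
}

oracleAdaptiveAvg <- function(x, OH, OW) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  y <- array(0, c(OH, OW, C, N))
  for (n in seq_len(N)) for (c in seq_len(C)) {
    for (i in seq_len(OH)) for (j in seq_len(OW)) {
      h0 <- ((i - 1L) * H) %/% OH + 1L
      h1 <- ceiling(i * H / OH)
      w0 <- ((j - 1L) * W) %/% OW + 1L
      w1 <- ceiling(j * W / OW)
      y[i, j, c, n] <- mean(x[h0:h1, w0:w1, c, n])
    }
  }
  y
}

oracleMaxPool2 <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    for (i in seq_len(d[1] %/% 2L)) for (j in seq_len(d[2] %/% 2L)) {
      y[i, j, c, n] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n])
    }
  }
  y
}

oracleBNTrain <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[3])) {
    v <- as.vector(x[, , c, , drop = FALSE])
    m <- mean(v)
    va <- mean((v - m)^2)
    y[, , c, ] <- gamma[c] * (x[, , c, , drop = FALSE] - m) / sqrt(va + eps) +
      beta[c]
  }
  y
}

oracleConvBnRelu <- function(store, tag, x, stride = 1L, dilation = 1L) {
  w <- paramByTag(store, paste0(tag, ".w"))$v
  gamma <- paramByTag(store, paste0(tag, ".gamma"))$v
  beta <- paramByTag(store, paste0(tag, ".beta"))$v
  pad <- as.integer(dilation * (dim(w)[1] - 1) / 2)
  h <- oracleConv(x, w, NULL, stride, pad, dilation)
  h <- oracleBNTrain(h, gamma, beta)
  pmax(h, 0)
}

oracleChannelAttention <- function(store, tag, x) {
  w1 <- paramByTag(store, paste0(tag, ".fc1.w"))$v
  b1 <- paramByTag(store, paste0(tag, ".fc1.b"))$v
  w2 <- paramByTag(store, paste0(tag, ".fc2.w"))$v
  b2 <- paramByTag(store, paste0(tag, ".fc2.b"))$v
  d <- dim(x)
  out <- array(0, c(1, 1, dim(w2)[4], d[4]))
  for (n in seq_len(d[4])) {
    g <- vapply(seq_len(d[3]), function(c) mean(x[, , c, n]), numeric(1))
    h1 <- pmax(as.vector(t(matrix(w1[1, 1, , ], dim(w1)[3])) %*% g + b1), 0)
    out[1, 1, , n] <- 1 / (1 + exp(-(as.vector(
      t(matrix(w2[1, 1, , ], dim(w2)[3])) %*% h1 + b2))))
  }
  out
}

oracleSpatialAttention <- function(store, tag, x) {
  w <- paramByTag(store, paste0(tag, ".conv.w"))$v
  b <- paramByTag(store, paste0(tag, ".conv.b"))$v
  d <- dim(x)
  sq <- array(0, c(d[1], d[2], 2, d[4]))
  for (n in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    sq[i, j, 1, n] <- mean(x[i, j, , n])
    sq[i, j, 2, n] <- max(x[i, j, , n])
  }
  1 / (1 + exp(-oracleConv(sq, w, b, 1L, 1L, 1L)))
}

# Straight-line multiscale attention module (training-mode batch norm),
# mirroring the documented construction step by step.
oracleMAM <- function(mam, x, dilations = c(1L, 2L, 4L)) {
  store <- mam$store
  tags <- store$tags
  tagRoot <- sub("\\.shared\\.w$", "",
                 tags[grepl("\\.shared\\.w$", tags)][1])
  d <- dim(x)
  H <- d[1]; W <- d[2]
  X <- oracleConvBnRelu(store, paste0(tagRoot, ".shared"), x)
  f1 <- oracleBilinear(
    oracleConvBnRelu(store, paste0(tagRoot, ".branch1"),
                     oracleBilinear(X, 2L * H, 2L * W),
                     dilation = dilations[1]), H, W)
  f2 <- oracleConvBnRelu(store, paste0(tagRoot, ".branch2"), X,
                         dilation = dilations[2])
  f3 <- oracleBilinear(
    oracleConvBnRelu(store, paste0(tagRoot, ".branch3"),
                     oracleAdaptiveAvg(X, (H + 1L) %/% 2L, (W + 1L) %/% 2L),
                     dilation = dilations[3]), H, W)
  fsum <- f1 + f2 + f3
  logits <- lapply(1:3, function(i) {
    cw <- oracleChannelAttention(store, paste0(tagRoot, ".catt", i), fsum)
    sw <- oracleSpatialAttention(store, paste0(tagRoot, ".satt", i), fsum)
    l <- array(0, d)
    for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
      l[, , c, n] <- cw[1, 1, c, n] * sw[, , 1, n]
    }
    l
  })
  es <- lapply(logits, exp)
  z <- es[[1]] + es[[2]] + es[[3]]
  S <- lapply(es, function(e) e / z)
  gated <- f1 * S[[1]] + f2 * S[[2]] + f3 * S[[3]]
  wf <- paramByTag(store, paste0(tagRoot, ".fuse.w"))$v
  bf <- paramByTag(store, paste0(tagRoot, ".fuse.b"))$v
  oracleConv(gated, wf, bf, 1L, 0L, 1L) + x
}

# Brute-force maximum F-measure: recompute precision/recall per threshold
# from scratch with table counts.
oracleMaxF <- function(p, y, nThr = 256L, beta2 = 0.3) {
  thr <- seq(0, 1, length.out = nThr)
  best <- 0
  for (t in thr) {
    pred <- as.vector(p) > t
    truth <- as.vector(y) == 1
    tp <- sum(pred & truth)
    prec <- if (sum(pred) == 0) 0 else tp / sum(pred)
    rec <- tp / sum(truth)
    den <- beta2 * prec + rec
    f <- if (den == 0) 0 else (1 + beta2) * prec * rec / den
    best <- max(best, f)
  }
  best
}

# Dense brute-force weighted F-measure: explicit nearest-foreground search,
# explicit zero-padded Gaussian dependency filtering, explicit weighting.
oracleWFb <- function(p, y, beta2 = 1, sigma = 5, alpha = log(0.5) / 5) {
  H <- nrow(y); W <- ncol(y)
  fgIdx <- which(y == 1, arr.ind = TRUE)
  E <- abs(p - y)
  D <- matrix(0, H, W)
  Et <- E
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (y[i, j] == 0) {
      d2 <- (fgIdx[, 1] - i)^2 + (fgIdx[, 2] - j)^2
      k <- which.min(d2)
      D[i, j] <- sqrt(d2[k])
      Et[i, j] <- E[fgIdx[k, 1], fgIdx[k, 2]]
    }
  }
  ks <- outer(exp(-(-3:3)^2 / (2 * sigma^2)), exp(-(-3:3)^2 / (2 * sigma^2)))
  ks <- ks / sum(ks)
  EA <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in -3:3) for (b in -3:3) {
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        acc <- acc + Et[ii, jj] * ks[a + 4, b + 4]
      }
    }
    EA[i, j] <- acc
  }
  minE <- E
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (y[i, j] == 1 && EA[i, j] < E[i, j]) minE[i, j] <- EA[i, j]
  }
  B <- matrix(1, H, W)
  B[y == 0] <- 2 - exp(alpha * D[y == 0])
  Ew <- minE * B
  fg <- y == 1
  eps <- .Machine$double.eps
  TPw <- sum(fg) - sum(Ew[fg])
  FPw <- sum(Ew[!fg])
  R <- max(1 - mean(Ew[fg]), 0)
  P <- max(TPw / (TPw + FPw + eps), 0)
  (1 + beta2) * P * R / (beta2 * P + R + eps)
}

# Small fully assembled model used by several tests (kept narrow but with
# the full five-stage topology).
tinyModelConfig <- function(seed = 1L) {
  sodModelConfig(
    encoder = encoderConfig(stageChannels = c(4L, 4L, 8L, 8L, 128L),
                            blocksPerStage = rep(1L, 5L)),
    decoder = decoderConfig(stageChannels = c(8L, 8L, 4L, 4L)),
    seed = seed)
}
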