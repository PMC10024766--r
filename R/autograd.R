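# Reverse-mode tape over dense (H, W, C, N) activation arrays.
#
# Every differentiable operation returns a node (an environment) holding the
# forward value, its parent nodes and a closure mapping the incoming gradient
# to per-parent gradients. backwardPass() walks the tape in reverse
# topological order. Heavy kernels (convolution, batch norm, resampling,
# pooling) live in src/kernels.cpp; the tape itself is plain R.

tnode <- function(v, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$param <- FALSE
  class(e) <- "sodTensor"
  e
}

#' @noRd
tdim <- function(x) dim(x$v)

# Gradient accumulation in reverse topological order. Non-parameter gradients
# are released as soon as they have been propagated.
backwardPass <- function(root, seed = NULL) {
  order <- vector("list", 256L)
  k <- 0L
  visit <- function(n) {
    if (isTRUE(n$.seen)) return(invisible(NULL))
    n$.seen <- TRUE
    for (p in n$parents) visit(p)
    k <<- k + 1L
    if (k > length(order)) length(order) <<- 2L * k
    order[[k]] <<- n
    invisible(NULL)
  }
  visit(root)
  if (is.null(seed)) {
    seed <- if (is.null(dim(root$v))) 1 else array(1, dim(root$v))
  }
  root$grad <- seed
  for (i in rev(seq_len(k))) {
    n <- order[[i]]
    n$.seen <- NULL
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- n$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!n$param) n$grad <- NULL
  }
  invisible(root)
}

tAdd <- function(a, b) {
  tnode(a$v + b$v, list(a, b), function(g) list(g, g))
}

tMul <- function(a, b) {
  av <- a$v; bv <- b$v
  tnode(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

tRelu <- function(a) {
  mask <- a$v > 0
  tnode(a$v * mask, list(a), function(g) list(g * mask))
}

tSigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  tnode(s, list(a), function(g) list(g * s * (1 - s)))
}

tBilinear <- function(a, oh, ow) {
  d <- dim(a$v)
  if (d[1] == oh && d[2] == ow) return(a)
  tnode(cppBilinearForward(a$v, oh, ow), list(a),
        function(g) list(cppBilinearBackward(g, d[1], d[2])))
}

tMaxPool2 <- function(a) {
  d <- dim(a$v)
  r <- cppMaxPool2Forward(a$v)
  tnode(r$y, list(a),
        function(g) list(cppMaxPool2Backward(g, r$idx, d[1], d[2])))
}

tAdaptiveAvg <- function(a, oh, ow) {
  d <- dim(a$v)
  tnode(cppAdaptiveAvgForward(a$v, oh, ow), list(a),
        function(g) list(cppAdaptiveAvgBackward(g, d[1], d[2])))
}

tConv <- function(x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  y <- cppConvForward(x$v, w$v, stride, stride, pad, pad, dilation, dilation)
  od <- dim(y)
  plane <- od[1] * od[2]
  if (!is.null(b)) {
    y <- y + rep(as.vector(b$v), each = plane)  # recycles across batch
    parents <- list(x, w, b)
  } else {
    parents <- list(x, w)
  }
  xv <- x$v; wv <- w$v
  tnode(y, parents, function(g) {
    cb <- cppConvBackward(xv, wv, g, stride, stride, pad, pad,
                          dilation, dilation)
    if (length(parents) == 3L) {
      gb <- g
      dim(gb) <- c(plane, od[3], od[4])
      list(cb$gx, cb$gw, rowSums(colSums(gb)))
    } else {
      list(cb$gx, cb$gw)
    }
  })
}

# Channel concatenation (dimension 3).
tConcatC <- function(xs) {
  d1 <- dim(xs[[1]]$v)
  cs <- vapply(xs, function(x) dim(x$v)[3], numeric(1))
  y <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (x in xs) {
    ci <- dim(x$v)[3]
    y[, , off + seq_len(ci), ] <- x$v
    off <- off + ci
  }
  tnode(y, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      ci <- cs[i]
      out[[i]] <- g[, , off + seq_len(ci), , drop = FALSE]
      off <- off + ci
    }
    out
  })
}

# Multiply (H,W,C,N) by per-channel weights (1,1,C,N).
tBroadcastC <- function(x, w) {
  d <- dim(x$v)
  plane <- d[1] * d[2]
  f <- rep(as.vector(w$v), each = plane)
  xv <- x$v
  tnode(x$v * f, list(x, w), function(g) {
    gw <- g * xv
    dim(gw) <- c(plane, d[3] * d[4])
    list(g * f, array(colSums(gw), c(1, 1, d[3], d[4])))
  })
}

# Multiply (H,W,C,N) by per-location weights (H,W,1,N).
tBroadcastS <- function(x, s) {
  d <- dim(x$v)
  f <- s$v[, , rep(1L, d[3]), , drop = FALSE]
  xv <- x$v
  tnode(x$v * f, list(x, s), function(g) {
    gs <- g * xv
    dim(gs) <- c(d[1] * d[2], d[3], d[4])
    out <- array(0, c(d[1], d[2], 1, d[4]))
    for (n in seq_len(d[4])) {
      out[, , 1, n] <- rowSums(gs[, , n, drop = FALSE], dims = 1)
    }
    list(g * f, out)
  })
}

# Softmax across a list of three same-shaped tensors (per element).
tSoftmax3 <- function(xs) {
  m <- pmax(xs[[1]]$v, xs[[2]]$v, xs[[3]]$v)
  es <- lapply(xs, function(x) exp(x$v - m))
  z <- es[[1]] + es[[2]] + es[[3]]
  ss <- lapply(es, function(e) e / z)
  lapply(seq_len(3L), function(i) {
    tnode(ss[[i]], xs, function(g) {
      lapply(seq_len(3L), function(j) {
        g * ss[[i]] * ((i == j) - ss[[j]])
      })
    })
  })
}

# Global average pool (H,W,C,N) -> (1,1,C,N).
tGlobalAvg <- function(x) {
  d <- dim(x$v)
  plane <- d[1] * d[2]
  v <- x$v
  dim(v) <- c(plane, d[3] * d[4])
  tnode(array(colMeans(v), c(1, 1, d[3], d[4])), list(x), function(g) {
    list(array(rep(as.vector(g), each = plane) / plane, d))
  })
}

# Channel squeeze: per-pixel mean and max over channels -> (H,W,2,N).
tChannelSqueeze <- function(x) {
  d <- dim(x$v)
  r <- cppChannelReduce(x$v)
  y <- array(0, c(d[1], d[2], 2, d[4]))
  y[, , 1, ] <- r$mean
  y[, , 2, ] <- r$max
  tnode(y, list(x), function(g) {
    gm <- g[, , 1, , drop = FALSE]
    gx <- g[, , 2, , drop = FALSE]
    list(cppChannelReduceBackward(gm, gx, r$argmax, d[3]))
  })
}

# Mean binary cross-entropy from logits (numerically stable softplus form).
tBceLogits <- function(z, y) {
  zv <- z$v
  n <- length(zv)
  loss <- mean(pmax(zv, 0) + log1p(exp(-abs(zv))) - y * zv)
  tnode(loss, list(z), function(g) {
    list(g * (1 / (1 + exp(-zv)) - y) / n)
  })
}

# Outer product of per-channel weights (1,1,C,N) and per-location weights
# (H,W,1,N) -> full attention logits (H,W,C,N).
tOuterCS <- function(cw, sw) {
  ds <- dim(sw$v)
  C <- dim(cw$v)[3]
  plane <- ds[1] * ds[2]
  f1 <- array(rep(as.vector(cw$v), each = plane), c(ds[1], ds[2], C, ds[4]))
  f2 <- sw$v[, , rep(1L, C), , drop = FALSE]
  tnode(f1 * f2, list(cw, sw), function(g) {
    gc <- g * f2
    dim(gc) <- c(plane, C * ds[4])
    gs <- g * f1
    dim(gs) <- c(plane, C, ds[4])
    out <- array(0, c(ds[1], ds[2], 1, ds[4]))
    for (n in seq_len(ds[4])) {
      out[, , 1, n] <- rowSums(gs[, , n, drop = FALSE], dims = 1)
    }
    list(array(colSums(gc), c(1, 1, C, ds[4])), out)
  })
}

tScale <- function(x, s) {
  tnode(x$v * s, list(x), function(g) list(g * s))
}

tAddScalarOf <- function(a, b) {
  # scalar nodes (loss terms)
  tnode(a$v + b$v, list(a, b), function(g) list(g, g))
}
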