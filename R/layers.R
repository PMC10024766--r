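# Layer constructors. Each layer registers its parameters (tagged tensor
# nodes) in a shared store so the optimizer, the parameter counter and the
# tests (which zero whole sub-modules by tag) can address them uniformly.

newStore <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$tags <- character()
  e$bnStates <- list()
  e
}

addParam <- function(store, arr, tag) {
  p <- tnode(arr)
  p$param <- TRUE
  store$params[[length(store$params) + 1L]] <- p
  store$tags <- c(store$tags, tag)
  p
}

#' @noRd
storeParamCount <- function(store) {
  sum(vapply(store$params, function(p) length(p$v), numeric(1)))
}

# Zero every parameter whose tag matches `pattern` (regex). Used by the
# residual-identity checks: a zeroed sub-network must vanish from the output.
zeroParamsByTag <- function(store, pattern) {
  hit <- grepl(pattern, store$tags)
  for (i in which(hit)) {
    p <- store$params[[i]]
    p$v <- p$v * 0
  }
  invisible(sum(hit))
}

kaimingUniform <- function(kh, kw, cin, cout) {
  bound <- sqrt(6 / (kh * kw * cin))
  array(stats::runif(kh * kw * cin * cout, -bound, bound),
        c(kh, kw, cin, cout))
}

convLayer <- function(store, tag, cin, cout, k = 3L, stride = 1L,
                      dilation = 1L, bias = FALSE) {
  pad <- as.integer(dilation * (k - 1) / 2)
  w <- addParam(store, kaimingUniform(k, k, cin, cout), paste0(tag, ".w"))
  b <- if (bias) addParam(store, numeric(cout), paste0(tag, ".b")) else NULL
  list(
    w = w, b = b,
    fwd = function(x) tConv(x, w, b, stride = stride, pad = pad,
                            dilation = dilation)
  )
}

bnLayer <- function(store, tag, C, eps = 1e-5, momentum = 0.1) {
  gamma <- addParam(store, rep(1, C), paste0(tag, ".gamma"))
  beta <- addParam(store, rep(0, C), paste0(tag, ".beta"))
  st <- new.env(parent = emptyenv())
  st$rm <- rep(0, C)
  st$rv <- rep(1, C)
  store$bnStates[[tag]] <- st
  fwd <- function(x, training) {
    if (training) {
      r <- cppBnForward(x$v, gamma$v, beta$v, eps)
      v <- 1 / r$invstd^2 - eps
      st$rm <- (1 - momentum) * st$rm + momentum * r$mean
      st$rv <- (1 - momentum) * st$rv + momentum * v
      xv <- x$v
      tnode(r$y, list(x, gamma, beta), function(g) {
        cb <- cppBnBackward(xv, gamma$v, r$mean, r$invstd, g)
        list(cb$gx, cb$ggamma, cb$gbeta)
      })
    } else {
      d <- dim(x$v)
      plane <- d[1] * d[2]
      a <- gamma$v / sqrt(st$rv + eps)
      fa <- rep(a, each = plane)   # recycles across batch
      off <- rep(beta$v - a * st$rm, each = plane)
      xv <- x$v
      tnode(x$v * fa + off, list(x, gamma, beta), function(g) {
        gm <- g * (xv - rep(st$rm, each = plane)) /
          rep(sqrt(st$rv + eps), each = plane)
        dim(gm) <- c(plane, d[3], d[4])
        gb <- g
        dim(gb) <- c(plane, d[3], d[4])
        list(g * fa, rowSums(colSums(gm)), rowSums(colSums(gb)))
      })
    }
  }
  list(gamma = gamma, beta = beta, state = st, fwd = fwd)
}

# conv -> batch norm -> ReLU (no conv bias; the norm supplies the shift)
convBnRelu <- function(store, tag, cin, cout, k = 3L, stride = 1L,
                       dilation = 1L, ctx) {
  cv <- convLayer(store, tag, cin, cout, k, stride, dilation, bias = FALSE)
  bn <- bnLayer(store, tag, cout)
  list(
    conv = cv, bn = bn,
    fwd = function(x) tRelu(bn$fwd(cv$fwd(x), ctx$training))
  )
}

#' Channel self-attention head
#'
#' Squeezes a feature map to one descriptor per channel by global average
#' pooling, passes it through a two-layer 1x1-convolution bottleneck
#' (reduction factor \code{reduction}) with ReLU, and maps to per-channel
#' weights in \[0, 1\] via a sigmoid.
#'
#' @param C number of input channels.
#' @param reduction bottleneck reduction factor (default 4).
#' @param store optional parameter store; a private one is created if omitted.
#' @param tag tag prefix for the registered parameters.
#' @return A module list; call \code{applyChannelAttention(mod, x)} on an
#'   (H, W, C, N) array to obtain a (1, 1, C, N) weight array.
#' @export
newChannelAttention <- function(C, reduction = 4L, store = NULL,
                                tag = "catt") {
  if (is.null(store)) store <- newStore()
  cr <- max(1L, as.integer(C / reduction))
  c1 <- convLayer(store, paste0(tag, ".fc1"), C, cr, k = 1L, bias = TRUE)
  c2 <- convLayer(store, paste0(tag, ".fc2"), cr, C, k = 1L, bias = TRUE)
  structure(list(store = store, c1 = c1, c2 = c2,
                 fwd = function(x) {
                   tSigmoid(c2$fwd(tRelu(c1$fwd(tGlobalAvg(x)))))
                 }),
            class = "sodChannelAttention")
}

#' Spatial self-attention head
#'
#' Squeezes channels to a two-plane map (per-pixel mean and maximum over
#' channels), applies a 3x3 convolution and a sigmoid, yielding one weight in
#' \[0, 1\] per spatial location.
#'
#' @inheritParams newChannelAttention
#' @return A module list; call \code{applySpatialAttention(mod, x)} on an
#'   (H, W, C, N) array to obtain an (H, W, 1, N) weight array.
#' @export
newSpatialAttention <- function(store = NULL, tag = "satt") {
  if (is.null(store)) store <- newStore()
  cv <- convLayer(store, paste0(tag, ".conv"), 2L, 1L, k = 3L, bias = TRUE)
  structure(list(store = store, conv = cv,
                 fwd = function(x) tSigmoid(cv$fwd(tChannelSqueeze(x)))),
            class = "sodSpatialAttention")
}

checkActivations <- function(x) {
  if (!all(is.finite(x))) stop("invalid activations")
  invisible(x)
}

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("expected an (H, W, C, N) array")
  dim(x) <- d
  x
}

#' Apply a channel-attention head to a feature map
#'
#' @param mod module from \code{\link{newChannelAttention}}.
#' @param x numeric array (H, W, C) or (H, W, C, N) of finite activations.
#' @return numeric array (1, 1, C, N) of per-channel weights in \[0, 1\].
#' @export
applyChannelAttention <- function(mod, x) {
  x <- as4d(x)
  checkActivations(x)
  mod$fwd(tnode(x))$v
}

#' Apply a spatial-attention head to a feature map
#'
#' @param mod module from \code{\link{newSpatialAttention}}.
#' @inheritParams applyChannelAttention
#' @return numeric array (H, W, 1, N) of per-location weights in \[0, 1\].
#' @export
applySpatialAttention <- function(mod, x) {
  x <- as4d(x)
  checkActivations(x)
  mod$fwd(tnode(x))$v
}
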