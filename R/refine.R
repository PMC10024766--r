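# Residual refinement module (RFM): a small symmetric encoder-decoder that
# maps the coarse probability map to a residual correction in logit space.
# Encoder stages carry 4, 8, 16, 24, 36 filters of size 3x3 (one conv-BN-ReLU
# per stage, 2x2 max pooling between stages); the decoder mirrors the
# schedule (36, 24, 16, 8, 4) with bilinear 2x upsampling; a final 3x3 conv
# produces the single-channel residual.

buildRFM <- function(store, ctx, filters = c(4L, 8L, 16L, 24L, 36L)) {
  if (length(filters) != 5L) stop("RFM requires 5 encoder filter counts")
  nf <- length(filters)
  encConvs <- vector("list", nf)
  cin <- 1L
  for (s in seq_len(nf)) {
    encConvs[[s]] <- convBnRelu(store, sprintf("rfm.enc%d", s), cin,
                                filters[s], ctx = ctx)
    cin <- filters[s]
  }
  decFilters <- rev(filters)
  decConvs <- vector("list", nf)
  for (s in seq_len(nf)) {
    cout <- decFilters[s]
    decConvs[[s]] <- convBnRelu(store, sprintf("rfm.dec%d", s), cin, cout,
                                ctx = ctx)
    cin <- cout
  }
  outConv <- convLayer(store, "rfm.out", cin, 1L, k = 3L, bias = TRUE)

  fwd <- function(coarse) {
    h <- coarse
    for (s in seq_len(nf)) {
      h <- encConvs[[s]]$fwd(h)
      if (s < nf) h <- tMaxPool2(h)
    }
    for (s in seq_len(nf)) {
      h <- decConvs[[s]]$fwd(h)
      if (s < nf) {
        d <- dim(h$v)
        h <- tBilinear(h, 2L * d[1], 2L * d[2])
      }
    }
    outConv$fwd(h)
  }
  list(fwd = fwd, filters = filters, decFilters = decFilters)
}
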