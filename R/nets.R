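# Pluggable classification networks. The desk-scale default is a small
# 4-block CNN so the full pipeline trains on one CPU; the configuration
# mirrors the reference setup (Inception-style classifier + ResNet-style
# auxiliaries) only in role, not in size. Inputs of side 224 are first
# 4x average-pooled to 56 to keep the arithmetic desk-scale.

# Plain conv blocks (no normalization): with a per-slide forward pass any
# single-image batch norm degenerates to instance normalization, which
# strips exactly the slide-level statistics the classifier must read.
init_small_cnn <- function(model, prefix, widths = c(16, 32, 32, 64), cin = 3) {
  cs <- c(cin, widths)
  for (i in seq_along(widths)) {
    pre <- sprintf("%s.b%d", prefix, i)
    model$params[[paste0(pre, ".w")]] <- he_init(3, 3, cs[i], cs[i + 1])
    model$params[[paste0(pre, ".b")]] <- numeric(cs[i + 1])
  }
  invisible(NULL)
}

# (side, side, 3) node -> feature vector node (length = 2 * last width).
# Average pooling summarizes tissue context; max pooling keeps point
# anomalies (a lesion a few pixels wide barely moves a 7x7 average).
small_cnn_fwd <- function(tape, model, x, prefix, widths, training) {
  d <- dim(ad_value(x))
  if (d[1] > 56) x <- ad_avgpool(tape, x, as.integer(d[1] / 56))
  h <- x
  for (i in seq_along(widths)) {
    pre <- sprintf("%s.b%d", prefix, i)
    h <- ad_relu(tape, ad_conv2d(tape, h,
                                 pnode(tape, model, paste0(pre, ".w")),
                                 pnode(tape, model, paste0(pre, ".b")),
                                 pad = 1L))
    if (i < length(widths)) h <- ad_maxpool(tape, h, 2L, 2L, 0L)
  }
  ad_cat(tape, list(ad_gap(tape, h), ad_gmp(tape, h)))
}

glorot <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / (nin + nout))), nout, nin)
}

init_dense <- function(model, prefix, nin, nout) {
  model$params[[paste0(prefix, ".w")]] <- glorot(nout, nin)
  model$params[[paste0(prefix, ".b")]] <- numeric(nout)
  invisible(NULL)
}

dense_fwd <- function(tape, model, x, prefix) {
  ad_add(tape, ad_matvec(tape, pnode(tape, model, paste0(prefix, ".w")), x),
         pnode(tape, model, paste0(prefix, ".b")))
}

init_gru <- function(model, prefix, nin, nh) {
  for (g in c("z", "r", "n")) {
    model$params[[sprintf("%s.W%s", prefix, g)]] <- glorot(nh, nin)
    model$params[[sprintf("%s.U%s", prefix, g)]] <- glorot(nh, nh)
    model$params[[sprintf("%s.b%s", prefix, g)]] <- numeric(nh)
  }
  invisible(NULL)
}

# standard GRU cell over a list of feature nodes; returns the last hidden state
gru_fwd <- function(tape, model, xs, prefix, nh) {
  h <- ad_const(tape, numeric(nh))
  for (x in xs) {
    z <- ad_sigmoid(tape, ad_add(tape, ad_add(tape,
           ad_matvec(tape, pnode(tape, model, paste0(prefix, ".Wz")), x),
           ad_matvec(tape, pnode(tape, model, paste0(prefix, ".Uz")), h)),
           pnode(tape, model, paste0(prefix, ".bz"))))
    r <- ad_sigmoid(tape, ad_add(tape, ad_add(tape,
           ad_matvec(tape, pnode(tape, model, paste0(prefix, ".Wr")), x),
           ad_matvec(tape, pnode(tape, model, paste0(prefix, ".Ur")), h)),
           pnode(tape, model, paste0(prefix, ".br"))))
    n <- ad_tanh(tape, ad_add(tape, ad_add(tape,
           ad_matvec(tape, pnode(tape, model, paste0(prefix, ".Wn")), x),
           ad_mul(tape, r,
                  ad_matvec(tape, pnode(tape, model, paste0(prefix, ".Un")), h))),
           pnode(tape, model, paste0(prefix, ".bn"))))
    one_minus_z <- ad_sub(tape, 1, z)
    h <- ad_add(tape, ad_mul(tape, one_minus_z, n), ad_mul(tape, z, h))
  }
  h
}
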