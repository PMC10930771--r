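# Minimal reverse-mode autodiff on a linear tape.
#
# Nodes are environments holding a value `v`, an accumulated gradient `g`
# and a backward closure `bwd`; the tape records tracked nodes in creation
# order and `ad_backward()` sweeps it in reverse. Constants are never
# recorded, so evaluation-mode forward passes carry no tape overhead
# (`ad_tape(grad = FALSE)`). Heavy kernels (convolution, pooling, sampling)
# are dispatched to C++.

#' Create an autodiff tape
#'
#' @param grad logical; record operations for a later backward sweep.
#' @return a tape environment.
#' @keywords internal
ad_tape <- function(grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$grad <- isTRUE(grad)
  tp$params <- list()
  tp
}

is_node <- function(x) is.environment(x)

#' @keywords internal
ad_value <- function(x) if (is_node(x)) x$v else x

node_new <- function(tape, v, parents = NULL, bwd = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  tracked <- FALSE
  if (!is.null(parents) && tape$grad) {
    for (p in parents) if (is_node(p) && p$track) { tracked <- TRUE; break }
  }
  nd$track <- tracked
  if (tracked) {
    nd$parents <- parents
    nd$bwd <- bwd
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

#' @keywords internal
ad_const <- function(tape, v) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v; nd$g <- NULL; nd$track <- FALSE
  nd
}

# Parameter leaf. `name` keys the gradient when it is harvested after the
# backward sweep.
#' @keywords internal
ad_param <- function(tape, v, name) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v; nd$g <- NULL
  nd$track <- tape$grad
  nd$name <- name
  if (tape$grad) tape$params[[name]] <- nd
  nd
}

gadd <- function(p, g) {
  if (is_node(p) && p$track)
    p$g <- if (is.null(p$g)) g else p$g + g
  invisible(NULL)
}

#' Run the backward sweep from a scalar node
#' @keywords internal
ad_backward <- function(tape, root) {
  stopifnot(length(root$v) == 1L)
  root$g <- 1
  if (tape$n == 0L) return(invisible(NULL))
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$bwd)) nd$bwd(nd)
  }
  invisible(NULL)
}

#' Collect parameter gradients from a tape into a named list
#' @keywords internal
ad_grads <- function(tape) {
  out <- list()
  for (nm in names(tape$params)) {
    g <- tape$params[[nm]]$g
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

# --- elementwise / reduction ops --------------------------------------------

ad_add <- function(tape, a, b) {
  node_new(tape, ad_value(a) + ad_value(b), list(a, b), function(nd) {
    g <- nd$g
    gadd(a, if (length(ad_value(a)) == 1L) sum(g) else g)
    gadd(b, if (length(ad_value(b)) == 1L) sum(g) else g)
  })
}

ad_sub <- function(tape, a, b) {
  node_new(tape, ad_value(a) - ad_value(b), list(a, b), function(nd) {
    g <- nd$g
    gadd(a, if (length(ad_value(a)) == 1L) sum(g) else g)
    gadd(b, if (length(ad_value(b)) == 1L) -sum(g) else -g)
  })
}

ad_mul <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  node_new(tape, av * bv, list(a, b), function(nd) {
    g <- nd$g
    gadd(a, if (length(av) == 1L) sum(g * bv) else g * bv)
    gadd(b, if (length(bv) == 1L) sum(g * av) else g * av)
  })
}

ad_scale <- function(tape, a, k) {
  node_new(tape, ad_value(a) * k, list(a), function(nd) gadd(a, nd$g * k))
}

ad_sum <- function(tape, a) {
  node_new(tape, sum(ad_value(a)), list(a), function(nd) {
    gadd(a, array(nd$g, dim = dim(ad_value(a)) %||% length(ad_value(a))))
  })
}

ad_mean <- function(tape, a) {
  n <- length(ad_value(a))
  node_new(tape, sum(ad_value(a)) / n, list(a), function(nd) {
    gadd(a, array(nd$g / n, dim = dim(ad_value(a)) %||% n))
  })
}

# sum(a * w) with a constant weight array
ad_dot <- function(tape, a, w) {
  node_new(tape, sum(ad_value(a) * w), list(a), function(nd) gadd(a, nd$g * w))
}

ad_abs <- function(tape, a) {
  av <- ad_value(a)
  node_new(tape, abs(av), list(a), function(nd) gadd(a, nd$g * sign(av)))
}

ad_tanh <- function(tape, a) {
  y <- tanh(ad_value(a))
  node_new(tape, y, list(a), function(nd) gadd(a, nd$g * (1 - y * y)))
}

ad_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-ad_value(a)))
  node_new(tape, y, list(a), function(nd) gadd(a, nd$g * y * (1 - y)))
}

ad_relu <- function(tape, a) {
  av <- ad_value(a)
  m <- av > 0
  node_new(tape, av * m, list(a), function(nd) gadd(a, nd$g * m))
}

# max(a, c) elementwise with constant c; subgradient at the tie goes to a=0
ad_clamp_min <- function(tape, a, c) {
  av <- ad_value(a)
  m <- av > c
  node_new(tape, pmax(av, c), list(a), function(nd) gadd(a, nd$g * m))
}

ad_log <- function(tape, a) {
  av <- ad_value(a)
  node_new(tape, log(av), list(a), function(nd) gadd(a, nd$g / av))
}

# reshape an (N, 3) sample matrix to (side, side, 3) and apply the grey
# filter; the kept-pixel mask acts as a constant in the backward pass
ad_sample_post <- function(tape, x, side, tau) {
  r <- cpp_grey_apply(ad_value(x), tau)
  keep <- as.numeric(r$keep)
  node_new(tape, array(r$y, dim = c(side, side, 3L)), list(x), function(nd) {
    gadd(x, matrix(nd$g, side * side, 3L) * keep)
  })
}

# multiply by a constant mask (grey filter, padding masks)
ad_mask <- function(tape, a, m) {
  node_new(tape, ad_value(a) * m, list(a), function(nd) gadd(a, nd$g * m))
}

ad_reshape <- function(tape, a, dims) {
  av <- ad_value(a)
  y <- array(av, dim = dims)
  node_new(tape, y, list(a), function(nd) {
    g <- nd$g
    gadd(a, array(g, dim = dim(av) %||% length(av)))
  })
}

# --- linear algebra ---------------------------------------------------------

# W %*% x for a matrix W and vector x
ad_matvec <- function(tape, W, x) {
  Wv <- ad_value(W); xv <- ad_value(x)
  node_new(tape, as.numeric(Wv %*% xv), list(W, x), function(nd) {
    g <- nd$g
    gadd(W, outer(g, xv))
    gadd(x, as.numeric(crossprod(Wv, g)))
  })
}

ad_cat <- function(tape, xs) {
  vs <- lapply(xs, ad_value)
  lens <- vapply(vs, length, 1L)
  node_new(tape, unlist(vs, use.names = FALSE), xs, function(nd) {
    off <- 0L
    for (i in seq_along(xs)) {
      gadd(xs[[i]], nd$g[(off + 1L):(off + lens[i])])
      off <- off + lens[i]
    }
  })
}

# concatenate (H, W, C_i) arrays along channels
ad_concat_c <- function(tape, xs) {
  vs <- lapply(xs, ad_value)
  d <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[3], 1L)
  y <- array(unlist(vs, use.names = FALSE), dim = c(d[1], d[2], sum(cs)))
  node_new(tape, y, xs, function(nd) {
    off <- 0L
    for (i in seq_along(xs)) {
      gadd(xs[[i]], nd$g[, , (off + 1L):(off + cs[i]), drop = FALSE])
      off <- off + cs[i]
    }
  })
}

# --- conv / pool / norm -----------------------------------------------------

ad_conv2d <- function(tape, x, w, b, pad) {
  xv <- ad_value(x); wv <- ad_value(w); bv <- ad_value(b)
  if (!tape$grad)
    return(node_new(tape, cpp_conv2d_fwd(xv, wv, bv, pad), NULL, NULL))
  r <- cpp_conv2d_fwd_col(xv, wv, bv, pad)  # keep im2col for the backward
  node_new(tape, r$y, list(x, w, b), function(nd) {
    gr <- cpp_conv2d_bwd_col(r$col, wv, nd$g, dim(xv), pad)
    gadd(x, gr$gx); gadd(w, gr$gw); gadd(b, gr$gb)
  })
}

ad_maxpool <- function(tape, x, k, stride, pad) {
  xv <- ad_value(x)
  r <- cpp_maxpool_fwd(xv, k, stride, pad)
  node_new(tape, r$y, list(x), function(nd) {
    gadd(x, cpp_maxpool_bwd(nd$g, r$argmax, dim(xv)))
  })
}

ad_avgpool <- function(tape, x, k) {
  xv <- ad_value(x)
  node_new(tape, cpp_avgpool_fwd(xv, k), list(x), function(nd) {
    gadd(x, cpp_avgpool_bwd(nd$g, k, dim(xv)))
  })
}

# global max pool (H, W, C) -> length-C vector; gradient to the argmax
ad_gmp <- function(tape, x) {
  xv <- ad_value(x)
  d <- dim(xv)
  n <- d[1] * d[2]
  xm <- matrix(xv, n, d[3])
  idx <- max.col(t(xm), ties.method = "first")
  y <- xm[cbind(idx, seq_len(d[3]))]
  node_new(tape, y, list(x), function(nd) {
    g <- array(0, dim = d)
    g[cbind((idx - 1L) %% d[1] + 1L, (idx - 1L) %/% d[1] + 1L,
            seq_len(d[3]))] <- nd$g
    gadd(x, g)
  })
}

# global average pool (H, W, C) -> length-C vector
ad_gap <- function(tape, x) {
  xv <- ad_value(x)
  d <- dim(xv)
  n <- d[1] * d[2]
  y <- colMeans(matrix(xv, n, d[3]))
  node_new(tape, y, list(x), function(nd) {
    g <- array(rep(nd$g / n, each = n), dim = d)
    gadd(x, g)
  })
}

# Spatial batch normalization over one image (statistics over H x W per
# channel). `state` is an environment carrying running_mean / running_var,
# updated in place during training and used verbatim in evaluation mode.
ad_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ad_value(x)
  d <- dim(xv)
  n <- d[1] * d[2]
  if (training) {
    xm <- matrix(xv, n, d[3])
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  gv <- ad_value(gamma); bv <- ad_value(beta)
  y <- cpp_bn_fwd(xv, mu, istd, gv, bv)
  node_new(tape, y, list(x, gamma, beta), function(nd) {
    # standard batch-norm backward (through the batch statistics when
    # training); evaluation mode treats mu/istd as constants
    r <- cpp_bn_bwd(xv, mu, istd, gv, nd$g, training)
    gadd(x, r$gx); gadd(gamma, r$ggamma); gadd(beta, r$gbeta)
  })
}

# --- sampling ---------------------------------------------------------------

# plain bilinear sampling at normalized points (align-corners)
ad_bilinear <- function(tape, img, gx, gy) {
  iv <- ad_value(img); gxv <- ad_value(gx); gyv <- ad_value(gy)
  y <- cpp_bilinear_fwd(iv, gxv, gyv)
  node_new(tape, y, list(img, gx, gy), function(nd) {
    gr <- cpp_bilinear_bwd(iv, gxv, gyv, nd$g)
    gadd(img, gr$gimg); gadd(gx, gr$ggx); gadd(gy, gr$ggy)
  })
}

# linearized multi-sampling; jitter offsets are generated in C++ from
# `seed` and regenerated identically in the backward pass
ad_linsample <- function(tape, img, gx, gy, k, noise_sd, seed) {
  iv <- ad_value(img); gxv <- ad_value(gx); gyv <- ad_value(gy)
  y <- cpp_linsample_fwd(iv, gxv, gyv, k, noise_sd, seed)
  need_gimg <- is_node(img) && img$track
  node_new(tape, y, list(img, gx, gy), function(nd) {
    gr <- cpp_linsample_bwd(iv, gxv, gyv, k, noise_sd, seed, nd$g, need_gimg)
    if (need_gimg) gadd(img, gr$gimg)
    gadd(gx, gr$ggx); gadd(gy, gr$ggy)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
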