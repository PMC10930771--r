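# Differentiable hard-attention core: Branch convolution stacks, spatial
# sparsemax localization, affine-parameter inference and constraints, grid
# generation, and linearized multi-sampling.

#' Sparsemax
#'
#' Euclidean projection of a vector onto the probability simplex
#' (Martins & Astudillo). Unlike softmax it can return exact zeros, giving
#' sparse spatial attention maps; it is shift-invariant and order-preserving.
#'
#' @param z numeric vector of finite values.
#' @return a probability vector of the same length.
#' @export
sparsemax <- function(z) {
  if (length(z) == 0) stop("sparsemax of empty input")
  zs <- sort(z, decreasing = TRUE)
  css <- cumsum(zs)
  k <- max(which(1 + seq_along(zs) * zs > css))
  tau <- (css[k] - 1) / k
  pmax(z - tau, 0)
}

# tape op; backward: g - mean(g over the support), on the support
ad_sparsemax <- function(tape, z) {
  p <- sparsemax(ad_value(z))
  supp <- p > 0
  ns <- sum(supp)
  node_new(tape, p, list(z), function(nd) {
    g <- nd$g
    gs <- sum(g[supp]) / ns
    gz <- numeric(length(p))
    gz[supp] <- g[supp] - gs
    gadd(z, gz)
  })
}

# --- Branch: five parallel conv paths + maxpool path ------------------------
#
# Paths (each Conv2D = convolution + batch norm + ReLU, 3x3 convs padded 1):
#   1: 1x1
#   2: 1x1 -> 3x3
#   3: 1x1 -> 3x3 -> 3x3
#   4: 1x1 -> 3x3 -> 3x3 -> 3x3
#   5: MaxPool(3x3, stride 1, pad 1) -> 1x1
# Outputs are concatenated along channels and projected to one channel by a
# final 1x1 convolution; a spatial sparsemax over the flattened map yields
# the attention distribution. Every patch slot has its own Branch.

branch_path_specs <- function(width) {
  list(p1 = list(c(1, width)),
       p2 = list(c(1, width), c(3, width)),
       p3 = list(c(1, width), c(3, width), c(3, width)),
       p4 = list(c(1, width), c(3, width), c(3, width), c(3, width)),
       p5 = list(c(1, width)))  # after the maxpool
}

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

add_conv_block <- function(model, prefix, k, cin, cout) {
  model$params[[paste0(prefix, ".w")]] <- he_init(k, k, cin, cout)
  model$params[[paste0(prefix, ".b")]] <- numeric(cout)
  model$params[[paste0(prefix, ".g")]] <- rep(1, cout)
  model$params[[paste0(prefix, ".be")]] <- numeric(cout)
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(cout)
  st$running_var <- rep(1, cout)
  model$states[[prefix]] <- st
  invisible(NULL)
}

init_branch <- function(model, key, cin = 3, width = 16) {
  specs <- branch_path_specs(width)
  for (pn in names(specs)) {
    c_in <- cin
    for (i in seq_along(specs[[pn]])) {
      k <- specs[[pn]][[i]][1]; cout <- specs[[pn]][[i]][2]
      add_conv_block(model, sprintf("%s.%s.c%d", key, pn, i), k, c_in, cout)
      c_in <- cout
    }
  }
  # final single-channel projection (no BN/ReLU: sparsemax needs raw scores)
  model$params[[paste0(key, ".proj.w")]] <-
    array(stats::rnorm(5 * width, 0, 0.01), dim = c(1, 1, 5 * width, 1))
  model$params[[paste0(key, ".proj.b")]] <- 0
  invisible(NULL)
}

# fetch-or-create the tape node of a named parameter (shared within a tape)
pnode <- function(tape, model, name) {
  nd <- tape$params[[name]]
  if (!is.null(nd)) return(nd)
  v <- model$params[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  ad_param(tape, v, name)
}

conv_block_fwd <- function(tape, model, x, prefix, k, training) {
  y <- ad_conv2d(tape, x, pnode(tape, model, paste0(prefix, ".w")),
                 pnode(tape, model, paste0(prefix, ".b")),
                 pad = if (k == 3) 1L else 0L)
  y <- ad_batchnorm(tape, y, pnode(tape, model, paste0(prefix, ".g")),
                    pnode(tape, model, paste0(prefix, ".be")),
                    model$states[[prefix]], training)
  ad_relu(tape, y)
}

# Branch forward: 56x56x3 -> sparsemax attention map node (56, 56)
branch_fwd <- function(tape, model, x, key, width, training) {
  specs <- branch_path_specs(width)
  outs <- vector("list", 5)
  for (pi in 1:5) {
    pn <- names(specs)[pi]
    h <- if (pi == 5) ad_maxpool(tape, x, 3L, 1L, 1L) else x
    for (i in seq_along(specs[[pn]])) {
      k <- specs[[pn]][[i]][1]
      h <- conv_block_fwd(tape, model, h, sprintf("%s.%s.c%d", key, pn, i),
                          k, training)
    }
    outs[[pi]] <- h
  }
  cc <- ad_concat_c(tape, outs)
  score <- ad_conv2d(tape, cc, pnode(tape, model, paste0(key, ".proj.w")),
                     pnode(tape, model, paste0(key, ".proj.b")), pad = 0L)
  d <- dim(ad_value(x))
  flat <- ad_reshape(tape, score, d[1] * d[2])
  p <- ad_sparsemax(tape, flat)
  ad_reshape(tape, p, c(d[1], d[2]))
}

#' Localize: attention map of a view
#'
#' Runs one Branch (five parallel convolution paths plus a max-pool path,
#' concatenated and projected to a single channel) followed by a spatial
#' sparsemax, producing a `(side, side)` attention map that sums to one.
#'
#' @param view numeric `(side, side, 3)` image (filtered and resize-padded).
#' @param model a model created by [magnet_init()].
#' @param key branch key (the trace name of the patch being extracted,
#'   e.g. `"I11"`).
#' @return the attention map.
#' @export
localize <- function(view, model, key) {
  tape <- ad_tape(grad = FALSE)
  ad_value(branch_fwd(tape, model, view, key, model$config$branch_width,
                      training = FALSE))
}

# --- affine parameter inference ---------------------------------------------

# normalized cell-center coordinate of cell i (0-based) on an n-cell axis
cell_centers <- function(n) (2 * seq_len(n) - 1) / n - 1

#' Infer raw affine parameters from an attention map
#'
#' With cell-center coordinates `u_i = (2i+1)/n - 1` on each axis, the
#' translations are the attention-weighted expected coordinates and the raw
#' scale is the expected L1 deviation from that centroid:
#' `s_raw = E_p(|u_x - tx| + |u_y - ty|)`. A point mass yields `s_raw = 0`
#' (maximal zoom, floored later); a uniform map yields `s_raw ~ 1` (no zoom).
#'
#' @param map non-negative `(n, n)` matrix summing to 1 (tolerance `1e-6`).
#' @return list with `s_raw`, `tx_raw`, `ty_raw`.
#' @export
infer_affine_params <- function(map) {
  if (abs(sum(map) - 1) > 1e-6 || any(map < 0))
    stop("attention map must be a normalized non-negative distribution")
  n <- nrow(map)
  ux <- matrix(cell_centers(ncol(map)), n, ncol(map), byrow = TRUE)
  uy <- matrix(cell_centers(n), n, ncol(map))
  tx <- sum(map * ux)
  ty <- sum(map * uy)
  s <- sum(map * (abs(ux - tx) + abs(uy - ty)))
  list(s_raw = s, tx_raw = tx, ty_raw = ty)
}

# tape version: map node (n, n) -> list of scalar nodes
ad_infer_affine <- function(tape, map) {
  mv <- ad_value(map)
  n <- nrow(mv)
  ux <- matrix(cell_centers(ncol(mv)), n, ncol(mv), byrow = TRUE)
  uy <- matrix(cell_centers(n), n, ncol(mv))
  tx <- ad_dot(tape, map, ux)
  ty <- ad_dot(tape, map, uy)
  dx <- ad_abs(tape, ad_sub(tape, ux, tx))
  dy <- ad_abs(tape, ad_sub(tape, uy, ty))
  s <- ad_sum(tape, ad_mul(tape, map, ad_add(tape, dx, dy)))
  list(s_raw = s, tx_raw = tx, ty_raw = ty)
}

#' Constrain affine parameters
#'
#' `s = max(s_raw, 0.05)` (the floor counters vanishing gradients early in
#' training), `tx = tanh(tx_raw)`, `ty = tanh(ty_raw)` (favors center
#' extraction), assembled into the 2x3 matrix
#' `theta = [[s, 0, tx], [0, s, ty]]`.
#'
#' @param s_raw,tx_raw,ty_raw raw parameters from [infer_affine_params()].
#' @return an `affine_params` object with fields `s`, `tx`, `ty`, `theta`.
#' @export
constrain_params <- function(s_raw, tx_raw, ty_raw) {
  affine_params(max(s_raw, 0.05), tanh(tx_raw), tanh(ty_raw))
}

#' Affine crop parameters
#' @param s isotropic scale (>= 0.05 after constraining).
#' @param tx,ty translations in normalized view coordinates.
#' @export
affine_params <- function(s, tx, ty) {
  structure(list(s = s, tx = tx, ty = ty,
                 theta = matrix(c(s, 0, 0, s, tx, ty), 2, 3)),
            class = "affine_params")
}

ad_constrain <- function(tape, raw) {
  list(s = ad_clamp_min(tape, raw$s_raw, 0.05),
       tx = ad_tanh(tape, raw$tx_raw),
       ty = ad_tanh(tape, raw$ty_raw))
}

#' Sampling grid from affine parameters
#'
#' Multiplies theta with an `out_side x out_side` meshgrid spanning
#' `[-1, 1]^2`: `x = s * gx + tx`, `y = s * gy + ty`.
#'
#' @param theta an [affine_params()].
#' @param out_side grid side in points.
#' @return list with `gx`, `gy` (matrices, row = y) and `out_side`.
#' @export
make_grid <- function(theta, out_side) {
  base <- seq(-1, 1, length.out = out_side)
  list(gx = theta$s * matrix(base, out_side, out_side, byrow = TRUE) + theta$tx,
       gy = theta$s * matrix(base, out_side, out_side) + theta$ty,
       out_side = out_side)
}

# tape version: scalar nodes -> flattened coordinate nodes (column-major)
ad_make_grid <- function(tape, s, tx, ty, out_side) {
  base <- seq(-1, 1, length.out = out_side)
  gxc <- as.numeric(matrix(base, out_side, out_side, byrow = TRUE))
  gyc <- as.numeric(matrix(base, out_side, out_side))
  list(gx = ad_add(tape, ad_mul(tape, s, gxc), tx),
       gy = ad_add(tape, ad_mul(tape, s, gyc), ty),
       out_side = out_side)
}

#' Linearized multi-sampling
#'
#' For each grid point, `k_aux` jittered auxiliary points are drawn, the
#' image is evaluated at all points by bilinear lookup, and a local linear
#' least-squares model in (x, y) supplies both the sampled value and -- in
#' the differentiable pipeline -- coordinate gradients that stay informative
#' under heavy scaling. Out-of-range lookups return black; a degenerate fit
#' falls back to the plain bilinear value. As `noise_sd -> 0` the result
#' converges to plain bilinear sampling.
#'
#' @param image numeric `(H, W, C)` array.
#' @param grid a grid from [make_grid()].
#' @param k_aux number of auxiliary points per grid point (default 8).
#' @param noise_sd jitter standard deviation in normalized grid units
#'   (default `1/out_side`).
#' @return sampled `(out_side, out_side, C)` array.
#' @export
linearized_sample <- function(image, grid, k_aux = 8, noise_sd = NULL) {
  stopifnot(k_aux >= 1)
  n <- grid$out_side
  if (is.null(noise_sd)) noise_sd <- 1 / n
  seed <- stats::runif(1, 0, 2^31)   # ties the C++ jitter to R's RNG state
  out <- cpp_linsample_fwd(image, as.numeric(grid$gx), as.numeric(grid$gy),
                           as.integer(k_aux), noise_sd, seed)
  array(out, dim = c(n, n, dim(image)[3]))
}

#' Plain bilinear sampling on a grid (align-corners)
#' @inheritParams linearized_sample
#' @export
bilinear_sample <- function(image, grid) {
  n <- grid$out_side
  out <- cpp_bilinear_fwd(image, as.numeric(grid$gx), as.numeric(grid$gy))
  array(out, dim = c(n, n, dim(image)[3]))
}
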