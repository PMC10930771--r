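# The magnifying network: recursive patch extraction over an image pyramid
# with per-slot hard attention, a frozen whole-view patch, a recurrent
# classification head over the final 224x224 patches, and auxiliary
# slide-level classifiers on intermediate layers.
#
# Per layer l, every incoming view carries a 56x56 working image I (the
# differentiable sampler output of its parent) and a larger version I'
# freshly read from the pyramid at the level selected dynamically from the
# view's extent (112 pixels, or 224 when the view feeds the final layer).
# Localization consumes I; sampling applies the affine transform to I', so
# each extracted patch can contain finer-grain information than was present
# in I. Gradients flow into the attention branches through the sampler.

#' Model configuration
#'
#' @param layers number of magnifying layers `L`.
#' @param patches_per_layer integer vector `P_1..P_L` of patches extracted
#'   per view at each layer.
#' @param frozen_patch freeze the first patch of the second layer to the
#'   identity transform so it always attends to the whole input view.
#' @param backbone `"small-cnn"` (desk-scale default; 4 conv blocks).
#' @param backbone_widths channel widths of the 4 backbone blocks.
#' @param branch_width channels of each Branch convolution path (5 paths are
#'   concatenated before the single-channel projection).
#' @param gru_hidden GRU hidden size.
#' @param head_sizes the two fully connected head widths.
#' @param k_aux auxiliary points per grid point for linearized sampling.
#' @param noise_sd sampling jitter in grid units (default `1/out_side`).
#' @param grey_tau grey-filter threshold on the 0-255 scale.
#' @return a `magnet_config` object.
#' @export
magnet_config <- function(layers = 3L, patches_per_layer = c(3L, 2L, 3L),
                          frozen_patch = TRUE, backbone = "small-cnn",
                          backbone_widths = c(16L, 32L, 32L, 64L),
                          branch_width = 16L, gru_hidden = 256L,
                          head_sizes = c(512L, 256L), k_aux = 8L,
                          noise_sd = NULL, grey_tau = 15) {
  stopifnot(layers >= 1, length(patches_per_layer) == layers,
            all(patches_per_layer >= 1))
  structure(list(L = as.integer(layers),
                 P = as.integer(patches_per_layer),
                 frozen_patch = isTRUE(frozen_patch),
                 backbone = backbone,
                 backbone_widths = as.integer(backbone_widths),
                 branch_width = as.integer(branch_width),
                 gru_hidden = as.integer(gru_hidden),
                 head_sizes = as.integer(head_sizes),
                 k_aux = as.integer(k_aux), noise_sd = noise_sd,
                 grey_tau = grey_tau,
                 in_side = 56L, hi_side = 112L, final_side = 224L),
            class = "magnet_config")
}

#' Desk-scale configuration used by the bundled tests
#'
#' A two-layer model with two patches per layer and narrow networks, sized
#' for single-CPU training on the synthetic pyramids.
#' @param ... overrides passed to [magnet_config()].
#' @export
desk_config <- function(...) {
  args <- utils::modifyList(
    list(layers = 2L, patches_per_layer = c(2L, 2L), branch_width = 8L,
         backbone_widths = c(8L, 16L, 16L, 32L), gru_hidden = 32L,
         head_sizes = c(64L, 32L), k_aux = 4L),
    list(...))
  do.call(magnet_config, args)
}

# hierarchical trace names of all extractions, by layer; root is "I1"
layer_names <- function(P) {
  out <- vector("list", length(P) + 1L)
  out[[1]] <- "I1"
  for (l in seq_along(P))
    out[[l + 1]] <- as.vector(t(outer(out[[l]], seq_len(P[l]), paste0)))
  out
}

is_frozen_slot <- function(config, layer, slot) {
  config$frozen_patch && layer == 2L && slot == 1L
}

#' Closed-form patch budget
#'
#' `n_small = 1 + sum_{l<L} prod(P_1..P_l)` images at 56x56 (the root input
#' plus every non-final-layer patch) and `n_large = prod(P)` final patches
#' at 224x224; `pixels_total` counts RGB pixels of both.
#'
#' @param config a [magnet_config()].
#' @return list with `n_small`, `n_large`, `total`, `pixels_total`.
#' @export
count_patches <- function(config) {
  P <- config$P
  L <- config$L
  n_small <- 1 + if (L > 1) sum(cumprod(P[seq_len(L - 1)])) else 0
  n_large <- prod(P)
  list(n_small = n_small, n_large = n_large, total = n_small + n_large,
       pixels_total = n_small * 56^2 * 3 + n_large * 224^2 * 3)
}

#' Initialize model weights
#'
#' Every extraction slot gets its own Branch (frozen slots excepted);
#' convolutions use He initialization and the attention projections start
#' near zero, so initial attention maps are near-uniform and the first
#' patches cover the whole view.
#'
#' @param config a [magnet_config()].
#' @param seed integer seed for the initialization draws.
#' @return a model environment with `params`, `states` and `config`.
#' @export
magnet_init <- function(config, seed = 1L) {
  model <- new.env(parent = emptyenv())
  model$params <- list()
  model$states <- list()
  model$config <- config
  with_seed(seed, {
    nm <- layer_names(config$P)
    for (l in seq_len(config$L)) {
      for (child in nm[[l + 1]]) {
        slot <- as.integer(substr(child, nchar(child), nchar(child)))
        if (!is_frozen_slot(config, l, slot))
          init_branch(model, child, cin = 3, width = config$branch_width)
      }
    }
    bw <- config$backbone_widths
    init_small_cnn(model, "head.cnn", bw)
    feat <- 2L * bw[length(bw)]   # avg + max pooled features
    init_gru(model, "head.gru", feat, config$gru_hidden)
    init_dense(model, "head.fc1", config$gru_hidden, config$head_sizes[1])
    init_dense(model, "head.fc2", config$head_sizes[1], config$head_sizes[2])
    init_dense(model, "head.fc3", config$head_sizes[2], 1)
    for (ai in seq_along(aux_layers(config))) {
      init_small_cnn(model, sprintf("aux%d.cnn", ai), bw)
      init_dense(model, sprintf("aux%d.out", ai), feat, 1)
    }
  })
  model
}

# magnifying layers whose patches feed the auxiliary classifiers
aux_layers <- function(config) {
  if (config$L >= 3) c(1L, 3L) else if (config$L == 2) c(1L, 2L) else 1L
}

# side of the larger version I' for a view at depth d (it feeds layer d+1)
hi_side_at <- function(config, depth) {
  if (depth + 1L >= config$L) config$final_side else config$hi_side
}

read_view_hi <- function(model, pyr, frame) {
  side <- hi_side_at(model$config, frame$depth)
  grey_filter(read_region(pyr, frame, side), model$config$grey_tau)
}

#' Full forward pass over one pyramid
#'
#' Reads the root view, applies the `L` magnifying layers (inferring an
#' affine crop per patch slot, composing frames, and sampling each child
#' from the freshly read larger view), then classifies the final 224x224
#' patch sequence with the CNN+GRU head. Auxiliary slide-level
#' probabilities are computed from the configured intermediate layers.
#'
#' @param model from [magnet_init()] (or a loaded checkpoint).
#' @param pyr a [pyramid_image()].
#' @param training logical; enables gradient tracking, batch-norm batch
#'   statistics and jittered linearized sampling (evaluation uses the exact
#'   zero-noise limit and running statistics, hence is deterministic).
#' @param with_aux compute the auxiliary slide-level probabilities (can be
#'   switched off for plain scoring, where only `y_hat` is needed).
#' @return list with `y_hat` (class-1 probability), `p_aux` (named class-1
#'   probabilities per auxiliary layer), `trace` (data frame: one row per
#'   materialized image with hierarchical name, parent, layer, affine
#'   parameters, source level and resolution), `leaf_frames`, and -- when
#'   `training = TRUE` -- the tape and loss-ready nodes.
#' @export
magnet_forward <- function(model, pyr, training = FALSE, with_aux = TRUE) {
  config <- model$config
  tape <- ad_tape(grad = training)
  root <- root_frame(pyr)
  I0 <- grey_filter(resize_pad(read_region(pyr, root, config$in_side),
                               config$in_side), config$grey_tau)
  trace <- list(list("I1", NA_character_, 0L, NA_real_, NA_real_, NA_real_,
                     frame_level(pyr, root), config$in_side))
  views <- list(list(name = "I1", frame = root, I = ad_const(tape, I0),
                     Ihi = NULL))
  layer_patches <- vector("list", config$L)
  leaves <- list()
  leaf_frames <- list()
  for (l in seq_len(config$L)) {
    out_side <- if (l < config$L) config$in_side else config$final_side
    new_views <- list()
    for (v in views) {
      Ihi <- ad_const(tape, read_view_hi(model, pyr, v$frame))
      for (p in seq_len(config$P[l])) {
        cname <- paste0(v$name, p)
        frozen <- is_frozen_slot(config, l, p)
        if (frozen) {
          s <- ad_const(tape, 1); tx <- ad_const(tape, 0)
          ty <- ad_const(tape, 0)
        } else {
          map <- branch_fwd(tape, model, v$I, cname, config$branch_width,
                            training)
          con <- ad_constrain(tape, ad_infer_affine(tape, map))
          s <- con$s; tx <- con$tx; ty <- con$ty
        }
        theta_v <- affine_params(ad_value(s), ad_value(tx), ad_value(ty))
        cframe <- compose_frames(v$frame, theta_v)
        grid <- ad_make_grid(tape, s, tx, ty, out_side)
        # jittered linearized sampling only where gradients flow; the frozen
        # slot's transform and source are constants, so its read is exact
        child <- if (training && !frozen) {
          sd <- config$noise_sd %||% (1 / out_side)
          ad_linsample(tape, Ihi, grid$gx, grid$gy, config$k_aux, sd,
                       stats::runif(1, 0, 2^31))
        } else {
          ad_bilinear(tape, Ihi, grid$gx, grid$gy)
        }
        child <- ad_sample_post(tape, child, out_side, config$grey_tau)
        layer_patches[[l]] <- c(layer_patches[[l]], list(child))
        trace[[length(trace) + 1L]] <-
          list(cname, v$name, l, theta_v$s, theta_v$tx, theta_v$ty,
               frame_level(pyr, cframe), out_side)
        if (l < config$L) {
          new_views[[length(new_views) + 1L]] <-
            list(name = cname, frame = cframe, I = child, Ihi = NULL)
        } else {
          leaves[[length(leaves) + 1L]] <- child
          leaf_frames[[length(leaf_frames) + 1L]] <- cframe
        }
      }
    }
    views <- new_views
  }
  # classification head: backbone features -> GRU over the canonical
  # depth-first patch order -> two-layer FCNN -> sigmoid
  yhat_node <- head_fwd(tape, model, leaves, training)
  # auxiliary classifiers
  p_aux <- list()
  if (with_aux) {
    for (ai in seq_along(aux_layers(config))) {
      al <- aux_layers(config)[ai]
      p_aux[[ai]] <- aux_fwd(tape, model, layer_patches[[al]], ai, training)
    }
    names(p_aux) <- paste0("layer", aux_layers(config))
  }
  trace_df <- data.frame(
    name = vapply(trace, function(r) r[[1]], ""),
    parent = vapply(trace, function(r) r[[2]], ""),
    layer = vapply(trace, function(r) r[[3]], 0L),
    s = vapply(trace, function(r) r[[4]], 0),
    tx = vapply(trace, function(r) r[[5]], 0),
    ty = vapply(trace, function(r) r[[6]], 0),
    level = vapply(trace, function(r) r[[7]], 0L),
    resolution = vapply(trace, function(r) r[[8]], 0L),
    stringsAsFactors = FALSE)
  res <- list(y_hat = ad_value(yhat_node),
              p_aux = vapply(p_aux, ad_value, 1),
              trace = trace_df,
              leaf_frames = leaf_frames)
  if (training) {
    res$tape <- tape
    res$nodes <- list(y_hat = yhat_node, p_aux = p_aux)
  }
  res
}

head_fwd <- function(tape, model, patches, training) {
  config <- model$config
  feats <- lapply(patches, function(pt)
    small_cnn_fwd(tape, model, pt, "head.cnn", config$backbone_widths,
                  training))
  h <- gru_fwd(tape, model, feats, "head.gru", config$gru_hidden)
  h <- ad_relu(tape, dense_fwd(tape, model, h, "head.fc1"))
  h <- ad_relu(tape, dense_fwd(tape, model, h, "head.fc2"))
  ad_sigmoid(tape, dense_fwd(tape, model, h, "head.fc3"))
}

aux_fwd <- function(tape, model, patches, ai, training) {
  config <- model$config
  ps <- lapply(patches, function(pt) {
    f <- small_cnn_fwd(tape, model, pt, sprintf("aux%d.cnn", ai),
                       config$backbone_widths, training)
    ad_sigmoid(tape, dense_fwd(tape, model, f, sprintf("aux%d.out", ai)))
  })
  ad_scale(tape, Reduce(function(a, b) ad_add(tape, a, b), ps),
           1 / length(ps))
}

#' Classification head on a patch sequence
#'
#' @param patches ordered list of `(224, 224, 3)` arrays (canonical
#'   depth-first trace order).
#' @param model a model whose head consumes the patches.
#' @return class-1 probability in (0, 1).
#' @export
classification_head <- function(patches, model) {
  if (length(patches) == 0) stop("empty patch sequence")
  tape <- ad_tape(grad = FALSE)
  nodes <- lapply(patches, function(p) ad_const(tape, p))
  ad_value(head_fwd(tape, model, nodes, training = FALSE))
}

#' Auxiliary slide-level probability of the true class
#'
#' Per-patch class-1 probabilities are averaged into one slide-level
#' probability `p`; the returned value is `p` when `y = 1` and `1 - p`
#' otherwise.
#'
#' @param patch_probs per-patch class-1 probabilities.
#' @param y binary label.
#' @export
auxiliary_predict <- function(patch_probs, y) {
  if (length(patch_probs) == 0) stop("auxiliary layer without patches")
  p <- mean(patch_probs)
  if (y == 1) p else 1 - p
}

#' Save / load a model checkpoint
#'
#' A single-file archive of the named parameter arrays, the batch-norm
#' running statistics and the configuration.
#' @param model a model environment.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  states <- lapply(model$states, function(st)
    list(running_mean = st$running_mean, running_var = st$running_var))
  saveRDS(list(params = model$params, states = states,
               config = unclass(model$config)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- new.env(parent = emptyenv())
  model$params <- ck$params
  model$config <- structure(ck$config, class = "magnet_config")
  model$states <- lapply(ck$states, function(st) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- st$running_mean
    e$running_var <- st$running_var
    e
  })
  model
}
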