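# Training loop (Adam + cosine annealing), evaluation metrics and the
# checkpointing used for validation-based model selection.

#' Training configuration
#'
#' Reference defaults: Adam, initial learning rate 3e-5 decayed by cosine
#' annealing, 200 epochs, batch size 16 (three-layer) / 8 (four-layer).
#' The desk profile ([desk_train_config()]) keeps the optimizer and
#' schedule but uses the learning rate and epoch count appropriate for
#' small from-scratch networks.
#'
#' @param lr initial learning rate.
#' @param epochs training epochs.
#' @param batch_size slides per optimizer step.
#' @param seed master seed (fans out to shuffling, augmentation draws,
#'   sampler jitter; weight initialization takes it too unless a model is
#'   passed in).
#' @param augment apply dihedral augmentation to each training slide.
#' @export
train_config <- function(lr = 3e-5, epochs = 200L, batch_size = 16L,
                         seed = 1L, augment = TRUE) {
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = isTRUE(augment)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... overrides.
#' @export
desk_train_config <- function(...) {
  do.call(train_config,
          utils::modifyList(list(lr = 1e-3, epochs = 15L, batch_size = 8L),
                            list(...)))
}

cosine_lr <- function(lr0, epoch, epochs) {
  0.5 * lr0 * (1 + cos(pi * (epoch - 1) / epochs))
}

adam_new <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_step <- function(model, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- if (is.null(st$m[[nm]])) g * 0 else st$m[[nm]]
    v <- if (is.null(st$v[[nm]])) g * 0 else st$v[[nm]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[nm]] <- m
    st$v[[nm]] <- v
    model$params[[nm]] <- model$params[[nm]] -
      lr * (m / b1t) / (sqrt(v / b2t) + eps)
  }
  invisible(NULL)
}

snapshot_model <- function(model) {
  list(params = model$params,
       states = lapply(model$states, function(st)
         list(running_mean = st$running_mean, running_var = st$running_var)))
}

restore_model <- function(model, snap) {
  model$params <- snap$params
  for (nm in names(snap$states)) {
    model$states[[nm]]$running_mean <- snap$states[[nm]]$running_mean
    model$states[[nm]]$running_var <- snap$states[[nm]]$running_var
  }
  invisible(model)
}

pyr_cache_get <- function(cache, path) {
  key <- path
  if (is.null(cache[[key]])) cache[[key]] <- read_pyramid(path)
  cache[[key]]
}

#' Train a magnifying network
#'
#' @param model_config a [magnet_config()].
#' @param train_manifest,val_manifest data frames with columns `path`
#'   (slide directory) and `label` (see [read_manifest()]).
#' @param tconf a [train_config()].
#' @param model optionally a pre-initialized model (weights are then not
#'   re-initialized).
#' @param out_dir if given, `history.csv` and `checkpoint.rds` (the best
#'   validation model) are written there.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-validation weights), `history` (one row
#'   per epoch: L1, L2, L3, total, val_auroc) and `best_epoch`.
#' @export
magnet_train <- function(model_config, train_manifest, val_manifest,
                         tconf = desk_train_config(), model = NULL,
                         out_dir = NULL, verbose = FALSE) {
  if (nrow(train_manifest) == 0) stop("empty training manifest")
  if (is.null(model)) model <- magnet_init(model_config, seed = tconf$seed)
  adam <- adam_new()
  cache <- new.env(parent = emptyenv())
  n_aux <- length(aux_layers(model$config))
  hist <- vector("list", tconf$epochs)
  best <- list(auroc = -Inf, snap = NULL, epoch = NA_integer_)
  for (epoch in seq_len(tconf$epochs)) {
    set.seed((tconf$seed * 7919L + epoch * 104729L) %% 2147483647L)
    lr <- cosine_lr(tconf$lr, epoch, tconf$epochs)
    # label-stratified order so every accumulation batch stays balanced
    pos <- sample(which(train_manifest$label == 1))
    neg <- sample(which(train_manifest$label == 0))
    k <- max(length(pos), length(neg))
    length(pos) <- k; length(neg) <- k
    ord <- as.vector(rbind(pos, neg))
    ord <- ord[!is.na(ord)]
    sums <- c(L1 = 0, L2 = 0, L3 = 0)
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + tconf$batch_size - 1L, length(ord))]
      i <- i + tconf$batch_size
      acc <- list()
      for (j in idx) {
        y <- train_manifest$label[j]
        pyr <- pyr_cache_get(cache, train_manifest$path[j])
        if (tconf$augment)
          pyr <- pyramid_augment(pyr, sample(augment_codes(), 1))
        fwd <- magnet_forward(model, pyr, training = TRUE)
        tape <- fwd$tape
        p_true <- lapply(fwd$nodes$p_aux, function(p)
          if (y == 1) p else ad_sub(tape, 1, p))
        l2 <- Reduce(function(a, b) ad_add(tape, a, b),
                     lapply(fwd$nodes$p_aux, function(p)
                       ad_bce_scalar(tape, y, p)))
        l3 <- ad_bce_scalar(tape, y, fwd$nodes$y_hat)
        loss <- ad_add(tape, l2, l3)
        l1v <- 0
        if (n_aux >= 2) {
          l1 <- ad_paradox_scalar(tape, p_true[[1]], p_true[[n_aux]])
          loss <- ad_add(tape, loss, l1)
          l1v <- ad_value(l1)
        }
        if (!is.finite(ad_value(loss)))
          stop("non-finite loss on slide ", train_manifest$path[j],
               " (epoch ", epoch, ")")
        sums <- sums + c(l1v, ad_value(l2), ad_value(l3))
        loss <- ad_scale(tape, loss, 1 / length(idx))
        ad_backward(tape, loss)
        g <- ad_grads(tape)
        for (nm in names(g))
          acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
      }
      adam_step(model, acc, adam, lr)
    }
    n <- nrow(train_manifest)
    va <- if (nrow(val_manifest) > 0) {
      ev <- magnet_evaluate(model, val_manifest, cache = cache)
      ev$auroc
    } else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, L1 = sums[1] / n,
                                L2 = sums[2] / n, L3 = sums[3] / n,
                                total = sum(sums) / n, val_auroc = va,
                                row.names = NULL)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  L1 %.4f L2 %.4f L3 %.4f  val AUROC %s",
                      epoch, lr, sums[1] / n, sums[2] / n, sums[3] / n,
                      format(va, digits = 3)))
    if (!is.na(va) && va >= best$auroc) {
      best <- list(auroc = va, snap = snapshot_model(model), epoch = epoch)
    }
  }
  if (!is.null(best$snap)) restore_model(model, best$snap)
  history <- do.call(rbind, hist)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    save_checkpoint(model, file.path(out_dir, "checkpoint.rds"))
  }
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney statistic with midranks for ties: the probability that a
#' random positive is ranked above a random negative.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return AUROC in `[0, 1]`, or `NA` for a single-class input.
#' @export
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a model on a labelled manifest
#'
#' @param model a trained model.
#' @param manifest data frame with `path` and `label` (plus optional
#'   stratum columns).
#' @param by optional column name; adds a per-stratum breakdown.
#' @param cache internal pyramid cache.
#' @return an `eval_report`: `auroc`, `accuracy` (threshold 0.5), `n`,
#'   per-slide `scores`, and `by_stratum` when requested. AUROC is `NA`
#'   for a single-class manifest.
#' @export
magnet_evaluate <- function(model, manifest, by = NULL, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  scores <- vapply(seq_len(nrow(manifest)), function(j) {
    pyr <- pyr_cache_get(cache, manifest$path[j])
    magnet_forward(model, pyr, training = FALSE, with_aux = FALSE)$y_hat
  }, 1)
  labels <- manifest$label
  rep0 <- list(auroc = auroc(scores, labels),
               accuracy = mean((scores > 0.5) == (labels == 1)),
               n = length(labels), scores = scores, labels = labels)
  if (!is.null(by) && by %in% names(manifest)) {
    strata <- split(seq_along(scores), manifest[[by]])
    rep0$by_stratum <- do.call(rbind, lapply(names(strata), function(sn) {
      ii <- strata[[sn]]
      data.frame(stratum = sn, n = length(ii),
                 auroc = auroc(scores[ii], labels[ii]),
                 accuracy = mean((scores[ii] > 0.5) == (labels[ii] == 1)),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(rep0, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: n = %d, AUROC = %s, accuracy = %.3f>\n", x$n,
              ifelse(is.na(x$auroc), "-", sprintf("%.3f", x$auroc)),
              x$accuracy))
  if (!is.null(x$by_stratum)) print(x$by_stratum)
  invisible(x)
}

#' Does a frame contain a point?
#' @param frame a [view_frame()].
#' @param x,y level-0 coordinates.
#' @export
frame_contains <- function(frame, x, y) {
  abs(x - frame$cx) <= frame$hw && abs(y - frame$cy) <= frame$hh
}
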