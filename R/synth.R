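# Synthetic labelled pyramids with planted lesions.
#
# Level 0 emulates a scanned slide: near-white glass background, a pink-ish
# textured tissue blob, grey smudge artifacts (channel spread < 15/255, so
# the grey filter provably removes them), and -- on positive slides -- a
# purple-ish high-frequency lesion placed fully inside the tissue. Lower
# levels are computed by successive 2x area-mean (box) downsampling, so a
# micro lesion is sub-pixel at the root view and only becomes visible when
# the model zooms: exactly the mechanism the method is supposed to learn.

#' Slide specification for the synthetic generator
#'
#' @param level0_side level-0 side in pixels (default 2048: the smallest
#'   pyramid whose root view matches the 56-pixel input regime while keeping
#'   a micro lesion sub-pixel at the root).
#' @param mmax number of pyramid levels (default 6).
#' @param tissue_fraction fraction of the slide covered by tissue.
#' @param lesion_scale `"macro"` (lesion diameter ~ 1/8 of the slide side) or
#'   `"micro"` (~ 1/64, invisible at the root resolution).
#' @param artifact_rate expected number of grey smudges per slide.
#' @param label binary slide label: 1 plants a lesion.
#' @return a `slide_spec` list.
#' @export
slide_spec <- function(level0_side = 2048L, mmax = 6L, tissue_fraction = 0.35,
                       lesion_scale = c("micro", "macro"), artifact_rate = 2,
                       label = 1L) {
  lesion_scale <- match.arg(lesion_scale)
  structure(list(level0_side = as.integer(level0_side), mmax = as.integer(mmax),
                 tissue_fraction = tissue_fraction, lesion_scale = lesion_scale,
                 artifact_rate = artifact_rate, label = as.integer(label)),
            class = "slide_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# bilinear lookup into a coarse noise grid at fractional positions
# (u, v in [0, 1]); mirrors the renderer's interpolation exactly
grid_lookup <- function(g, u, v) {
  n <- nrow(g)
  px <- pmin(pmax(u * n - 0.5, 0), n - 1)
  py <- pmin(pmax(v * n - 0.5, 0), n - 1)
  x0 <- floor(px); y0 <- floor(py)
  x1 <- pmin(x0 + 1, n - 1); y1 <- pmin(y0 + 1, n - 1)
  fx <- px - x0; fy <- py - y0
  (1 - fy) * ((1 - fx) * g[cbind(y0 + 1, x0 + 1)] +
              fx * g[cbind(y0 + 1, x1 + 1)]) +
    fy * ((1 - fx) * g[cbind(y1 + 1, x0 + 1)] +
          fx * g[cbind(y1 + 1, x1 + 1)])
}

#' Generate one synthetic slide
#'
#' All randomness is consumed identically for both labels, so two slides
#' generated from the same seed differ only in the painted lesion.
#'
#' @param spec a [slide_spec()].
#' @param seed integer seed fixing all randomness.
#' @return list with `pyramid` (a [pyramid_image()]) and `truth`
#'   (`label`, and for positives `lesion_center` = (x, y) level-0
#'   coordinates and `lesion_radius` in pixels).
#' @export
generate_slide <- function(spec, seed) {
  with_seed(seed, {
    S <- spec$level0_side
    # coarse noise grids; the per-pixel render happens in one C++ pass
    bg_noise <- matrix(stats::runif(64, -1, 1) * 0.015, 8, 8)
    blob_noise <- matrix(stats::runif(144, -1, 1) * 0.18, 12, 12)
    tex_noise <- matrix(stats::runif(48 * 48, -1, 1) * 0.10, 48, 48)
    fine_seed <- stats::runif(1, 0, 2^31)

    # tissue field: radial bias + smooth noise; threshold at the quantile
    # (estimated on a 256^2 subgrid) that yields the tissue fraction
    u <- (seq_len(256) - 0.5) / 256
    UU <- matrix(u, 256, 256, byrow = TRUE); VV <- matrix(u, 256, 256)
    field_at <- function(uu, vv)
      -sqrt((uu - 0.5)^2 + (vv - 0.5)^2) + grid_lookup(blob_noise, uu, vv)
    thr <- stats::quantile(field_at(as.numeric(UU), as.numeric(VV)),
                           1 - spec$tissue_fraction, names = FALSE)

    # grey smudges: channels exactly equal, so spread is 0 < 15
    n_smudge <- min(stats::rpois(1, spec$artifact_rate), 12L)
    smudge_par <- matrix(stats::runif(12 * 4), ncol = 4)  # fixed RNG budget
    smudges <- cbind(smudge_par[, 1] * S, smudge_par[, 2] * S,
                     S / 64 + smudge_par[, 3] * S / 20,
                     0.45 + smudge_par[, 4] * 0.3)[seq_len(n_smudge), ,
                                                   drop = FALSE]

    # lesion placement (drawn regardless of label so the RNG budget is
    # label-independent): center plus a ring at 1.05 r must lie in tissue
    r <- if (spec$lesion_scale == "micro") S / 128 else S / 16
    ang <- seq(0, 2 * pi, length.out = 17)[-17]
    placed <- FALSE
    for (try in 1:100) {
      cand <- stats::runif(2, r + 2, S - r - 2)
      px <- c(cand[1], cand[1] + 1.05 * r * cos(ang))
      py <- c(cand[2], cand[2] + 1.05 * r * sin(ang))
      if (all(field_at(px / S, py / S) > thr)) { placed <- TRUE; break }
    }
    speck <- stats::runif(ceiling(2 * r)^2)     # lesion speckle, fixed budget
    if (spec$label == 1L && !placed)
      stop("could not place a lesion inside tissue after 100 tries")
    base <- c(0.86, 0.58, 0.74)                 # eosin-like pink
    lbase <- c(0.44, 0.22, 0.55)                # hematoxylin-like purple
    img <- cpp_render_slide(S, bg_noise, blob_noise, tex_noise, thr, base,
                            lbase, cand[1], cand[2], r,
                            as.integer(spec$label == 1L), smudges, 0.04,
                            fine_seed, speck, 0.35)
    truth <- if (spec$label == 1L) {
      list(label = 1L, lesion_center = c(x = cand[1], y = cand[2]),
           lesion_radius = r)
    } else {
      list(label = 0L)
    }

    levels <- vector("list", spec$mmax)
    levels[[1]] <- as_raw_img(img)
    cur <- img
    for (k in 2:spec$mmax) {
      cur <- cpp_box_down2(cur)
      levels[[k]] <- as_raw_img(cur)
    }
    list(pyramid = pyramid_image(levels), truth = truth)
  })
}

#' Generate a labelled dataset of slide directories
#'
#' Labels are balanced to within one slide; per-slide seeds are derived from
#' the master seed; the split column stratifies train/validation by label.
#'
#' @param n number of slides (>= 2).
#' @param dir output directory; one subdirectory per slide plus
#'   `manifest.csv` (columns `path`, `label`, `lesion_x`, `lesion_y`,
#'   `lesion_r`, `split`).
#' @param seed master seed.
#' @param split named proportions for the split column
#'   (default `c(train = 0.8, val = 0.2)`).
#' @param ... passed to [slide_spec()] (e.g. `lesion_scale`, `level0_side`).
#' @return the manifest as a data frame, invisibly.
#' @export
generate_dataset <- function(n, dir, seed = 1L,
                             split = c(train = 0.8, val = 0.2), ...) {
  stopifnot(n >= 2)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- rep(c(1L, 0L), length.out = n)
  rows <- with_seed(seed, {
    slide_seeds <- sample.int(2147483646L, n)
    # stratified split: within each label, assign by shuffled proportions
    split_col <- character(n)
    for (lb in unique(labels)) {
      idx <- which(labels == lb)
      idx <- idx[sample.int(length(idx))]
      counts <- diff(round(cumsum(c(0, split)) * length(idx)))
      split_col[idx] <- rep(names(split), counts)
    }
    list(seeds = slide_seeds, split = split_col)
  })
  man <- data.frame(path = character(n), label = labels,
                    lesion_x = NA_real_, lesion_y = NA_real_,
                    lesion_r = NA_real_, split = rows$split,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sp <- slide_spec(label = labels[i], ...)
    sl <- generate_slide(sp, rows$seeds[i])
    sub <- sprintf("slide_%04d", i)
    write_pyramid(sl$pyramid, file.path(dir, sub))
    man$path[i] <- sub
    if (labels[i] == 1L) {
      man$lesion_x[i] <- sl$truth$lesion_center["x"]
      man$lesion_y[i] <- sl$truth$lesion_center["y"]
      man$lesion_r[i] <- sl$truth$lesion_radius
    }
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a dataset manifest
#' @param dir dataset directory written by [generate_dataset()].
#' @return data frame with absolute slide paths.
#' @export
read_manifest <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  man$path <- file.path(dir, man$path)
  man
}
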