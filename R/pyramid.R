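# Pyramid abstraction: multi-level 8-bit RGB rasters with strict x2
# downsampling, dynamic level selection for region reads, and affine view
# frames composed across magnifying layers.
#
# Coordinates are continuous level-0 pixels, origin at the top-left corner,
# y pointing down; level-0 pixel i covers [i, i+1). Frames are center +
# half-extent, which sidesteps 0/1-based indexing ambiguity.

#' Construct an in-memory image pyramid
#'
#' @param levels list of rasters ordered from level 0 (full resolution) to
#'   the coarsest level. Each raster is either a numeric `(H, W, 3)` array in
#'   `[0, 1]` or a raw array of the same shape (8-bit). Level `k` must have
#'   `ceiling(h0 / 2^k)` rows and `ceiling(w0 / 2^k)` columns.
#' @return an object of class `pyramid_image` with fields `h0`, `w0`, `mmax`.
#' @export
pyramid_image <- function(levels) {
  stopifnot(length(levels) >= 1)
  levels <- lapply(levels, as_raw_img)
  h0 <- dim(levels[[1]])[1]
  w0 <- dim(levels[[1]])[2]
  for (k in seq_along(levels)) {
    d <- dim(levels[[k]])
    eh <- ceiling(h0 / 2^(k - 1)); ew <- ceiling(w0 / 2^(k - 1))
    if (d[1] != eh || d[2] != ew)
      stop(sprintf("level %d has dims %dx%d, expected %dx%d (ceil h0/2^k)",
                   k - 1, d[1], d[2], eh, ew))
  }
  structure(list(levels = levels, h0 = h0, w0 = w0, mmax = length(levels),
                 path = NULL, cache = new.env(parent = emptyenv())),
            class = "pyramid_image")
}

#' @export
print.pyramid_image <- function(x, ...) {
  cat(sprintf("<pyramid_image: %d x %d level-0 pixels, %d levels%s>\n",
              x$h0, x$w0, x$mmax,
              if (is.null(x$path)) "" else paste0(", on disk at ", x$path)))
  invisible(x)
}

as_raw_img <- function(x) {
  if (is.raw(x)) return(x)
  cpp_to_raw(x)
}

as_num_img <- function(x) {
  if (!is.raw(x)) return(x)
  d <- dim(x)
  y <- as.integer(x) / 255
  dim(y) <- d
  y
}

# fetch the raw raster of a level, reading it from disk when lazy; only
# rasters up to ~1 MB are cached so deep levels of many slides can be read
# in one session without exhausting memory
get_level <- function(pyr, k) {
  if (!is.null(pyr$levels[[k + 1]])) return(pyr$levels[[k + 1]])
  key <- paste0("L", k)
  if (!is.null(pyr$cache[[key]])) return(pyr$cache[[key]])
  lev <- if (!is.null(pyr$aug)) {
    dihedral_raw(get_level(pyr$base, k), pyr$aug)
  } else {
    as_raw_img(png::readPNG(file.path(pyr$path, sprintf("level_%d.png", k))))
  }
  if (length(lev) <= 1100000) pyr$cache[[key]] <- lev
  lev
}

#' Write a pyramid to the on-disk directory layout
#'
#' One PNG per level (`level_<k>.png`) plus `meta.json` holding
#' `h0`, `w0` and `mmax`.
#'
#' @param pyr a [pyramid_image()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pyramid <- function(pyr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(pyr$mmax) - 1L) {
    png::writePNG(as_num_img(get_level(pyr, k)),
                  file.path(dir, sprintf("level_%d.png", k)))
  }
  jsonlite::write_json(list(h0 = pyr$h0, w0 = pyr$w0, mmax = pyr$mmax),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a pyramid directory
#'
#' @param dir a directory written by [write_pyramid()].
#' @param lazy if `TRUE` (default) levels are loaded on first access and
#'   cached; if `FALSE` all levels are loaded eagerly.
#' @return a `pyramid_image`.
#' @export
read_pyramid <- function(dir, lazy = TRUE) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  mmax <- meta$mmax
  levels <- vector("list", mmax)
  if (!lazy) {
    for (k in seq_len(mmax) - 1L)
      levels[[k + 1]] <- as_raw_img(png::readPNG(
        file.path(dir, sprintf("level_%d.png", k))))
  }
  structure(list(levels = levels, h0 = meta$h0, w0 = meta$w0, mmax = mmax,
                 path = dir, cache = new.env(parent = emptyenv())),
            class = "pyramid_image")
}

#' Dynamic magnification-level selection
#'
#' Picks the pyramid level for a requested region of `hc x wc` level-0
#' pixels on a slide of `h0 x w0` pixels with `mmax` levels:
#' `Rh = floor(log2(h0/hc))`, `Rw = floor(log2(w0/wc))`, `R = max(Rh, Rw)`,
#' `m = max(mmax - R, 0)`, with `m` additionally clamped to `mmax - 1`
#' (the coarsest stored level) so a full-slide request resolves to the top
#' of the stack.
#'
#' @param h0,w0 slide height/width at level 0 (pixels).
#' @param hc,wc requested region height/width (level-0 pixels).
#' @param mmax number of pyramid levels.
#' @return integer level index in `[0, mmax - 1]`.
#' @export
select_level <- function(h0, w0, hc, wc, mmax) {
  if (hc <= 0 || wc <= 0) stop("requested extents must be positive")
  if (hc > h0 || wc > w0) stop("requested extent exceeds the slide")
  if (mmax < 1) stop("mmax must be >= 1")
  rh <- floor(log2(h0 / hc) + 1e-9)
  rw <- floor(log2(w0 / wc) + 1e-9)
  m <- mmax - max(rh, rw)
  as.integer(min(max(m, 0), mmax - 1))
}

#' Create a view frame
#'
#' @param cx,cy frame center in continuous level-0 pixel coordinates.
#' @param hw,hh half-extents (level-0 pixels).
#' @param depth magnifying-layer depth (0 for the root).
#' @return an object of class `view_frame`.
#' @export
view_frame <- function(cx, cy, hw, hh, depth = 0L) {
  stopifnot(hw > 0, hh > 0)
  structure(list(cx = cx, cy = cy, hw = hw, hh = hh, depth = as.integer(depth)),
            class = "view_frame")
}

#' Root frame covering the whole slide
#' @param pyr a `pyramid_image`.
#' @export
root_frame <- function(pyr) {
  view_frame(pyr$w0 / 2, pyr$h0 / 2, pyr$w0 / 2, pyr$h0 / 2, 0L)
}

#' Compose a parent frame with affine crop parameters
#'
#' The child center moves by `(tx * hw, ty * hh)` in level-0 pixels and the
#' half-extents shrink by the isotropic scale `s`. Identity parameters
#' `(1, 0, 0)` return an equal frame. No clipping happens here; reads clip.
#'
#' @param parent a [view_frame()].
#' @param theta an [affine_params()] object or a list with `s`, `tx`, `ty`.
#' @return the child `view_frame` with `depth` incremented.
#' @export
compose_frames <- function(parent, theta) {
  view_frame(parent$cx + theta$tx * parent$hw,
             parent$cy + theta$ty * parent$hh,
             theta$s * parent$hw,
             theta$s * parent$hh,
             parent$depth + 1L)
}

#' Read a square view of a frame from the pyramid
#'
#' The level is chosen by [select_level()] from the frame extent, the
#' frame's level-0 rectangle is mapped to that level, read with bilinear
#' interpolation (regions outside the raster are black), and placed
#' aspect-preserved with symmetric black padding into an
#' `out_side x out_side` canvas (odd padding deficits go to bottom/right).
#'
#' @param pyr a `pyramid_image`.
#' @param frame a [view_frame()].
#' @param out_side output side in pixels (56, 112 and 224 are the sides the
#'   model uses).
#' @return numeric `(out_side, out_side, 3)` array in `[0, 1]`.
#' @export
read_region <- function(pyr, frame, out_side) {
  stopifnot(out_side >= 2)
  x0 <- frame$cx - frame$hw; x1 <- frame$cx + frame$hw
  y0 <- frame$cy - frame$hh; y1 <- frame$cy + frame$hh
  if (x1 <= 0 || y1 <= 0 || x0 >= pyr$w0 || y0 >= pyr$h0) {
    warning("frame entirely outside the slide; returning black")
    return(array(0, dim = c(out_side, out_side, 3)))
  }
  hc <- min(max(2 * frame$hh, 1), pyr$h0)
  wc <- min(max(2 * frame$hw, 1), pyr$w0)
  m <- select_level(pyr$h0, pyr$w0, hc, wc, pyr$mmax)
  lev <- get_level(pyr, m)
  d <- dim(lev)
  sc <- 2^m
  # aspect-preserving content box inside the square canvas
  if (frame$hw >= frame$hh) {
    cw <- out_side
    ch <- max(1L, as.integer(round(out_side * frame$hh / frame$hw)))
  } else {
    ch <- out_side
    cw <- max(1L, as.integer(round(out_side * frame$hw / frame$hh)))
  }
  ox <- (out_side - cw) %/% 2L
  oy <- (out_side - ch) %/% 2L
  cpp_read_region(lev, d[1], d[2], x0 / sc, y0 / sc, x1 / sc, y1 / sc,
                  cw, ch, out_side, ox, oy)
}

# level index actually used for a frame read (for traces)
frame_level <- function(pyr, frame) {
  hc <- min(max(2 * frame$hh, 1), pyr$h0)
  wc <- min(max(2 * frame$hw, 1), pyr$w0)
  select_level(pyr$h0, pyr$w0, hc, wc, pyr$mmax)
}

# Apply a dihedral code to the whole slide by transforming level rasters
# lazily on access (used for train-time augmentation so that localization,
# sampling and pyramid reads stay geometrically consistent).
pyramid_augment <- function(pyr, code) {
  if (code == "none") return(pyr)
  structure(list(levels = vector("list", pyr$mmax),
                 h0 = if (code %in% c("rot90", "rot270")) pyr$w0 else pyr$h0,
                 w0 = if (code %in% c("rot90", "rot270")) pyr$h0 else pyr$w0,
                 mmax = pyr$mmax, path = NULL,
                 cache = new.env(parent = emptyenv()),
                 base = pyr, aug = code),
            class = "pyramid_image")
}

dihedral_raw <- function(x, code) {
  d <- dim(x)
  y <- switch(code,
    none   = x,
    hflip  = x[, d[2]:1, , drop = FALSE],
    vflip  = x[d[1]:1, , , drop = FALSE],
    rot180 = x[d[1]:1, d[2]:1, , drop = FALSE],
    rot90  = aperm(x, c(2, 1, 3))[d[2]:1, , , drop = FALSE],
    rot270 = aperm(x, c(2, 1, 3))[, d[1]:1, , drop = FALSE],
    stop("unknown augmentation code: ", code)
  )
  y
}
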