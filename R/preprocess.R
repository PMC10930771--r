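# Input conditioning applied identically at train and inference time:
# grey/background filtering, aspect-preserving resize with symmetric black
# padding, and dihedral (mirror/rotation) augmentation.

#' Grey filter
#'
#' Sets every pixel whose red, green and blue values differ from each other
#' by less than `tau` (on the 0-255 scale) to black. This removes the white
#' slide background and grey scanning artifacts such as smudges; all other
#' pixels pass through unchanged. Idempotent.
#'
#' @param img numeric `(H, W, 3)` array in `[0, 1]`.
#' @param tau intensity threshold on the 0-255 scale (default 15); the
#'   predicate is strict (`max - min < tau` is removed).
#' @return the filtered image.
#' @export
grey_filter <- function(img, tau = 15) {
  keep <- grey_keep_mask(img, tau)
  img * keep
}

# (H, W, 3) 0/1 mask of pixels that survive the grey filter
grey_keep_mask <- function(img, tau = 15) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) stop("grey_filter expects an (H, W, 3) image")
  m <- matrix(img, d[1] * d[2], 3)
  spread <- (pmax(m[, 1], m[, 2], m[, 3]) - pmin(m[, 1], m[, 2], m[, 3])) * 255
  keep <- spread >= tau - 1e-9
  array(rep(as.numeric(keep), 3), dim = d)
}

#' Aspect-preserving resize with symmetric black padding
#'
#' The longer image side is scaled to `side` by bilinear interpolation; the
#' shorter side is then padded symmetrically with black pixels to `side`
#' (an odd padding deficit puts the extra row/column at the bottom/right).
#'
#' @param img numeric `(H, W, 3)` array.
#' @param side target side in pixels.
#' @return a `(side, side, 3)` array.
#' @export
resize_pad <- function(img, side) {
  d <- dim(img)
  if (is.null(d) || d[1] < 1 || d[2] < 1) stop("empty image")
  if (d[1] == side && d[2] == side) return(img)
  if (d[2] >= d[1]) {
    ow <- side; oh <- max(1L, as.integer(round(side * d[1] / d[2])))
  } else {
    oh <- side; ow <- max(1L, as.integer(round(side * d[2] / d[1])))
  }
  content <- cpp_resize_bilinear(img, oh, ow)
  out <- array(0, dim = c(side, side, 3))
  oy <- (side - oh) %/% 2L
  ox <- (side - ow) %/% 2L
  out[(oy + 1):(oy + oh), (ox + 1):(ox + ow), ] <- content
  out
}

#' Dihedral augmentation
#'
#' Exact pixel permutations: horizontal/vertical mirroring and rotations by
#' 90, 180 and 270 degrees. Applying the inverse code restores the input
#' bit-exactly.
#'
#' @param img numeric `(H, W, 3)` array (square for the rotation codes).
#' @param code one of `"none"`, `"hflip"`, `"vflip"`, `"rot90"`, `"rot180"`,
#'   `"rot270"`.
#' @return the transformed image.
#' @export
augment <- function(img, code = c("none", "hflip", "vflip",
                                  "rot90", "rot180", "rot270")) {
  code <- match.arg(code)
  dihedral_raw(img, code)
}

#' @rdname augment
#' @export
augment_codes <- function() c("none", "hflip", "vflip", "rot90", "rot180", "rot270")
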