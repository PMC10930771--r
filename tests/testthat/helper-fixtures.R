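# Shared fixtures and independent oracles, built in code at test time.

# deterministic gradient pyramid: level 0 is a smooth ramp, lower levels by
# box downsampling (exactly the generator's scheme)
ramp_pyramid <- function(side = 64, mmax = 3) {
  g <- outer(seq(0, 1, length.out = side), seq(0, 1, length.out = side),
             function(a, b) (a + b) / 2)
  img <- array(0, dim = c(side, side, 3))
  img[, , 1] <- g; img[, , 2] <- g^2; img[, , 3] <- 1 - g
  levels <- list(img)
  cur <- img
  for (k in seq_len(mmax - 1)) {
    cur <- magnet:::cpp_box_down2(cur)
    levels[[k + 1]] <- cur
  }
  pyramid_image(levels)
}

# small synthetic slide for end-to-end smoke tests
small_slide <- function(seed = 7, label = 1, side = 512, mmax = 4,
                        lesion_scale = "macro") {
  generate_slide(slide_spec(level0_side = side, mmax = mmax, label = label,
                            lesion_scale = lesion_scale), seed)
}

# brute-force Euclidean projection onto the probability simplex by
# exhaustive enumeration of candidate supports (oracle for sparsemax)
simplex_project_bruteforce <- function(z) {
  K <- length(z)
  best <- NULL
  bestd <- Inf
  for (ss in seq_len(2^K - 1)) {
    S <- which(bitwAnd(ss, 2^(seq_len(K) - 1)) > 0)
    tau <- (sum(z[S]) - 1) / length(S)
    p <- pmax(z - tau, 0)
    # valid KKT point: support matches and p sums to one
    if (abs(sum(p) - 1) > 1e-9) next
    if (!all(p[S] >= -1e-12)) next
    if (!all(p[-S] == 0) && length(S) < K) next
    d <- sum((p - z)^2)
    if (d < bestd - 1e-15) { bestd <- d; best <- p }
  }
  best
}

# dense bilinear oracle (pure R, align-corners, zero outside)
bilinear_oracle <- function(img, gx, gy) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  out <- matrix(0, length(gx), C)
  for (n in seq_along(gx)) {
    px <- (gx[n] + 1) / 2 * (W - 1)
    py <- (gy[n] + 1) / 2 * (H - 1)
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    for (b in 0:1) for (a in 0:1) {
      xi <- x0 + a; yi <- y0 + b
      if (xi < 0 || xi >= W || yi < 0 || yi >= H) next
      w <- (if (a) fx else 1 - fx) * (if (b) fy else 1 - fy)
      out[n, ] <- out[n, ] + w * img[yi + 1, xi + 1, ]
    }
  }
  out
}

# integer-arithmetic oracle for the level-selection formula (no log2):
# R = largest k with hc * 2^k <= h0
level_oracle <- function(h0, w0, hc, wc, mmax) {
  pow_floor <- function(num, den) {
    k <- 0
    while (den * 2^(k + 1) <= num) k <- k + 1
    k
  }
  rh <- pow_floor(h0, hc)
  rw <- pow_floor(w0, wc)
  min(max(mmax - max(rh, rw), 0), mmax - 1)
}

# O(n^2) pairwise AUROC oracle with midrank tie handling
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
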