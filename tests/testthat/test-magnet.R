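# Patch accounting, frozen patch, forward contracts, heads, checkpoints.

test_that("count_patches reproduces the printed budgets exactly", {
  b3 <- count_patches(magnet_config(3, c(3, 2, 3)))
  expect_identical(b3$n_small, 10)
  expect_identical(b3$n_large, 18)
  expect_identical(b3$total, 28)
  expect_identical(b3$pixels_total, 10 * 56^2 * 3 + 18 * 224^2 * 3)
  expect_identical(b3$pixels_total, 2803584)   # ~3 million pixels per slide
  b4 <- count_patches(magnet_config(4, c(3, 2, 3, 2)))
  expect_identical(b4$n_small, 28)
  expect_identical(b4$n_large, 36)
  expect_identical(b4$total, 64)
  expect_identical(b4$pixels_total, 5682432)   # ~6 million pixels per slide
  b1 <- count_patches(magnet_config(3, c(1, 1, 1)))
  expect_identical(b1$n_small, 3)              # input + one patch per layer
  expect_identical(b1$n_large, 1)
})

test_that("forward traces agree with the closed-form budget", {
  sl <- small_slide(seed = 2, side = 256, mmax = 3)
  set.seed(30)
  for (i in 1:8) {
    L <- sample(1:3, 1)
    P <- sample(1:3, L, replace = TRUE)
    cfg <- desk_config(layers = L, patches_per_layer = P,
                       frozen_patch = sample(c(TRUE, FALSE), 1))
    model <- magnet_init(cfg, seed = i)
    fwd <- magnet_forward(model, sl$pyramid)
    b <- count_patches(cfg)
    expect_identical(nrow(fwd$trace), as.integer(b$total))
    expect_identical(sum(fwd$trace$resolution == 56), as.integer(b$n_small))
    expect_identical(sum(fwd$trace$resolution == 224), as.integer(b$n_large))
    # names encode the extraction path; every parent exists; leaf count
    expect_true(all(fwd$trace$parent[-1] %in% fwd$trace$name))
    leaves <- fwd$trace$name[fwd$trace$layer == L]
    expect_identical(length(leaves), as.integer(b$n_large))
    expect_true(all(nchar(leaves) == L + 2L))  # "I" + L+1 index digits
  }
})

test_that("the frozen patch always re-reads the whole parent view", {
  sl <- small_slide(seed = 4, side = 256, mmax = 3)
  for (s in 1:2) {
    model <- magnet_init(desk_config(), seed = s * 11)
    fwd <- magnet_forward(model, sl$pyramid)
    tr <- fwd$trace
    frames <- magnet:::trace_frames(tr, sl$pyramid)
    frozen <- tr[tr$layer == 2 & substr(tr$name, 4, 4) == "1", ]
    expect_identical(nrow(frozen), 2L)
    expect_equal(frozen$s, c(1, 1))
    expect_equal(frozen$tx, c(0, 0)); expect_equal(frozen$ty, c(0, 0))
    for (i in seq_len(nrow(frozen))) {
      child <- frames[[frozen$name[i]]]
      parent <- frames[[frozen$parent[i]]]
      expect_equal(child[c("cx", "cy", "hw", "hh")],
                   parent[c("cx", "cy", "hw", "hh")])
    }
  }
})

test_that("identity thetas keep every child frame equal to its parent", {
  pyr <- ramp_pyramid(64, 3)
  fr <- root_frame(pyr)
  for (i in 1:3) {
    child <- compose_frames(fr, affine_params(1, 0, 0))
    expect_equal(child[c("cx", "cy", "hw", "hh")], fr[c("cx", "cy", "hw", "hh")])
    fr <- child
  }
})

test_that("forward outputs are probabilities and eval mode is deterministic", {
  sl <- small_slide(seed = 6, side = 256, mmax = 3)
  model <- magnet_init(desk_config(), seed = 5)
  a <- magnet_forward(model, sl$pyramid)
  b <- magnet_forward(model, sl$pyramid)
  expect_gt(a$y_hat, 0); expect_lt(a$y_hat, 1)
  expect_true(all(a$p_aux >= 0 & a$p_aux <= 1))
  expect_identical(a$y_hat, b$y_hat)
  expect_identical(a$trace, b$trace)
})

test_that("zoom shrinks requested extents geometrically when s <= 1", {
  pyr <- ramp_pyramid(64, 3)
  fr <- root_frame(pyr)
  s <- 0.6
  for (k in 1:4) {
    fr <- compose_frames(fr, affine_params(s, 0.1, -0.1))
    expect_equal(2 * fr$hh, s^k * pyr$h0)
  }
})

test_that("classification_head consumes an ordered patch sequence", {
  model <- magnet_init(desk_config(), seed = 9)
  set.seed(31)
  patches <- lapply(1:4, function(i) array(runif(224^2 * 3), c(224, 224, 3)))
  p <- classification_head(patches, model)
  expect_gt(p, 0); expect_lt(p, 1)
  expect_identical(p, classification_head(patches, model))
  # order matters for a recurrent head
  expect_false(isTRUE(all.equal(p, classification_head(rev(patches), model))))
  expect_error(classification_head(list(), model), "empty")
})

test_that("auxiliary_predict averages then conditions on the label", {
  expect_equal(auxiliary_predict(0.7, 1), 0.7)
  expect_equal(auxiliary_predict(c(0.6, 0.8), 0), 0.3)
  set.seed(32)
  for (i in 1:20) {
    p <- runif(sample(1:5, 1))
    expect_gte(auxiliary_predict(p, 1), 0)
    expect_lte(auxiliary_predict(p, 0), 1)
  }
  expect_error(auxiliary_predict(numeric(0), 1), "without patches")
})

test_that("checkpoints round-trip bit-exactly", {
  sl <- small_slide(seed = 8, side = 256, mmax = 3)
  model <- magnet_init(desk_config(), seed = 13)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_identical(magnet_forward(model, sl$pyramid)$y_hat,
                   magnet_forward(back, sl$pyramid)$y_hat)
})
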