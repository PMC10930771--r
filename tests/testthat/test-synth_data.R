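# Synthetic slide generator: determinism, lesion visibility across scales,
# dataset manifests, pyramid conservation, filterable artifacts.

test_that("generation is bit-deterministic in the seed", {
  a <- small_slide(seed = 11, side = 256, mmax = 3)
  b <- small_slide(seed = 11, side = 256, mmax = 3)
  for (k in 0:2)
    expect_identical(magnet:::get_level(a$pyramid, k),
                     magnet:::get_level(b$pyramid, k))
  expect_identical(a$truth, b$truth)
})

test_that("negative slides carry no lesion, same seed differs only locally", {
  pos <- small_slide(seed = 5, label = 1, side = 512, mmax = 4)
  neg <- small_slide(seed = 5, label = 0, side = 512, mmax = 4)
  expect_identical(neg$truth, list(label = 0L))
  expect_identical(pos$truth$label, 1L)
  l1 <- magnet:::as_num_img(magnet:::get_level(pos$pyramid, 0))
  l0 <- magnet:::as_num_img(magnet:::get_level(neg$pyramid, 0))
  diff <- abs(l1 - l0)
  cx <- pos$truth$lesion_center["x"]; cy <- pos$truth$lesion_center["y"]
  r <- pos$truth$lesion_radius
  outside <- diff
  yb <- max(1, floor(cy - r - 2)):min(512, ceiling(cy + r + 2))
  xb <- max(1, floor(cx - r - 2)):min(512, ceiling(cx + r + 2))
  outside[yb, xb, ] <- 0
  expect_equal(max(outside), 0)                # differences only at the lesion
  expect_gt(max(diff[yb, xb, ]), 0.1)          # and the lesion is really there
})

test_that("micro lesions are invisible at the root view, visible zoomed in", {
  pos <- generate_slide(slide_spec(label = 1, lesion_scale = "micro"), 21)
  neg <- generate_slide(slide_spec(label = 0, lesion_scale = "micro"), 21)
  r1 <- read_region(pos$pyramid, root_frame(pos$pyramid), 56)
  r0 <- read_region(neg$pyramid, root_frame(neg$pyramid), 56)
  expect_lt(mean(abs(r1 - r0)), 0.01)          # sub-tolerance at the root
  fr <- view_frame(pos$truth$lesion_center["x"], pos$truth$lesion_center["y"],
                   2 * pos$truth$lesion_radius, 2 * pos$truth$lesion_radius, 2)
  z1 <- read_region(pos$pyramid, fr, 56)
  z0 <- read_region(neg$pyramid, fr, 56)
  expect_gt(mean(abs(z1 - z0)), 0.02)          # clearly visible at native scale
})

test_that("lesions lie fully inside tissue (non-grey, non-background)", {
  sl <- small_slide(seed = 9, side = 512, mmax = 4, lesion_scale = "macro")
  lev0 <- magnet:::as_num_img(magnet:::get_level(sl$pyramid, 0))
  filt <- grey_filter(lev0)
  cx <- sl$truth$lesion_center["x"]; cy <- sl$truth$lesion_center["y"]
  r <- sl$truth$lesion_radius
  # a ring just outside the lesion is tissue: it survives the grey filter
  ang <- seq(0, 2 * pi, length.out = 32)
  px <- pmin(pmax(round(cx + 1.2 * r * cos(ang)), 1), 512)
  py <- pmin(pmax(round(cy + 1.2 * r * sin(ang)), 1), 512)
  ring <- sapply(seq_along(px), function(i) sum(filt[py[i], px[i], ]))
  expect_true(all(ring > 0))
})

test_that("downsampling conserves mean intensity across levels", {
  sl <- small_slide(seed = 13, side = 512, mmax = 4)
  means <- sapply(0:3, function(k)
    mean(magnet:::as_num_img(magnet:::get_level(sl$pyramid, k))))
  expect_lt(max(abs(diff(means))), 1e-3)
})

test_that("grey smudges satisfy the grey-filter predicate", {
  sl <- generate_slide(slide_spec(level0_side = 512, mmax = 3, label = 0,
                                  artifact_rate = 8), 17)
  lev0 <- magnet:::as_num_img(magnet:::get_level(sl$pyramid, 0))
  m <- matrix(lev0, ncol = 3)
  spread <- (pmax(m[, 1], m[, 2], m[, 3]) - pmin(m[, 1], m[, 2], m[, 3])) * 255
  grey <- spread < 15
  expect_gt(mean(grey), 0.3)                   # background + smudges are grey
  filt <- grey_filter(lev0)
  fm <- matrix(filt, ncol = 3)
  expect_true(all(fm[grey, ] == 0))            # filter removes all of them
})

test_that("generate_dataset balances labels, splits and is reproducible", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(10, d1, seed = 77, level0_side = 128, mmax = 2)
  m2 <- generate_dataset(10, d2, seed = 77, level0_side = 128, mmax = 2)
  expect_identical(sum(m1$label == 1), 5L)
  expect_identical(sum(m1$label == 0), 5L)
  expect_identical(table(m1$split)[["train"]], 8L)
  expect_identical(table(m1$split)[["val"]], 2L)
  expect_identical(m1[setdiff(names(m1), "path")],
                   m2[setdiff(names(m2), "path")])
  man <- read_manifest(d1)
  expect_true(all(dir.exists(man$path)))
  expect_true(all(is.na(man$lesion_x[man$label == 0])))
  expect_true(all(!is.na(man$lesion_x[man$label == 1])))
})
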