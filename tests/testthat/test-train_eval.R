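# Metrics, schedule, training smoke contracts, evaluation reports.

test_that("auroc matches the O(n^2) pairwise oracle", {
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_true(is.na(auroc(runif(5), rep(1, 5))))
  set.seed(50)
  for (i in 1:5) {
    n <- 200
    labels <- rbinom(n, 1, 0.4)
    scores <- runif(n) + 0.3 * labels
    scores[sample(n, 20)] <- 0.5            # force ties
    expect_equal(auroc(scores, labels), auroc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("cosine schedule starts at lr0, ends near zero, never increases", {
  lr0 <- 3e-5
  lrs <- sapply(1:200, function(e) magnet:::cosine_lr(lr0, e, 200))
  expect_equal(lrs[1], lr0)
  expect_lt(lrs[200], lr0 * 1e-3)
  expect_true(all(diff(lrs) <= 0))
})

test_that("one training epoch on four slides produces a sane history", {
  d <- withr::local_tempdir()
  generate_dataset(4, d, seed = 55, level0_side = 256, mmax = 3,
                   lesion_scale = "macro", split = c(train = 1))
  man <- read_manifest(d)
  cfg <- desk_config()
  tc <- desk_train_config(epochs = 1L, batch_size = 2L, seed = 3L)
  fit1 <- magnet_train(cfg, man, man[0, ], tc)
  expect_identical(nrow(fit1$history), 1L)
  expect_true(all(is.finite(unlist(fit1$history[, c("L1", "L2", "L3", "total")]))))
  expect_true(is.na(fit1$history$val_auroc))   # no validation slides
  # determinism: same seed, same first-epoch losses
  fit2 <- magnet_train(cfg, man, man[0, ], tc)
  expect_identical(fit1$history, fit2$history)
  expect_error(magnet_train(cfg, man[0, ], man, tc), "empty")
})

test_that("training writes history and a loadable best checkpoint", {
  d <- withr::local_tempdir()
  generate_dataset(6, d, seed = 56, level0_side = 256, mmax = 3,
                   lesion_scale = "macro", split = c(train = 0.67, val = 0.33))
  man <- read_manifest(d)
  out <- withr::local_tempdir()
  fit <- magnet_train(desk_config(), man[man$split == "train", ],
                      man[man$split == "val", ],
                      desk_train_config(epochs = 2L, batch_size = 2L, seed = 4L),
                      out_dir = out)
  expect_true(file.exists(file.path(out, "history.csv")))
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  back <- load_checkpoint(file.path(out, "checkpoint.rds"))
  va <- man[man$split == "val", ]
  expect_identical(magnet_evaluate(back, va)$scores,
                   magnet_evaluate(fit$model, va)$scores)
})

test_that("evaluate reports AUROC, accuracy and stratified rows", {
  d <- withr::local_tempdir()
  generate_dataset(6, d, seed = 57, level0_side = 256, mmax = 3,
                   lesion_scale = "macro", split = c(train = 1))
  man <- read_manifest(d)
  model <- magnet_init(desk_config(), seed = 8)
  man$scale <- rep(c("a", "b"), 3)
  ev <- magnet_evaluate(model, man, by = "scale")
  expect_identical(ev$n, 6L)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_true(is.na(ev$auroc) || (ev$auroc >= 0 && ev$auroc <= 1))
  expect_identical(nrow(ev$by_stratum), 2L)
  # single-class stratum reports AUROC as NA (mirrors "-" cells)
  one <- magnet_evaluate(model, man[man$label == 1, ])
  expect_true(is.na(one$auroc))
})

test_that("frame_contains checks the closed box", {
  fr <- view_frame(100, 100, 10, 20, 1)
  expect_true(frame_contains(fr, 105, 115))
  expect_true(frame_contains(fr, 110, 120))
  expect_false(frame_contains(fr, 111, 100))
  expect_false(frame_contains(fr, 100, 121))
})
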