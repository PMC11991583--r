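# Training schedule, optimizer behaviour, evaluation driver.

test_that("learning-rate schedule hits its endpoints", {
  cfg <- trainConfig(epochs = 300, warmupEpochs = 3)
  # first warmup iteration: bias group starts at warmup_bias_lr
  s0 <- lrSchedule(0, 0, 10, cfg)
  expect_equal(s0$lrBias, 0.1)
  expect_equal(s0$lrWeights, 0)
  expect_equal(s0$momentum, 0.8)
  # final epoch: lr = lr0 * lrf = 1e-4
  sf <- lrSchedule(299, 9, 10, cfg)
  expect_equal(sf$lrWeights, 0.01 * 0.01, tolerance = 1e-12)
  expect_equal(sf$momentum, 0.937)
})

test_that("mid-schedule values match a brute-force tabulation", {
  cfg <- trainConfig(epochs = 50, warmupEpochs = 2)
  steps <- 7
  nw <- cfg$warmupEpochs * steps
  for (ep in c(0, 1, 3, 10, 25, 49)) for (st in c(0, 3, 6)) {
    sc <- lrSchedule(ep, st, steps, cfg)
    # loop tabulation of the interpolation rule
    lf <- 1 - (1 - cfg$lrf) * ep / (cfg$epochs - 1)
    target <- cfg$lr0 * lf
    ni <- ep * steps + st
    if (ni <= nw) {
      xi <- ni / nw
      expect_equal(sc$lrWeights, xi * target, tolerance = 1e-12)
      expect_equal(sc$lrBias, 0.1 + xi * (target - 0.1), tolerance = 1e-12)
      expect_equal(sc$momentum, 0.8 + xi * (0.937 - 0.8), tolerance = 1e-12)
    } else {
      expect_equal(sc$lrWeights, target, tolerance = 1e-12)
      expect_equal(sc$lrBias, target, tolerance = 1e-12)
    }
  }
})

test_that("a short training run reduces the loss deterministically", {
  scenes <- lapply(1:4, function(s) generateSyntheticScene(tinySceneConfig(), s))
  run <- function() {
    m <- buildWheatNet(seed = 10)
    r <- trainWheatNet(m, scenes, cfg = trainConfig(epochs = 6, batchSize = 4,
                                                    imgSize = 96, lr0 = 0.01,
                                                    warmupEpochs = 1, seed = 3),
                       verbose = FALSE)
    r$history
  }
  h1 <- run()
  expect_true(all(is.finite(h1$loss)))
  expect_lt(h1$loss[nrow(h1)], h1$loss[1])
  # identical seed: identical first-epoch loss to 6 decimals
  h2 <- run()
  expect_equal(round(h1$loss[1], 6), round(h2$loss[1], 6))
})

test_that("evaluation and counting run end to end on a tiny model", {
  scenes <- lapply(1:2, function(s) generateSyntheticScene(tinySceneConfig(), s))
  m <- buildWheatNet(seed = 1)
  ev <- evaluateWheatNet(m, scenes)
  expect_true(ev$map50 >= 0 && ev$map50 <= 1)
  cnt <- countSpikes(m, scenes[[1]])
  expect_gte(cnt[["total"]], 0)
})
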