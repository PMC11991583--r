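# Network assembly: variant factory, parameter/FLOP accounting, forward
# shape contracts, head behaviour, decoding.

test_that("all eight variants build and parameter ordering is consistent", {
  tab <- runAblation(inputSize = c(320L, 320L))
  expect_equal(nrow(tab), 8)
  base <- tab$parameters[!tab$secuib & !tab$dwdown & !tab$lightdetect]
  pS <- tab$parameters[tab$secuib & !tab$dwdown & !tab$lightdetect]
  pD <- tab$parameters[!tab$secuib & tab$dwdown & !tab$lightdetect]
  pL <- tab$parameters[!tab$secuib & !tab$dwdown & tab$lightdetect]
  expect_gt(pS, base)   # squeeze-excitation adds parameters
  expect_lt(pD, base)   # DWDown removes parameters
  expect_lt(pL, base)   # LightDetect removes parameters
  # module substitutions are structurally independent: deltas add up
  full <- tab$parameters[tab$secuib & tab$dwdown & tab$lightdetect]
  expect_equal(full, base + (pS - base) + (pD - base) + (pL - base))
})

test_that("parameter count ignores input size; FLOPs scale with area", {
  m <- buildWheatNet(seed = 1)
  p <- countParameters(m)
  f1 <- countFlops(m, c(320L, 320L))
  f2 <- countFlops(m, c(640L, 640L))
  expect_equal(countParameters(m), p)
  # squeeze-excitation adds a constant (area-independent) term, so the ratio
  # is 4 up to that small offset
  expect_equal(f2 / f1, 4, tolerance = 1e-3)
  expect_error(countFlops(m, c(100L, 100L)), "divisible")
})

test_that("forward emits three pyramid levels at strides 8/16/32", {
  m <- buildWheatNet(seed = 1)
  x <- array(rnorm(2 * 3 * 64 * 64), c(2, 3, 64, 64))
  o <- wheatnetForward(m, x)
  expect_equal(dim(o$reg3), c(2, 64, 8, 8))
  expect_equal(dim(o$cls3), c(2, 3, 8, 8))
  expect_equal(dim(o$reg4), c(2, 64, 4, 4))
  expect_equal(dim(o$reg5), c(2, 64, 2, 2))
  expect_error(wheatnetForward(m, array(0, c(1, 3, 60, 60))), "divisible")
  # deterministic in evaluation mode
  o2 <- wheatnetForward(m, x)
  expect_identical(o$cls4, o2$cls4)
})

test_that("gradient reaches every trainable parameter", {
  m <- buildWheatNet(seed = 2)
  x <- array(rnorm(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  o <- wheatnetForward(m, x, training = TRUE)
  grads <- lapply(o, function(a) array(rnorm(length(a)), dim(a)))
  LGWheatNet:::zeroGradients(m)
  LGWheatNet:::wheatnetBackward(m, grads)
  missing <- 0
  for (nd in m@graph$nodes)
    for (pn in LGWheatNet:::nodeParamNames(nd)) {
      g <- nd[[LGWheatNet:::nodeGradName(pn)]]
      if (is.null(g) || all(g == 0)) missing <- missing + 1
    }
  expect_equal(missing, 0)
})

test_that("zeroed final classification conv yields 0.5 scores everywhere", {
  m <- buildWheatNet(seed = 1)
  for (nm in c("cls3", "cls4", "cls5")) {
    nd <- m@graph$nodes[[m@outputs[[nm]]]]
    nd$W[] <- 0; nd$b[] <- 0
  }
  x <- array(rnorm(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  o <- wheatnetForward(m, x)
  expect_lt(max(abs(o$cls3)), 1e-6)
  expect_equal(max(abs(1 / (1 + exp(-o$cls5)) - 0.5)), 0, tolerance = 1e-6)
})

test_that("weights survive a save/load round trip", {
  m <- buildWheatNet(seed = 5)
  x <- array(rnorm(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  o1 <- wheatnetForward(m, x)
  p <- tempfile(fileext = ".rds")
  saveWeights(m, p)
  m2 <- buildWheatNet(seed = 99)
  loadWeights(m2, p)
  o2 <- wheatnetForward(m2, x)
  expect_equal(o1$reg3, o2$reg3, tolerance = 1e-7)
})

test_that("DFL decoding turns one-hot bins into distances", {
  hc <- headConfig()
  nb <- hc$regMax
  # one level: 1 x 64 x 1 x 2 regression map, bin j one-hot on all sides
  j <- 5
  mkRaw <- function() {
    reg <- array(-20, c(1, 4 * nb, 1, 2))
    for (s in 1:4) reg[1, (s - 1) * nb + j + 1, 1, ] <- 20
    cls <- array(-20, c(1, 3, 1, 2))
    cls[1, 1, 1, 1] <- 5   # only cell 1 confident
    list(reg3 = reg, cls3 = cls,
         reg4 = array(-20, c(1, 4 * nb, 1, 1)), cls4 = array(-20, c(1, 3, 1, 1)),
         reg5 = array(-20, c(1, 4 * nb, 1, 1)), cls5 = array(-20, c(1, 3, 1, 1)))
  }
  d <- decodePredictions(mkRaw(), hc, strides = c(8L, 16L, 32L),
                         confThreshold = 0.25)
  expect_equal(nrow(d), 1)
  # anchor of cell (h=1, w=1) at (4, 4), stride 8: box = anchor +- j*8
  expect_equal(as.numeric(d[1, c("x1", "y1", "x2", "y2")]),
               c(4 - 40, 4 - 40, 4 + 40, 4 + 40))
  # below-threshold scores produce no detections
  raw2 <- mkRaw(); raw2$cls3[1, 1, 1, 1] <- -20
  expect_equal(nrow(decodePredictions(raw2, hc)), 0)
})

test_that("NMS keeps the higher-scoring of two coincident boxes", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10), c(30, 30, 40, 40))
  keep <- nmsBoxes(b, c(0.9, 0.8, 0.7), 0.5)
  expect_equal(sort(keep), c(1, 3))
})
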