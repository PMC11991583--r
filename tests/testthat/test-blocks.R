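# Building-block primitives: SiLU, channel shuffle, squeeze-excitation,
# batch normalization, and the SeCUIB / DWDown / SPPF blocks.

test_that("silu matches its closed form and saturates", {
  expect_equal(silu(0), 0)
  expect_lt(abs(silu(-30)), 1e-8)
  expect_equal(silu(1), 1 / (1 + exp(-1)), tolerance = 1e-9)
  x <- array(rnorm(24), c(2, 3, 2, 2))
  expect_equal(dim(silu(x)), dim(x))
})

test_that("channel shuffle is the reshape-transpose permutation and inverts", {
  x <- array(0, c(1, 4, 2, 2))
  for (c_ in 1:4) x[1, c_, , ] <- c_
  expect_identical(channelShuffle(x, 1), x)
  expect_identical(channelShuffle(x, 4), x)
  y <- channelShuffle(x, 2)
  expect_equal(as.numeric(y[1, , 1, 1]), c(1, 3, 2, 4))
  # exhaustive inversion check for all divisor pairs up to C = 32
  for (C in 1:32) for (g in which(C %% seq_len(C) == 0)) {
    x <- array(seq_len(C), c(1, C, 1, 1))
    expect_identical(channelUnshuffle(channelShuffle(x, g), g), x)
  }
  expect_error(channelShuffle(array(0, c(1, 5, 1, 1)), 2), "divisible")
})

test_that("squeeze-excitation gates as the hand-evaluated chain", {
  x <- array(rnorm(2 * 6 * 4 * 4), c(2, 6, 4, 4))
  w0 <- seInit(6, 0.25, init = "zero")
  expect_equal(squeezeExcite(x, w0), 0.5 * x, tolerance = 1e-12)
  expect_equal(dim(squeezeExcite(x, seInit(6, 0.5))), dim(x))
  # 1 -> 1 -> 1 identity gate path, no bias: output = sigmoid(c) * c
  for (cv in c(0.3, 1.7)) {
    xc <- array(cv, c(1, 1, 3, 3))
    wi <- list(W1 = matrix(1, 1, 1), b1 = 0, W2 = matrix(1, 1, 1), b2 = 0)
    expect_equal(squeezeExcite(xc, wi),
                 array(plogis(cv) * cv, c(1, 1, 3, 3)), tolerance = 1e-12)
  }
})

test_that("batch normalization follows the affine form", {
  x <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  eps <- 1e-3
  expect_equal(batchNorm(x, mean = rep(0, 3), var = rep(1 - eps, 3),
                         gamma = rep(1, 3), beta = rep(0, 3), eps = eps),
               x, tolerance = 1e-12)
  y <- batchNorm(x, rep(0, 3), rep(1, 3), gamma = rep(0, 3), beta = c(1, 2, 3))
  expect_equal(as.numeric(y[1, , 2, 2]), c(1, 2, 3))
  # scalar evaluation: x=2, mu=1, var=4, eps=0, gamma=3, beta=1 -> 2.5
  xs <- array(2, c(1, 1, 1, 1))
  expect_equal(as.numeric(batchNorm(xs, 1, 4, 3, 1, eps = 0)), 2.5)
})

test_that("SeCUIB respects the shape contract and residual identity", {
  # zero weights + residual-eligible config -> identity map
  cfg <- secuibConfig(8, 8, expandRatio = 2, midKernel = 3, stride = 1)
  m <- secuibModule(cfg, init = "zero")
  x <- array(rnorm(1 * 8 * 6 * 6), c(1, 8, 6, 6))
  expect_equal(blockForward(m, x), x, tolerance = 1e-6)
  # stride-2 halves spatial dims (ceiling for odd sizes)
  cfg2 <- secuibConfig(8, 12, 2, startKernel = 3, midKernel = 3, stride = 2)
  m2 <- secuibModule(cfg2, seed = 1)
  y <- blockForward(m2, array(rnorm(8 * 9 * 9), c(1, 8, 9, 9)))
  expect_equal(dim(y), c(1, 12, 5, 5))
  # misconfiguration: stride 2 with no depthwise stage
  expect_error(secuibConfig(8, 8, 2, startKernel = 0, midKernel = 0, stride = 2),
               "depthwise")
  expect_error(secuibConfig(8, 8, expandRatio = 17 / 8), "divisible")
})

test_that("block parameter counts match the layer-by-layer oracle", {
  set.seed(42)
  for (i in 1:20) {
    io <- sample(c(8, 12, 16, 24, 32), 2, replace = TRUE)
    st <- if (io[1] == io[2]) sample(1:2, 1) else sample(1:2, 1)
    k0 <- sample(c(0, 3, 5), 1)
    k1 <- if (k0 == 0 && st == 2) 3 else sample(c(0, 3), 1)
    if (k0 == 0 && k1 == 0) k1 <- 3
    er <- sample(c(1, 2, 4), 1)
    cfg <- secuibConfig(io[1], io[2], er, k0, k1, st)
    for (sec in c(TRUE, FALSE)) {
      m <- secuibModule(cfg, secuib = sec, seed = i)
      expect_equal(countParameters(m), oracleUibParams(cfg, sec))
    }
  }
  for (i in 1:8) {
    cfg <- dwdownConfig(sample(8:64, 1), sample(8:64, 1))
    expect_equal(countParameters(dwdownModule(cfg)), oracleDwdownParams(cfg))
    cfgS <- sppfConfig(2 * sample(4:64, 1), sample(8:64, 1))
    expect_equal(countParameters(sppfModule(cfgS)), oracleSppfParams(cfgS))
  }
})

test_that("DWDown halves resolution with ceiling and adjusts channels", {
  m <- dwdownModule(dwdownConfig(16, 24), seed = 1)
  y <- blockForward(m, array(rnorm(16 * 40 * 40), c(1, 16, 40, 40)))
  expect_equal(dim(y), c(1, 24, 20, 20))
  y2 <- blockForward(m, array(rnorm(16 * 41 * 41), c(1, 16, 41, 41)))
  expect_equal(dim(y2), c(1, 24, 21, 21))
})

test_that("SPPF preserves shape and its chained pools equal one large pool", {
  m <- sppfModule(sppfConfig(32, 32), seed = 2)
  x <- array(rnorm(32 * 12 * 12), c(1, 32, 12, 12))
  expect_equal(dim(blockForward(m, x)), c(1, 32, 12, 12))
  # constant input stays spatially constant
  yc <- blockForward(m, array(1, c(1, 32, 8, 8)))
  expect_lt(max(abs(sweep(yc, 2, yc[1, , 1, 1]))), 1e-5)
  # three chained 5x5 stride-1 poolings have a 13x13 effective window
  x1 <- array(rnorm(3 * 10 * 10), c(1, 3, 10, 10))
  p <- LGWheatNet:::maxpool_fw(x1, 5L)$y
  p <- LGWheatNet:::maxpool_fw(p, 5L)$y
  p <- LGWheatNet:::maxpool_fw(p, 5L)$y
  expect_equal(p, LGWheatNet:::maxpool_fw(x1, 13L)$y)
})

test_that("blocks keep batch size and shapes for randomized configurations", {
  set.seed(7)
  for (i in 1:10) {
    cin <- sample(c(8, 16), 1); cout <- sample(c(8, 16, 24), 1)
    st <- sample(1:2, 1)
    cfg <- secuibConfig(cin, cout, 2, startKernel = 3, midKernel = 3, stride = st)
    m <- secuibModule(cfg, seed = i)
    n <- sample(1:2, 1); hw <- sample(c(6, 9, 12), 1)
    y <- blockForward(m, array(rnorm(n * cin * hw * hw), c(n, cin, hw, hw)))
    expect_equal(dim(y), c(n, cout, ceiling(hw / st), ceiling(hw / st)))
  }
})
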