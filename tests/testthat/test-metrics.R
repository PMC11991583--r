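# Detection matching, average precision, the mAP suite, confusion matrix,
# counting metrics.

det1 <- function(cls, score, b) data.frame(class = cls, score = score,
                                           x1 = b[1], y1 = b[2], x2 = b[3],
                                           y2 = b[4], stringsAsFactors = FALSE)
gt1 <- function(cls, b) data.frame(class = cls, x1 = b[1], y1 = b[2],
                                   x2 = b[3], y2 = b[4],
                                   stringsAsFactors = FALSE)

test_that("greedy matching hand cases", {
  g <- gt1("ripewheat", c(0, 0, 10, 10))
  m <- matchDetections(det1("ripewheat", 0.9, c(0, 0, 10, 10)), g)
  expect_true(all(m$dets$tp))
  expect_length(m$unmatchedGT, 0)
  # two detections on one truth: only the more confident is a TP
  d2 <- rbind(det1("ripewheat", 0.9, c(0, 0, 10, 10)),
              det1("ripewheat", 0.8, c(1, 1, 10, 10)))
  m2 <- matchDetections(d2, g)
  expect_equal(m2$dets$tp, c(TRUE, FALSE))
  # wrong class: a false positive and a missed truth
  m3 <- matchDetections(det1("flowerwheat", 0.9, c(0, 0, 10, 10)), g)
  expect_false(any(m3$dets$tp))
  expect_length(m3$unmatchedGT, 1)
})

test_that("average precision matches hand computation and the loop oracle", {
  expect_equal(averagePrecision(0.9, TRUE, 1), 1)
  expect_equal(averagePrecision(numeric(0), logical(0), 2), 0)
  # (TP, FP, TP) at 0.9/0.8/0.7 with 2 GT -> 0.5 * 1 + 0.5 * (2/3)
  expect_equal(averagePrecision(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2),
               1 * 0.5 + (2 / 3) * 0.5, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:30) {
    n <- sample(1:12, 1); nGT <- sample(1:8, 1)
    sc <- runif(n); tp <- runif(n) < 0.5
    tp[cumsum(tp) > nGT] <- FALSE     # cannot exceed the truth count
    expect_equal(averagePrecision(sc, tp, nGT),
                 oracleAveragePrecision(sc, tp, nGT), tolerance = 1e-12)
  }
})

test_that("mAP suite equals an independent protocol oracle on fixed detections", {
  set.seed(77)
  dets <- list(); gts <- list()
  for (i in 1:6) {
    sc <- randomScenario(sample(2:6, 1), sample(1:5, 1), seed = 100 + i)
    # bias some detections toward the truth so TPs exist
    if (nrow(sc$gts) && nrow(sc$dets)) {
      k <- min(nrow(sc$gts), nrow(sc$dets))
      sc$dets[1:k, c("x1", "y1", "x2", "y2")] <-
        sc$gts[1:k, c("x1", "y1", "x2", "y2")] +
        matrix(runif(4 * k, -1, 1), k)
      sc$dets$class[1:k] <- sc$gts$class[1:k]
    }
    dets[[i]] <- sc$dets; gts[[i]] <- sc$gts
  }
  res <- mapSuite(dets, gts, mode = "standard10")
  # oracle: loop over classes and thresholds with the loop-based AP
  ths <- seq(0.5, 0.95, by = 0.05)
  aps <- matrix(NA_real_, 3, length(ths))
  for (ci in 1:3) {
    cl <- wheatClasses()[ci]
    nGT <- sum(vapply(gts, function(g) sum(g$class == cl), numeric(1)))
    if (nGT == 0) next
    for (ti in seq_along(ths)) {
      scs <- numeric(0); tps <- logical(0)
      for (i in seq_along(dets)) {
        m <- matchDetections(dets[[i]], gts[[i]], ths[ti])
        sel <- m$dets$class == cl
        scs <- c(scs, m$dets$score[sel]); tps <- c(tps, m$dets$tp[sel])
      }
      aps[ci, ti] <- oracleAveragePrecision(scs, tps, nGT)
    }
  }
  present <- which(!is.na(aps[, 1]))
  expect_equal(res$map50, mean(aps[present, 1]), tolerance = 1e-6)
  expect_equal(res$map5095, mean(rowMeans(aps[present, , drop = FALSE])),
               tolerance = 1e-6)
  expect_lte(res$map5095, res$map50 + 1e-12)
  # the 91-point protocol agrees closely on the same data
  res91 <- mapSuite(dets, gts, mode = "paper91")
  expect_lt(abs(res91$map5095 - res$map5095), 0.02)
})

test_that("a perfect detector scores 1.0 everywhere", {
  gts <- lapply(1:3, function(s) generateSyntheticScene(tinySceneConfig(), s))
  dets <- lapply(gts, function(g) {
    df <- LGWheatNet:::gtToDf(g)
    df$score <- 0.95
    df[, c("class", "score", "x1", "y1", "x2", "y2")]
  })
  res <- mapSuite(dets, gts)
  expect_equal(res$map50, 1)
  expect_equal(res$map5095, 1)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
})

test_that("greedy matching agrees with the optimal assignment on small cases", {
  set.seed(55)
  agree <- 0; total <- 0; worse <- 0
  for (i in 1:120) {
    sc <- randomScenario(sample(0:3, 1), sample(0:3, 1))
    if (!nrow(sc$dets) || !nrow(sc$gts)) next
    g <- oracleGreedyTP(sc$dets, sc$gts, 0.3)
    o <- oracleOptimalTP(sc$dets, sc$gts, 0.3)
    m <- matchDetections(sc$dets, sc$gts, 0.3)
    expect_equal(sum(m$dets$tp), g)    # implementation == greedy oracle
    expect_lte(g, o)                   # greedy never beats optimal
    total <- total + 1
    if (g == o) agree <- agree + 1 else worse <- worse + 1
  }
  # greedy-vs-optimal divergence is a rare tie-breaking artefact
  expect_gt(agree / total, 0.9)
})

test_that("confusion matrix hand cases", {
  g <- list(gt1("ripewheat", c(0, 0, 10, 10)))
  # perfect detection -> identity block
  d <- list(det1("ripewheat", 0.9, c(0, 0, 10, 10)))
  M <- confusionMatrixDet(d, g)
  expect_equal(M["ripewheat", "ripewheat"], 1)
  # no detections -> truth mass in the background row
  M0 <- confusionMatrixDet(list(det1("ripewheat", 0.9, c(0, 0, 1, 1))[0, ]), g)
  expect_equal(M0["background", "ripewheat"], 1)
  # cross-class confusion
  d2 <- list(det1("flowerwheat", 0.9, c(0, 0, 10, 10)))
  M2 <- confusionMatrixDet(d2, g)
  expect_equal(M2["flowerwheat", "ripewheat"], 1)
})

test_that("counting metrics follow their definitions", {
  m <- countingMetrics(c(3, 5, 7), c(3, 5, 7))
  expect_equal(unlist(m), c(rmse = 0, mae = 0, mse = 0, r2 = 1))
  m2 <- countingMetrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(m2$rmse, 1); expect_equal(m2$mae, 1); expect_equal(m2$mse, 1)
  expect_equal(m2$r2, 1)  # correlation form is offset-insensitive
  set.seed(9)
  t_ <- rpois(20, 8); p_ <- t_ + rnorm(20)
  m3 <- countingMetrics(t_, p_)
  expect_equal(m3$rmse^2, m3$mse, tolerance = 1e-12)
  expect_warning(countingMetrics(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})
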