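# IoU/CIoU geometry, gradients, target assignment, composite loss.

test_that("IoU hand cases", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
})

test_that("CIoU hand cases and bounds", {
  expect_equal(ciou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1, tolerance = 1e-9)
  # equal aspect ratios: v = 0; rho2 = 2, c2 = 18
  expect_equal(ciou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7 - 2 / 18,
               tolerance = 1e-7)
  expect_lt(ciou(c(0, 0, 2, 2), c(50, 50, 52, 52)), 0)
  set.seed(3)
  for (i in 1:50) {
    a <- c(runif(1, 0, 30), runif(1, 0, 30))
    a <- c(a, a + runif(2, 1, 15))
    b <- c(runif(1, 0, 30), runif(1, 0, 30))
    b <- c(b, b + runif(2, 1, 15))
    expect_lte(ciou(a, b), iou(a, b) + 1e-12)
    expect_equal(ciou(a, b), ciou(b, a), tolerance = 1e-9)  # fully symmetric
    expect_gte(1 - ciou(a, b), -1e-12)
  }
})

test_that("box-loss gradient matches finite differences", {
  set.seed(11)
  for (i in 1:25) {
    a <- c(runif(1, 0, 30), runif(1, 0, 30)); a <- c(a, a + runif(2, 2, 15))
    b <- c(runif(1, 0, 30), runif(1, 0, 30)); b <- c(b, b + runif(2, 2, 15))
    cg <- LGWheatNet:::ciouWithGrad(a, b)
    # loss = 1 - ciou; compare -grad against central differences
    for (j in 1:4) {
      e <- 1e-5
      a1 <- a; a1[j] <- a1[j] + e
      a2 <- a; a2[j] <- a2[j] - e
      fd <- ((1 - ciou(a1, b)) - (1 - ciou(a2, b))) / (2 * e)
      expect_equal(-cg$grad[j], fd, tolerance = 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("target assignment behaves on simple geometries", {
  # anchor grid 4x4, stride 8 (cells at 4, 12, 20, 28)
  an <- as.matrix(expand.grid(x = c(4, 12, 20, 28), y = c(4, 12, 20, 28)))
  A <- nrow(an)
  predBoxes <- cbind(an[, 1] - 6, an[, 2] - 6, an[, 1] + 6, an[, 2] + 6)
  predScores <- matrix(0.5, A, 3)
  # no ground truth: no positives
  asn0 <- assignTargets(matrix(0, 0, 4), integer(0), an, predScores, predBoxes)
  expect_length(asn0$fg, 0)
  expect_equal(sum(asn0$targetScores), 0)
  # one box covering one anchor
  gt <- matrix(c(0, 0, 9, 9), 1)
  asn1 <- assignTargets(gt, 1L, an, predScores, predBoxes)
  expect_true(1 %in% asn1$fg)        # the (4,4) anchor is inside
  expect_true(all(asn1$gtIdx == 1))
  # two disjoint boxes assign independently (per-box brute force)
  gt2 <- rbind(c(0, 0, 9, 9), c(16, 16, 32, 32))
  asn2 <- assignTargets(gt2, c(1L, 2L), an, predScores, predBoxes)
  for (g in 1:2) {
    sep <- assignTargets(gt2[g, , drop = FALSE], g, an, predScores, predBoxes)
    expect_setequal(asn2$fg[asn2$gtIdx == g], sep$fg)
  }
})

test_that("detection loss: empty image gives the closed-form BCE at 0.5", {
  hc <- headConfig()
  mkZero <- function(c_, h, w) array(0, c(1, c_, h, w))
  raw <- list(reg3 = mkZero(64, 4, 4), cls3 = mkZero(3, 4, 4),
              reg4 = mkZero(64, 2, 2), cls4 = mkZero(3, 2, 2),
              reg5 = mkZero(64, 1, 1), cls5 = mkZero(3, 1, 1))
  tg <- list(list(boxes = matrix(0, 0, 4), classes = integer(0)))
  ls <- detectionLoss(raw, tg, hc)
  expect_equal(ls$box, 0)
  expect_equal(ls$dfl, 0)
  expect_equal(ls$cls, -log(0.5), tolerance = 1e-9)
})

test_that("detection loss is finite/positive at random init and its gradient matches FD", {
  set.seed(4)
  m <- buildWheatNet(seed = 4)
  sc <- generateSyntheticScene(tinySceneConfig(), seed = 3)
  x <- LGWheatNet:::imageToInput(LGWheatNet:::padTo32(sc@image))
  raw <- wheatnetForward(m, x, training = TRUE)
  tg <- list(LGWheatNet:::annToTarget(sc))
  ls <- detectionLoss(raw, tg, gradients = TRUE)
  expect_true(is.finite(ls$total) && ls$total > 0)
  for (nm in c("cls3", "reg3", "reg4", "cls5")) {
    idx <- sample(length(raw[[nm]]), 3)
    for (ii in idx) {
      e <- 1e-5
      r2 <- raw; r2[[nm]][ii] <- r2[[nm]][ii] + e
      r3 <- raw; r3[[nm]][ii] <- r3[[nm]][ii] - e
      fd <- (detectionLoss(r2, tg)$total - detectionLoss(r3, tg)$total) / (2 * e)
      expect_equal(ls$grads[[nm]][ii], fd, tolerance = 2e-3 * max(1, abs(fd)))
    }
  }
})

test_that("near-perfect confident predictions drive the loss toward zero", {
  # single gt; construct raw outputs whose decode reproduces it exactly
  hc <- headConfig()
  nb <- hc$regMax
  # grid 4x4 at stride 8; gt centred on anchor (12, 12) with distances 8 px
  gt <- matrix(c(4, 4, 20, 20), 1)
  reg <- array(-15, c(1, 4 * nb, 4, 4))
  cls <- array(-15, c(1, 3, 4, 4))
  # anchor (h=2, w=2): distances 8 px = bin 1 at stride 8
  for (s in 1:4) reg[1, (s - 1) * nb + 2, 2, 2] <- 15
  cls[1, 1, 2, 2] <- 15
  raw <- list(reg3 = reg, cls3 = cls,
              reg4 = array(-15, c(1, 4 * nb, 2, 2)), cls4 = array(-15, c(1, 3, 2, 2)),
              reg5 = array(-15, c(1, 4 * nb, 1, 1)), cls5 = array(-15, c(1, 3, 1, 1)))
  tg <- list(list(boxes = gt, classes = 1L))
  ls <- detectionLoss(raw, tg, hc)
  expect_lt(ls$box, 1e-4)
  expect_lt(ls$dfl, 1e-4)
  expect_lt(ls$cls, 0.05)
})
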