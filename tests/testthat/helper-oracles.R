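# Independent oracles used across the suite. Deliberately written as plain
# loops, separate from the package's vectorised implementations.

# Average precision by explicit envelope construction over every distinct
# confidence cut (all-points interpolation).
oracleAveragePrecision <- function(scores, tp, nGT) {
  if (nGT == 0) return(NA_real_)
  if (!length(scores)) return(0)
  ord <- order(scores, decreasing = TRUE)
  tp <- tp[ord]
  n <- length(tp)
  rec <- numeric(n); prec <- numeric(n)
  cum <- 0
  for (i in seq_len(n)) {
    cum <- cum + tp[i]
    rec[i] <- cum / nGT
    prec[i] <- cum / i
  }
  # integrate max precision at recall >= r over recall steps
  ap <- 0
  prevR <- 0
  for (i in seq_len(n)) {
    if (rec[i] > prevR) {
      pmaxRight <- max(prec[i:n])
      ap <- ap + (rec[i] - prevR) * pmaxRight
      prevR <- rec[i]
    }
  }
  ap
}

# Greedy per-image matching written as nested loops (oracle for
# matchDetections), returning the TP count.
oracleGreedyTP <- function(dets, gts, thr) {
  ord <- order(dets$score, decreasing = TRUE)
  used <- rep(FALSE, nrow(gts))
  tp <- 0
  for (i in ord) {
    best <- -1; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j] || gts$class[j] != dets$class[i]) next
      v <- iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
               as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= thr) { tp <- tp + 1; used[bj] <- TRUE }
  }
  tp
}

# Optimal assignment TP count by exhaustive enumeration (dets <= 3, gts <= 3).
oracleOptimalTP <- function(dets, gts, thr) {
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0 || ng == 0) return(0)
  feas <- matrix(FALSE, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng))
    feas[i, j] <- dets$class[i] == gts$class[j] &&
      iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
          as.numeric(gts[j, c("x1", "y1", "x2", "y2")])) >= thr
  best <- 0
  assign <- function(i, usedG, count) {
    if (i > nd) { best <<- max(best, count); return(invisible()) }
    assign(i + 1, usedG, count)
    for (j in seq_len(ng)) if (!usedG[j] && feas[i, j]) {
      u2 <- usedG; u2[j] <- TRUE
      assign(i + 1, u2, count + 1)
    }
  }
  assign(1, rep(FALSE, ng), 0)
  best
}

# Layer-by-layer parameter count of an inverted-bottleneck block from its
# configuration (independent of the builder).
oracleUibParams <- function(cfg, secuib) {
  p <- 0
  i <- cfg$inChannels; e <- cfg$expanded; o <- cfg$outChannels
  if (cfg$startKernel > 0) p <- p + cfg$startKernel^2 * i + 2 * i
  p <- p + i * e + 2 * e
  if (cfg$midKernel > 0) p <- p + cfg$midKernel^2 * e + 2 * e
  p <- p + e * o + 2 * o
  if (secuib) {
    r <- max(1, round(o * cfg$seRatio))
    p <- p + o * r + r + r * o + o
  }
  p
}

oracleDwdownParams <- function(cfg) {
  cfg$inChannels * cfg$outChannels + cfg$dwKernel^2 * cfg$outChannels +
    2 * cfg$outChannels
}

oracleSppfParams <- function(cfg) {
  h <- cfg$inChannels %/% 2
  cfg$inChannels * h + 2 * h + 4 * h * cfg$outChannels + 2 * cfg$outChannels
}

# Random small detection scenario on a WxH canvas.
randomScenario <- function(nDet, nGt, size = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- function(n) {
    if (n == 0)
      return(data.frame(class = character(0), score = numeric(0),
                        x1 = numeric(0), y1 = numeric(0),
                        x2 = numeric(0), y2 = numeric(0)))
    x1 <- runif(n, 0, size - 12); y1 <- runif(n, 0, size - 12)
    data.frame(class = sample(wheatClasses(), n, replace = TRUE),
               score = runif(n), x1 = x1, y1 = y1,
               x2 = x1 + runif(n, 4, 12), y2 = y1 + runif(n, 4, 12),
               stringsAsFactors = FALSE)
  }
  list(dets = mk(nDet), gts = mk(nGt)[, -2])
}

tinySceneConfig <- function(size = 96L)
  syntheticSceneConfig(imageSize = c(size, size), spikesRange = c(2L, 4L),
                       spikeLength = c(18, 30))
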