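# Detection metrics (precision, recall, mAP at one or many IoU thresholds,
# confusion matrix) and counting metrics (RMSE, MAE, MSE, squared-correlation
# R^2).

#' Greedy matching of detections to ground truth
#'
#' Detections are visited in descending confidence; each is a true positive
#' iff the best still-unmatched ground-truth box of the same class overlaps
#' it with IoU at or above the threshold. Every ground truth is matched at
#' most once.
#'
#' @param dets detections data.frame (`class`, `score`, `x1..y2`).
#' @param gts ground truth data.frame (`class`, `x1..y2`) or
#'   [AnnotatedImage-class].
#' @param iouThreshold matching threshold.
#' @return list: `dets` (input rows ordered by descending score with a `tp`
#'   logical column), `nGT` (named per-class ground-truth counts),
#'   `unmatchedGT` (row indices of unmatched truth).
#' @export
matchDetections <- function(dets, gts, iouThreshold = 0.5) {
  if (methods::is(gts, "AnnotatedImage"))
    gts <- gtToDf(gts)
  nGT <- table(factor(gts$class, levels = wheatClasses()))
  dets <- dets[order(dets$score, decreasing = TRUE), , drop = FALSE]
  tp <- logical(nrow(dets))
  used <- logical(nrow(gts))
  for (i in seq_len(nrow(dets))) {
    cand <- which(!used & gts$class == dets$class[i])
    if (!length(cand)) next
    ious <- iouMatrix(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                      as.matrix(gts[cand, c("x1", "y1", "x2", "y2")]))[1, ]
    j <- which.max(ious)
    if (ious[j] >= iouThreshold) {
      tp[i] <- TRUE
      used[cand[j]] <- TRUE
    }
  }
  dets$tp <- tp
  list(dets = dets, nGT = nGT, unmatchedGT = which(!used))
}

#' @keywords internal
gtToDf <- function(ann) {
  data.frame(class = ann@labels,
             x1 = ann@boxes[, 1], y1 = ann@boxes[, 2],
             x2 = ann@boxes[, 3], y2 = ann@boxes[, 4],
             stringsAsFactors = FALSE)
}

#' Average precision from a scored TP/FP sequence
#'
#' Area under the monotone precision envelope of the precision-recall curve
#' (all-points interpolation). With no ground truth the value is `NA`; with
#' ground truth but no detections it is 0.
#'
#' @param scores detection confidences.
#' @param tp logical true-positive flags aligned with `scores`.
#' @param nGT number of ground-truth instances.
#' @return scalar AP.
#' @export
averagePrecision <- function(scores, tp, nGT) {
  if (nGT == 0) return(NA_real_)
  if (!length(scores)) return(0)
  ord <- order(scores, decreasing = TRUE)
  tp <- tp[ord]
  rec <- cumsum(tp) / nGT
  prec <- cumsum(tp) / seq_along(tp)
  mrec <- c(0, rec)
  mpre <- c(1, prec)
  for (i in rev(seq_len(length(mpre) - 1)))
    mpre[i] <- max(mpre[i], mpre[i + 1])
  sum(diff(mrec) * mpre[-1])
}

#' Detection metric suite over a dataset
#'
#' Computes per-class AP at IoU 0.5, mean AP over a threshold sweep
#' (`standard10`: 0.50 to 0.95 in steps of 0.05; `paper91`: steps of 0.005),
#' and precision/recall at the confidence that maximises F1 at IoU 0.5.
#'
#' @param dets list of per-image detection data.frames.
#' @param gts list of per-image ground truths ([AnnotatedImage-class] or
#'   data.frames).
#' @param mode `"standard10"` or `"paper91"`.
#' @param classes class vocabulary.
#' @return list with `precision`, `recall`, `map50`, `map5095`, `perClass`
#'   (data.frame of per-class AP50 and AP50-95), `f1Conf` (the operating
#'   confidence) and `mode`.
#' @export
mapSuite <- function(dets, gts, mode = c("standard10", "paper91"),
                     classes = wheatClasses()) {
  mode <- match.arg(mode)
  thresholds <- if (mode == "standard10") seq(0.5, 0.95, by = 0.05)
                else seq(0.5, 0.95, by = 0.005)
  gts <- lapply(gts, function(g) if (methods::is(g, "AnnotatedImage")) gtToDf(g) else g)
  nGT <- sapply(classes, function(cl)
    sum(vapply(gts, function(g) sum(g$class == cl), numeric(1))))
  # pool matches per class per threshold
  apMat <- matrix(NA_real_, length(classes), length(thresholds),
                  dimnames = list(classes, NULL))
  pooled50 <- NULL
  for (ti in seq_along(thresholds)) {
    th <- thresholds[ti]
    pooled <- list()
    for (cl in classes) pooled[[cl]] <- list(scores = numeric(0), tp = logical(0))
    for (i in seq_along(dets)) {
      m <- matchDetections(dets[[i]], gts[[i]], th)
      for (cl in classes) {
        sel <- m$dets$class == cl
        pooled[[cl]]$scores <- c(pooled[[cl]]$scores, m$dets$score[sel])
        pooled[[cl]]$tp <- c(pooled[[cl]]$tp, m$dets$tp[sel])
      }
    }
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      if (nGT[cl] > 0)
        apMat[ci, ti] <- averagePrecision(pooled[[cl]]$scores, pooled[[cl]]$tp,
                                          nGT[cl])
    }
    if (abs(th - 0.5) < 1e-9) pooled50 <- pooled
  }
  present <- which(nGT > 0)
  map50 <- mean(apMat[present, 1])
  map5095 <- mean(rowMeans(apMat[present, , drop = FALSE]))
  # operating point: confidence maximising pooled F1 at IoU 0.5
  allScores <- unlist(lapply(pooled50, `[[`, "scores"))
  allTp <- unlist(lapply(pooled50, `[[`, "tp"))
  totGT <- sum(nGT)
  if (length(allScores)) {
    ord <- order(allScores, decreasing = TRUE)
    ctp <- cumsum(allTp[ord])
    prec <- ctp / seq_along(ctp)
    rec <- ctp / max(totGT, 1)
    f1 <- 2 * prec * rec / pmax(prec + rec, 1e-12)
    bi <- which.max(f1)
    precision <- unname(prec[bi]); recall <- unname(rec[bi])
    f1Conf <- unname(allScores[ord][bi])
  } else {
    precision <- 0; recall <- 0; f1Conf <- NA_real_
  }
  perClass <- data.frame(class = classes, nGT = as.numeric(nGT),
                         ap50 = apMat[, 1], ap5095 = rowMeans(apMat))
  list(precision = precision, recall = recall, map50 = map50,
       map5095 = map5095, perClass = perClass, f1Conf = f1Conf, mode = mode)
}

#' Detection confusion matrix
#'
#' `(K+1) x (K+1)` matrix over the classes plus a background row/column,
#' indexed `[predicted, truth]`. Detections above the confidence threshold
#' are matched to ground truth greedily by IoU (class-agnostic, each side
#' used once); unmatched truth contributes to the background row, unmatched
#' detections to the background column. Rows are normalised to sum to one.
#'
#' @param dets,gts per-image lists as in [mapSuite()].
#' @param classes class vocabulary.
#' @param iouThreshold match threshold.
#' @param confThreshold detections below this are ignored.
#' @return normalised matrix with dimnames; `attr(,"counts")` holds raw
#'   counts.
#' @export
confusionMatrixDet <- function(dets, gts, classes = wheatClasses(),
                               iouThreshold = 0.5, confThreshold = 0.25) {
  K <- length(classes)
  nm <- c(classes, "background")
  M <- matrix(0, K + 1, K + 1, dimnames = list(pred = nm, truth = nm))
  gts <- lapply(gts, function(g) if (methods::is(g, "AnnotatedImage")) gtToDf(g) else g)
  for (i in seq_along(dets)) {
    d <- dets[[i]]
    d <- d[d$score >= confThreshold, , drop = FALSE]
    g <- gts[[i]]
    nd <- nrow(d); ng <- nrow(g)
    if (nd && ng) {
      ious <- iouMatrix(as.matrix(d[, c("x1", "y1", "x2", "y2")]),
                        as.matrix(g[, c("x1", "y1", "x2", "y2")]))
      dUsed <- logical(nd); gUsed <- logical(ng)
      repeat {
        ious2 <- ious
        ious2[dUsed, ] <- -1; ious2[, gUsed] <- -1
        best <- which.max(ious2)
        if (!length(best) || ious2[best] < iouThreshold) break
        di <- (best - 1) %% nd + 1; gi <- (best - 1) %/% nd + 1
        M[match(d$class[di], nm), match(g$class[gi], nm)] <-
          M[match(d$class[di], nm), match(g$class[gi], nm)] + 1
        dUsed[di] <- TRUE; gUsed[gi] <- TRUE
        if (all(dUsed) || all(gUsed)) break
      }
      for (di in which(!dUsed)) M[match(d$class[di], nm), K + 1] <-
        M[match(d$class[di], nm), K + 1] + 1
      for (gi in which(!gUsed)) M[K + 1, match(g$class[gi], nm)] <-
        M[K + 1, match(g$class[gi], nm)] + 1
    } else if (nd) {
      for (di in seq_len(nd)) M[match(d$class[di], nm), K + 1] <-
        M[match(d$class[di], nm), K + 1] + 1
    } else if (ng) {
      for (gi in seq_len(ng)) M[K + 1, match(g$class[gi], nm)] <-
        M[K + 1, match(g$class[gi], nm)] + 1
    }
  }
  counts <- M
  rs <- rowSums(M)
  M[rs > 0, ] <- M[rs > 0, ] / rs[rs > 0]
  attr(M, "counts") <- counts
  M
}

#' Counting accuracy metrics
#'
#' RMSE, MAE and MSE of predicted versus true per-image counts, and R^2 as
#' the squared Pearson correlation between the two series (insensitive to a
#' constant offset). Zero variance in either series makes the correlation
#' undefined; 0 is returned with a warning.
#'
#' @param truth,pred numeric vectors of per-image counts.
#' @return named list `rmse`, `mae`, `mse`, `r2`.
#' @export
countingMetrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  e <- truth - pred
  mse <- mean(e^2)
  r2 <- if (stats::sd(truth) == 0 || stats::sd(pred) == 0) {
    warning("zero variance in counts; R^2 reported as 0")
    0
  } else stats::cor(truth, pred)^2
  list(rmse = sqrt(mse), mae = mean(abs(e)), mse = mse, r2 = r2)
}
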