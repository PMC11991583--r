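# Box-regression geometry (IoU, complete IoU) with analytic gradients, the
# task-aligned target assigner, and the composite detection loss
# (CIoU box term + binary cross-entropy classification + distribution focal
# loss) with gradients with respect to the raw head outputs.

#' Complete IoU between two boxes
#'
#' CIoU = IoU - rho^2/c^2 - alpha v, where rho^2 is the squared centre
#' distance, c^2 the squared diagonal of the smallest enclosing box,
#' v = (4/pi^2)(atan(w_b/h_b) - atan(w_a/h_a))^2 the aspect-ratio penalty
#' and alpha = v / ((1 - IoU) + v). The associated loss is `1 - ciou(a, b)`.
#'
#' @param a,b boxes `(x1, y1, x2, y2)`; degenerate sides are clamped to a
#'   small epsilon.
#' @return CIoU value (<= IoU, and 1 only for identical boxes).
#' @export
ciou <- function(a, b) {
  ciouMatrix(matrix(a, ncol = 4), matrix(b, ncol = 4))[1, 1]
}

#' Pairwise CIoU matrix
#'
#' @param A,B matrices of boxes (rows).
#' @return `nrow(A)` x `nrow(B)` matrix.
#' @export
ciouMatrix <- function(A, B) {
  A <- matrix(A, ncol = 4); B <- matrix(B, ncol = 4)
  n <- nrow(A); m <- nrow(B)
  out <- iouMatrix(A, B)
  eps <- 1e-9
  wa <- pmax(A[, 3] - A[, 1], eps); ha <- pmax(A[, 4] - A[, 2], eps)
  wb <- pmax(B[, 3] - B[, 1], eps); hb <- pmax(B[, 4] - B[, 2], eps)
  acx <- (A[, 1] + A[, 3]) / 2; acy <- (A[, 2] + A[, 4]) / 2
  bcx <- (B[, 1] + B[, 3]) / 2; bcy <- (B[, 2] + B[, 4]) / 2
  rho2 <- outer(acx, bcx, "-")^2 + outer(acy, bcy, "-")^2
  cw <- pmax(outer(A[, 3], B[, 3], pmax) - outer(A[, 1], B[, 1], pmin), eps)
  ch <- pmax(outer(A[, 4], B[, 4], pmax) - outer(A[, 2], B[, 2], pmin), eps)
  c2 <- cw^2 + ch^2
  v <- (4 / pi^2) * outer(atan(wa / ha), atan(wb / hb), "-")^2
  alpha <- v / ((1 - out) + v + eps)
  out - rho2 / c2 - alpha * v
}

# CIoU and its gradient with respect to the first argument, vectorised over
# paired rows of A and B. Full gradient (alpha treated as a function of the
# box, not detached), so it matches finite differences of ciou().
ciouWithGrad <- function(A, B) {
  A <- matrix(A, ncol = 4); B <- matrix(B, ncol = 4)
  n <- nrow(A)
  eps <- 1e-9
  ax1 <- A[, 1]; ay1 <- A[, 2]; ax2 <- A[, 3]; ay2 <- A[, 4]
  bx1 <- B[, 1]; by1 <- B[, 2]; bx2 <- B[, 3]; by2 <- B[, 4]
  wa <- pmax(ax2 - ax1, eps); ha <- pmax(ay2 - ay1, eps)
  wb <- pmax(bx2 - bx1, eps); hb <- pmax(by2 - by1, eps)
  # intersection / union
  ix1 <- pmax(ax1, bx1); iy1 <- pmax(ay1, by1)
  ix2 <- pmin(ax2, bx2); iy2 <- pmin(ay2, by2)
  iw <- pmax(0, ix2 - ix1); ih <- pmax(0, iy2 - iy1)
  I <- iw * ih
  U <- wa * ha + wb * hb - I
  iouv <- I / pmax(U, eps)
  act <- iw > 0 & ih > 0
  dI <- matrix(0, n, 4)
  dI[, 1] <- ifelse(act & ax1 >= bx1, -ih, 0)
  dI[, 2] <- ifelse(act & ay1 >= by1, -iw, 0)
  dI[, 3] <- ifelse(act & ax2 <= bx2, ih, 0)
  dI[, 4] <- ifelse(act & ay2 <= by2, iw, 0)
  dAarea <- cbind(-ha, -wa, ha, wa)
  dU <- dAarea - dI
  dIoU <- (dI * U - I * dU) / pmax(U, eps)^2
  # centre-distance penalty
  acx <- (ax1 + ax2) / 2; acy <- (ay1 + ay2) / 2
  bcx <- (bx1 + bx2) / 2; bcy <- (by1 + by2) / 2
  rho2 <- (acx - bcx)^2 + (acy - bcy)^2
  drho2 <- cbind(acx - bcx, acy - bcy, acx - bcx, acy - bcy)
  cw <- pmax(pmax(ax2, bx2) - pmin(ax1, bx1), eps)
  ch <- pmax(pmax(ay2, by2) - pmin(ay1, by1), eps)
  c2 <- cw^2 + ch^2
  dc2 <- cbind(ifelse(ax1 < bx1, -2 * cw, 0), ifelse(ay1 < by1, -2 * ch, 0),
               ifelse(ax2 > bx2, 2 * cw, 0), ifelse(ay2 > by2, 2 * ch, 0))
  dpen <- (drho2 * c2 - rho2 * dc2) / c2^2
  # aspect-ratio penalty
  D <- atan(wb / hb) - atan(wa / ha)
  v <- (4 / pi^2) * D^2
  dD_dwa <- -ha / (ha^2 + wa^2)
  dD_dha <- wa / (ha^2 + wa^2)
  dv_dwa <- (8 / pi^2) * D * dD_dwa
  dv_dha <- (8 / pi^2) * D * dD_dha
  dv <- cbind(-dv_dwa, -dv_dha, dv_dwa, dv_dha)
  denom <- (1 - iouv) + v + eps
  alpha <- v / denom
  # d(alpha v) = alpha dv + v dalpha; dalpha = (dv (1 - iou) + v dIoU)/denom^2
  dalpha <- (dv * (1 - iouv) + v * dIoU) / denom^2
  dav <- alpha * dv + v * dalpha
  ciouv <- iouv - rho2 / c2 - alpha * v
  list(ciou = ciouv, grad = dIoU - dpen - dav)
}

#' Task-aligned assignment of ground truth to anchors
#'
#' Alignment metric `score^alpha * CIoU^beta` between each anchor's decoded
#' prediction and each ground-truth box; only anchors whose centre lies
#' inside the box are candidates; the top-k candidates per ground truth
#' become positives. An anchor claimed by several boxes goes to the one with
#' the highest overlap. Per-anchor target scores are the alignment metric
#' normalised so that each box's best anchor scores its best overlap.
#'
#' @param gtBoxes G x 4 matrix (pixels); may have zero rows.
#' @param gtClasses integer class ids (1-based), length G.
#' @param anchors A x 2 anchor centres (pixels).
#' @param predScores A x nc sigmoid class scores.
#' @param predBoxes A x 4 decoded boxes (pixels).
#' @param topk candidates per ground truth.
#' @param alpha,beta alignment exponents.
#' @return list with `fg` (positive anchor indices), `gtIdx` (assigned box
#'   per positive), `targetScores` (length A), `targetBoxes`, `targetClasses`
#'   (per positive).
#' @export
assignTargets <- function(gtBoxes, gtClasses, anchors, predScores, predBoxes,
                          topk = 10L, alpha = 0.5, beta = 6.0) {
  A <- nrow(anchors)
  empty <- list(fg = integer(0), gtIdx = integer(0),
                targetScores = numeric(A),
                targetBoxes = matrix(0, 0, 4), targetClasses = integer(0))
  if (is.null(gtBoxes) || nrow(matrix(gtBoxes, ncol = 4)) == 0) return(empty)
  gtBoxes <- matrix(gtBoxes, ncol = 4)
  G <- nrow(gtBoxes)
  inside <- outer(anchors[, 1], gtBoxes[, 1], ">") &
            outer(anchors[, 1], gtBoxes[, 3], "<") &
            outer(anchors[, 2], gtBoxes[, 2], ">") &
            outer(anchors[, 2], gtBoxes[, 4], "<")
  ov <- pmax(ciouMatrix(predBoxes, gtBoxes), 0)
  sc <- predScores[, gtClasses, drop = FALSE]
  align <- (sc^alpha) * (ov^beta)
  align[!inside] <- 0
  sel <- matrix(FALSE, A, G)
  for (g in seq_len(G)) {
    cand <- which(align[, g] > 0)
    if (!length(cand)) next
    kk <- cand[order(align[cand, g], decreasing = TRUE)][seq_len(min(topk, length(cand)))]
    sel[kk, g] <- TRUE
  }
  fg <- which(rowSums(sel) > 0)
  if (!length(fg)) return(empty)
  gtIdx <- vapply(fg, function(a) {
    gs <- which(sel[a, ])
    gs[which.max(ov[a, gs])]
  }, integer(1))
  # normalised target scores
  targetScores <- numeric(A)
  for (g in unique(gtIdx)) {
    aidx <- fg[gtIdx == g]
    amax <- max(align[aidx, g])
    omax <- max(ov[aidx, g])
    targetScores[aidx] <- align[aidx, g] / max(amax, 1e-9) * omax
  }
  list(fg = fg, gtIdx = gtIdx, targetScores = targetScores,
       targetBoxes = gtBoxes[gtIdx, , drop = FALSE],
       targetClasses = gtClasses[gtIdx])
}

# Flatten raw head outputs of image n into matrices plus anchor geometry.
flattenOutputs <- function(raw, n, headCfg, strides) {
  nb <- headCfg$regMax; nc <- headCfg$numClasses
  regs <- list(); clss <- list(); ancs <- list(); strs <- list(); dims <- list()
  for (li in seq_along(strides)) {
    reg <- raw[[paste0("reg", li + 2)]]
    cls <- raw[[paste0("cls", li + 2)]]
    h <- dim(reg)[3]; w <- dim(reg)[4]
    regs[[li]] <- matrix(reg[n, , , ], nrow = 4 * nb)
    clss[[li]] <- matrix(cls[n, , , ], nrow = nc)
    ancs[[li]] <- anchorCenters(h, w, strides[li])
    strs[[li]] <- rep(strides[li], h * w)
    dims[[li]] <- c(h, w)
  }
  list(reg = do.call(cbind, regs), cls = do.call(cbind, clss),
       anchors = do.call(rbind, ancs), stride = unlist(strs),
       dims = dims, counts = vapply(dims, prod, numeric(1)))
}

# softmax probabilities and expectation per side; reg: (4*nb) x A
dflProbs <- function(reg, nb) {
  A <- ncol(reg)
  probs <- array(0, c(nb, 4, A))
  expd <- matrix(0, A, 4)
  for (s in 1:4) {
    z <- reg[(s - 1) * nb + seq_len(nb), , drop = FALSE]
    z <- exp(sweep(z, 2, apply(z, 2, max)))
    p <- sweep(z, 2, colSums(z), "/")
    probs[, s, ] <- p
    expd[, s] <- colSums(p * (seq_len(nb) - 1))
  }
  list(probs = probs, expd = expd)
}

#' Composite detection loss
#'
#' CIoU box loss and distribution focal loss over assigned positives plus
#' binary cross-entropy over all cells, normalised by the summed target
#' scores, with weights `lambda = (box, cls, dfl)`. Optionally returns
#' gradients with respect to every raw head output, ready for
#' backpropagation.
#'
#' @param raw named list of raw head outputs (batched).
#' @param targets list (length batch) of lists with elements `boxes`
#'   (G x 4 pixel matrix) and `classes` (integer ids); `G = 0` allowed.
#' @param headCfg,strides model head configuration and level strides.
#' @param lambda loss weights `c(box, cls, dfl)`.
#' @param gradients logical; also return `grads` (named like `raw`).
#' @return list with `total`, `box`, `cls`, `dfl` (scalars) and optionally
#'   `grads`.
#' @export
detectionLoss <- function(raw, targets, headCfg = headConfig(),
                          strides = c(8L, 16L, 32L),
                          lambda = c(box = 7.5, cls = 0.5, dfl = 1.5),
                          gradients = FALSE) {
  N <- dim(raw$reg3)[1]
  nb <- headCfg$regMax; nc <- headCfg$numClasses
  totBox <- 0; totCls <- 0; totDfl <- 0
  grads <- NULL
  if (gradients)
    grads <- lapply(raw, function(a) array(0, dim(a)))
  for (n in seq_len(N)) {
    fl <- flattenOutputs(raw, n, headCfg, strides)
    A <- ncol(fl$reg)
    dp <- dflProbs(fl$reg, nb)
    dists <- dp$expd * fl$stride
    predBoxes <- cbind(fl$anchors[, 1] - dists[, 1], fl$anchors[, 2] - dists[, 2],
                       fl$anchors[, 1] + dists[, 3], fl$anchors[, 2] + dists[, 4])
    scores <- 1 / (1 + exp(-t(fl$cls)))  # A x nc
    tg <- targets[[n]]
    asn <- assignTargets(tg$boxes, tg$classes, fl$anchors, scores, predBoxes)
    Y <- matrix(0, A, nc)
    if (length(asn$fg))
      Y[cbind(asn$fg, asn$targetClasses)] <- asn$targetScores[asn$fg]
    tss <- max(sum(asn$targetScores), 1)
    # classification BCE: summed and normalised by the summed target scores;
    # with no positives at all this falls back to the plain per-entry mean.
    eps <- 1e-12
    bce <- -(Y * log(scores + eps) + (1 - Y) * log(1 - scores + eps))
    clsDenom <- if (length(asn$fg)) tss else length(bce)
    lCls <- sum(bce) / clsDenom
    lBox <- 0; lDfl <- 0
    if (length(asn$fg)) {
      wgt <- asn$targetScores[asn$fg]
      cg <- ciouWithGrad(predBoxes[asn$fg, , drop = FALSE], asn$targetBoxes)
      lBox <- sum((1 - cg$ciou) * wgt) / tss
      # DFL target distances in stride units
      s_fg <- fl$stride[asn$fg]
      an_fg <- fl$anchors[asn$fg, , drop = FALSE]
      tb <- asn$targetBoxes
      td <- cbind(an_fg[, 1] - tb[, 1], an_fg[, 2] - tb[, 2],
                  tb[, 3] - an_fg[, 1], tb[, 4] - an_fg[, 2]) / s_fg
      td <- pmin(pmax(td, 0), nb - 1 - 0.01)
      tl <- floor(td); tu <- tl + 1
      wl <- tu - td; wu <- td - tl
      ce <- matrix(0, length(asn$fg), 4)
      for (s in 1:4) {
        p <- dp$probs[, s, asn$fg, drop = FALSE][, 1, ]
        p <- matrix(p, nrow = nb)
        pl <- p[cbind(tl[, s] + 1, seq_along(asn$fg))]
        pu <- p[cbind(pmin(tu[, s], nb - 1) + 1, seq_along(asn$fg))]
        ce[, s] <- -(wl[, s] * log(pl + eps) + wu[, s] * log(pu + eps))
      }
      lDfl <- sum(rowMeans(ce) * wgt) / tss
    }
    totBox <- totBox + lBox; totCls <- totCls + lCls; totDfl <- totDfl + lDfl
    if (gradients) {
      # classification gradient: (sigmoid - Y) * lambda_cls / normaliser
      gCls <- t(scores - Y) * lambda[["cls"]] / clsDenom  # nc x A
      gReg <- matrix(0, 4 * nb, A)
      if (length(asn$fg)) {
        wgt <- asn$targetScores[asn$fg]
        # box loss gradient -> decoded box -> distances -> bin logits
        dLdBox <- -cg$grad * (wgt * lambda[["box"]] / tss)  # d(1-ciou)*w/tss
        s_fg <- fl$stride[asn$fg]
        # box = (cx - l s, cy - t s, cx + r s, cy + b s)
        dLdD <- cbind(-dLdBox[, 1], -dLdBox[, 2], dLdBox[, 3], dLdBox[, 4]) * s_fg
        tb <- asn$targetBoxes
        an_fg <- fl$anchors[asn$fg, , drop = FALSE]
        td <- cbind(an_fg[, 1] - tb[, 1], an_fg[, 2] - tb[, 2],
                    tb[, 3] - an_fg[, 1], tb[, 4] - an_fg[, 2]) / s_fg
        td <- pmin(pmax(td, 0), nb - 1 - 0.01)
        tl <- floor(td); tu <- tl + 1
        wl <- tu - td; wu <- td - tl
        for (s in 1:4) {
          p <- matrix(dp$probs[, s, asn$fg, drop = FALSE][, 1, ], nrow = nb)
          E <- dp$expd[asn$fg, s]
          # expectation path: dE/dz_k = p_k (k - E)
          gExp <- sweep(p * (matrix(seq_len(nb) - 1, nb, length(asn$fg)) -
                             matrix(E, nb, length(asn$fg), byrow = TRUE)),
                        2, dLdD[, s], "*")
          # DFL cross-entropy path: p - target distribution
          tdist <- matrix(0, nb, length(asn$fg))
          tdist[cbind(tl[, s] + 1, seq_along(asn$fg))] <-
            tdist[cbind(tl[, s] + 1, seq_along(asn$fg))] + wl[, s]
          tdist[cbind(pmin(tu[, s], nb - 1) + 1, seq_along(asn$fg))] <-
            tdist[cbind(pmin(tu[, s], nb - 1) + 1, seq_along(asn$fg))] + wu[, s]
          gCe <- sweep(p - tdist, 2, wgt * lambda[["dfl"]] / (4 * tss), "*")
          gReg[(s - 1) * nb + seq_len(nb), asn$fg] <-
            gReg[(s - 1) * nb + seq_len(nb), asn$fg] + gExp + gCe
        }
      }
      # scatter back into per-level arrays
      at <- 0
      for (li in seq_along(strides)) {
        cnt <- fl$counts[li]
        idx <- (at + 1):(at + cnt)
        h <- fl$dims[[li]][1]; w <- fl$dims[[li]][2]
        grads[[paste0("reg", li + 2)]][n, , , ] <-
          array(gReg[, idx], c(4 * nb, h, w))
        grads[[paste0("cls", li + 2)]][n, , , ] <-
          array(gCls[, idx], c(nc, h, w))
        at <- at + cnt
      }
    }
  }
  out <- list(total = (lambda[["box"]] * totBox + lambda[["cls"]] * totCls +
                       lambda[["dfl"]] * totDfl) / N,
              box = totBox / N, cls = totCls / N, dfl = totDfl / N)
  if (gradients) {
    out$grads <- lapply(grads, function(g) g / N)
  }
  out
}
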