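# Box geometry utilities: pairwise IoU and greedy non-maximum suppression.

#' Intersection over union of two boxes
#'
#' Boxes are `(x1, y1, x2, y2)` with `x2 > x1`, `y2 > y1`. Disjoint boxes
#' score 0.
#'
#' @param a,b numeric length-4 vectors.
#' @return IoU in [0, 1].
#' @export
iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Pairwise IoU matrix
#'
#' @param A,B matrices with 4 columns `(x1, y1, x2, y2)`, one box per row.
#' @return `nrow(A)` x `nrow(B)` matrix of IoU values.
#' @export
iouMatrix <- function(A, B) {
  A <- matrix(A, ncol = 4)
  B <- matrix(B, ncol = 4)
  n <- nrow(A); m <- nrow(B)
  ix1 <- pmax(matrix(A[, 1], n, m), matrix(B[, 1], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(A[, 2], n, m), matrix(B[, 2], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(A[, 3], n, m), matrix(B[, 3], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(A[, 4], n, m), matrix(B[, 4], n, m, byrow = TRUE))
  inter <- pmax(0, ix2 - ix1) * pmax(0, iy2 - iy1)
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  un <- matrix(areaA, n, m) + matrix(areaB, n, m, byrow = TRUE) - inter
  out <- inter / pmax(un, .Machine$double.eps)
  out[un <= 0] <- 0
  out
}

#' Greedy non-maximum suppression
#'
#' Keeps boxes in descending score order, suppressing any remaining box whose
#' IoU with a kept box exceeds `iouThreshold`.
#'
#' @param boxes matrix with 4 columns.
#' @param scores numeric vector.
#' @param iouThreshold overlap threshold.
#' @return integer indices of kept boxes (in original order).
#' @export
nmsBoxes <- function(boxes, scores, iouThreshold = 0.5) {
  boxes <- matrix(boxes, ncol = 4)
  n <- nrow(boxes)
  if (n == 0) return(integer(0))
  ord <- order(scores, decreasing = TRUE)
  alive <- rep(TRUE, n)  # positions within ord
  keep <- integer(0)
  for (ii in seq_len(n)) {
    if (!alive[ii]) next
    i <- ord[ii]
    keep <- c(keep, i)
    if (ii < n) {
      cand <- ((ii + 1):n)[alive[(ii + 1):n]]
      if (length(cand)) {
        ious <- iouMatrix(boxes[i, , drop = FALSE],
                          boxes[ord[cand], , drop = FALSE])[1, ]
        alive[cand[ious > iouThreshold]] <- FALSE
      }
    }
  }
  keep
}

# class-wise NMS: returns indices kept across all classes
classwiseNms <- function(boxes, scores, classes, iouThreshold = 0.5) {
  keep <- integer(0)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    k <- nmsBoxes(boxes[idx, , drop = FALSE], scores[idx], iouThreshold)
    keep <- c(keep, idx[k])
  }
  keep[order(scores[keep], decreasing = TRUE)]
}
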