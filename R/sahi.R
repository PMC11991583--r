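# Sliced inference for large images: overlapping slice grids, per-slice
# detection, coordinate remapping, overlap-aware merging and region counts.

#' Grid of overlapping slices
#'
#' @slot windows matrix with columns `x0, y0, w, h` (0-based source pixels).
#' @slot sliceSize nominal slice side.
#' @slot overlap overlap ratio.
#' @export
setClass("SliceGrid",
         representation(windows = "matrix", sliceSize = "integer",
                        overlap = "numeric"))

setMethod("show", "SliceGrid", function(object) {
  cat(sprintf("SliceGrid: %d windows of %d px, overlap %.2f\n",
              nrow(object@windows), object@sliceSize, object@overlap))
})

#' Compute the slice grid for an image
#'
#' Along each axis, window starts advance by `floor(S (1 - overlap))`; a
#' start that would overrun the image is replaced by the single clamped
#' start `max(0, dim - S)`, and an axis no longer than `S` gets one window
#' of size `min(S, dim)`. Every pixel is covered and adjacent windows share
#' at least `floor(S * overlap)` pixels except where border clamping forces
#' more.
#'
#' @param width,height source image size in pixels.
#' @param sliceSize nominal slice side (default 256).
#' @param overlap overlap ratio in [0, 1) (default 0.1).
#' @return [SliceGrid-class].
#' @export
computeSlices <- function(width, height, sliceSize = 256L, overlap = 0.1) {
  stopifnot(width >= 1, height >= 1, overlap >= 0, overlap < 1)
  S <- as.integer(sliceSize)
  axisStarts <- function(dim) {
    if (dim <= S) return(list(starts = 0, size = min(S, dim)))
    step <- floor(S * (1 - overlap))
    starts <- seq(0, dim - 1, by = step)
    over <- starts + S > dim
    starts <- c(starts[!over], max(0, dim - S))
    list(starts = unique(starts), size = S)
  }
  ax <- axisStarts(width); ay <- axisStarts(height)
  wins <- as.matrix(expand.grid(x0 = ax$starts, y0 = ay$starts))
  wins <- cbind(wins, w = pmin(ax$size, width - wins[, 1]),
                h = pmin(ay$size, height - wins[, 2]))
  methods::new("SliceGrid", windows = wins, sliceSize = S,
               overlap = as.numeric(overlap))
}

#' Sliced prediction over a large image
#'
#' Runs a detector on every slice of the grid, shifts each detection by its
#' window origin, pools across slices and merges duplicates with class-wise
#' greedy NMS. Border windows smaller than the slice size are zero-padded on
#' the right/bottom before detection.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param detector either a [WheatNet-class] model or a function
#'   `function(image)` returning a detections data.frame in slice
#'   coordinates (useful for stub detectors in tests).
#' @param grid [SliceGrid-class]; computed from the image and defaults when
#'   `NULL`.
#' @param mergeIou NMS threshold applied to the pooled detections.
#' @param confThreshold per-slice confidence threshold (model detectors).
#' @param borderMargin detections clipped at an interior window edge (within
#'   this many pixels) are dropped before merging: the overlapping
#'   neighbouring window sees the same object untruncated, so border
#'   fragments only create duplicates. Edges that coincide with the source
#'   image border are exempt. The default only removes boxes clipped
#'   essentially exactly at the edge; raise it if a detector regresses
#'   truncated boxes slightly inside the slice.
#' @return detections data.frame in source-image coordinates, clipped.
#' @export
slicePredict <- function(image, detector, grid = NULL, mergeIou = 0.5,
                         confThreshold = 0.25, borderMargin = 0.01) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.null(grid)) grid <- computeSlices(W, H)
  S <- grid@sliceSize
  all <- list()
  for (i in seq_len(nrow(grid@windows))) {
    wn <- grid@windows[i, ]
    ys <- (wn["y0"] + 1):(wn["y0"] + wn["h"])
    xs <- (wn["x0"] + 1):(wn["x0"] + wn["w"])
    crop <- image[ys, xs, , drop = FALSE]
    if (wn["h"] < S || wn["w"] < S) {
      padded <- array(0, c(S, S, 3))
      padded[seq_len(wn["h"]), seq_len(wn["w"]), ] <- crop
      crop <- padded
    }
    attr(crop, "window") <- wn   # (x0, y0, w, h), for window-aware detectors
    d <- if (methods::is(detector, "WheatNet"))
      detectImage(detector, crop, confThreshold = confThreshold)
    else detector(crop)
    if (nrow(d)) {
      # suppress fragments cut off by an interior slice edge
      cut <- (d$x1 < borderMargin & wn["x0"] > 0) |
             (d$y1 < borderMargin & wn["y0"] > 0) |
             (d$x2 > wn["w"] - borderMargin & wn["x0"] + wn["w"] < W) |
             (d$y2 > wn["h"] - borderMargin & wn["y0"] + wn["h"] < H)
      big <- (d$x2 - d$x1) > 0.8 * wn["w"] | (d$y2 - d$y1) > 0.8 * wn["h"]
      d <- d[!cut | big, , drop = FALSE]
    }
    if (nrow(d)) {
      d$x1 <- d$x1 + wn["x0"]; d$x2 <- d$x2 + wn["x0"]
      d$y1 <- d$y1 + wn["y0"]; d$y2 <- d$y2 + wn["y0"]
      all[[length(all) + 1]] <- d
    }
  }
  if (!length(all)) return(emptyDetections())
  pooled <- do.call(rbind, all)
  pooled$x1 <- pmin(pmax(pooled$x1, 0), W); pooled$x2 <- pmin(pmax(pooled$x2, 0), W)
  pooled$y1 <- pmin(pmax(pooled$y1, 0), H); pooled$y2 <- pmin(pmax(pooled$y2, 0), H)
  pooled <- pooled[pooled$x2 > pooled$x1 & pooled$y2 > pooled$y1, , drop = FALSE]
  keep <- classwiseNms(as.matrix(pooled[, c("x1", "y1", "x2", "y2")]),
                       pooled$score, pooled$class, mergeIou)
  out <- pooled[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-region detection counts
#'
#' A detection is counted in a region iff its box centre lies inside it,
#' with a half-open rule (left/top edges inclusive, right/bottom exclusive)
#' so a centre on a shared boundary belongs to exactly one of two abutting
#' regions. Overlapping regions are allowed; a detection may then count in
#' several.
#'
#' @param dets detections data.frame.
#' @param regions matrix with columns `x1, y1, x2, y2`, or `NULL` for the
#'   whole image (one region).
#' @param imageSize `(H, W)`; required when `regions` is `NULL`.
#' @return list with `counts` (per region) and `total` (all detections).
#' @export
countRegions <- function(dets, regions = NULL, imageSize = NULL) {
  if (is.null(regions)) {
    if (is.null(imageSize)) stop("imageSize required when regions is NULL")
    regions <- matrix(c(0, 0, imageSize[2], imageSize[1]), 1)
  }
  regions <- matrix(regions, ncol = 4)
  cx <- (dets$x1 + dets$x2) / 2
  cy <- (dets$y1 + dets$y2) / 2
  counts <- apply(regions, 1, function(r)
    sum(cx >= r[1] & cx < r[3] & cy >= r[2] & cy < r[4]))
  list(counts = counts, total = nrow(dets))
}
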