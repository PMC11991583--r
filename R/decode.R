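# Prediction decoding: distribution-focal-loss box regression around anchor
# points, sigmoid class scores, confidence filtering and class-wise NMS.

#' Anchor centre points for one pyramid level
#'
#' Cell (row h, col w) of a level with stride s has its anchor at
#' `((w + 0.5) s, (h + 0.5) s)` in image pixels.
#'
#' @param h,w level grid size.
#' @param stride level stride in pixels.
#' @return matrix `[h*w, 2]` of (x, y) centres; rows ordered column-major
#'   (h fastest), matching the flattening of a `[C, h, w]` feature map.
#' @keywords internal
anchorCenters <- function(h, w, stride) {
  hh <- rep(seq_len(h) - 0.5, times = w)
  ww <- rep(seq_len(w) - 0.5, each = h)
  cbind(x = ww * stride, y = hh * stride)
}

# DFL expectation decode for one level and one image.
# reg: [4*regMax, h, w] raw logits -> distances (l, t, r, b) in stride units.
dflExpect <- function(regMat, regMax) {
  nb <- regMax
  out <- matrix(0, nrow = ncol(regMat), ncol = 4)
  for (s in 1:4) {
    z <- regMat[(s - 1) * nb + seq_len(nb), , drop = FALSE]
    z <- exp(sweep(z, 2, apply(z, 2, max)))
    p <- sweep(z, 2, colSums(z), "/")
    out[, s] <- colSums(p * (seq_len(nb) - 1))
  }
  out
}

#' Decode raw head outputs into detections
#'
#' Per cell, the four box distances are the expectations of the softmaxed
#' regression bins, scaled by the level stride around the cell's anchor
#' point; class scores are sigmoid logits. Detections below
#' `confThreshold` are dropped and class-wise greedy NMS at `iouThreshold`
#' merges the rest. Boxes are clipped to the image.
#'
#' @param raw named list of raw outputs (`reg3`, `cls3`, ...) as returned by
#'   [wheatnetForward()] for a single image (batch size 1).
#' @param headCfg [headConfig()] used to build the model.
#' @param strides integer strides of the levels (default 8/16/32).
#' @param confThreshold minimum class score.
#' @param iouThreshold NMS overlap threshold.
#' @param imageSize `(H, W)` of the input image, for clipping.
#' @param classes character vector of class names.
#' @return data.frame with columns `class`, `score`, `x1`, `y1`, `x2`, `y2`
#'   (pixel coordinates, 0-based half-open).
#' @export
decodePredictions <- function(raw, headCfg = headConfig(),
                              strides = c(8L, 16L, 32L),
                              confThreshold = 0.25, iouThreshold = 0.5,
                              imageSize = NULL, classes = wheatClasses()) {
  nb <- headCfg$regMax
  nc <- headCfg$numClasses
  allBoxes <- NULL; allScores <- NULL; allClasses <- NULL
  for (li in seq_along(strides)) {
    reg <- raw[[paste0("reg", li + 2)]]
    cls <- raw[[paste0("cls", li + 2)]]
    if (dim(reg)[1] != 1) stop("decodePredictions expects a single image")
    h <- dim(reg)[3]; w <- dim(reg)[4]
    regMat <- matrix(reg[1, , , ], nrow = 4 * nb)
    clsMat <- matrix(cls[1, , , ], nrow = nc)
    sc <- 1 / (1 + exp(-clsMat))
    best <- apply(sc, 2, max)
    keep <- which(best > confThreshold)
    if (!length(keep)) next
    an <- anchorCenters(h, w, strides[li])
    d <- dflExpect(regMat[, keep, drop = FALSE], nb) * strides[li]
    boxes <- cbind(an[keep, 1] - d[, 1], an[keep, 2] - d[, 2],
                   an[keep, 1] + d[, 3], an[keep, 2] + d[, 4])
    cl <- apply(sc[, keep, drop = FALSE], 2, which.max)
    allBoxes <- rbind(allBoxes, boxes)
    allScores <- c(allScores, best[keep])
    allClasses <- c(allClasses, cl)
  }
  if (is.null(allBoxes))
    return(emptyDetections(classes))
  if (!is.null(imageSize)) {
    allBoxes[, c(1, 3)] <- pmin(pmax(allBoxes[, c(1, 3)], 0), imageSize[2])
    allBoxes[, c(2, 4)] <- pmin(pmax(allBoxes[, c(2, 4)], 0), imageSize[1])
  }
  keep <- classwiseNms(allBoxes, allScores, allClasses, iouThreshold)
  data.frame(class = classes[allClasses[keep]],
             score = allScores[keep],
             x1 = allBoxes[keep, 1], y1 = allBoxes[keep, 2],
             x2 = allBoxes[keep, 3], y2 = allBoxes[keep, 4],
             stringsAsFactors = FALSE)
}

#' @keywords internal
emptyDetections <- function(classes = wheatClasses()) {
  data.frame(class = character(0), score = numeric(0),
             x1 = numeric(0), y1 = numeric(0),
             x2 = numeric(0), y2 = numeric(0), stringsAsFactors = FALSE)
}

#' The annotation vocabulary: three wheat growth stages
#'
#' @return character vector of the class names.
#' @export
wheatClasses <- function() c("flowerwheat", "fillingwheat", "ripewheat")

#' Run the detector on one image
#'
#' Convenience wrapper: converts an image (H x W x 3 array in [0, 1] or an
#' [AnnotatedImage-class]) to network input, pads to a multiple of 32, runs
#' the forward pass in evaluation mode and decodes detections in original
#' image coordinates.
#'
#' @param model a [WheatNet-class].
#' @param image H x W x 3 array or [AnnotatedImage-class].
#' @param confThreshold,iouThreshold see [decodePredictions()].
#' @return detections data.frame.
#' @export
detectImage <- function(model, image, confThreshold = 0.25, iouThreshold = 0.5) {
  if (methods::is(image, "AnnotatedImage")) image <- image@image
  d <- dim(image)
  hp <- ceiling(d[1] / 32) * 32
  wp <- ceiling(d[2] / 32) * 32
  x <- array(0, c(1, 3, hp, wp))
  for (c_ in 1:3) x[1, c_, seq_len(d[1]), seq_len(d[2])] <- image[, , c_]
  raw <- wheatnetForward(model, x, training = FALSE)
  decodePredictions(raw, model@headCfg, model@strides,
                    confThreshold, iouThreshold, imageSize = d[1:2])
}
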