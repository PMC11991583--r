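#' Annotated field image
#'
#' An RGB image together with its ground-truth spike boxes and growth-stage
#' labels. Pixel values are doubles in [0, 1]; boxes use 0-based, half-open
#' pixel coordinates `[x1, x2) x [y1, y2)` internally (the VOC files on disk
#' use the 1-based inclusive dialect, see [readVOC()]).
#'
#' @slot image H x W x 3 array in [0, 1].
#' @slot boxes numeric matrix with columns `x1, y1, x2, y2`.
#' @slot labels character vector of class names, one per box.
#' @export
setClass("AnnotatedImage",
         representation(image = "array", boxes = "matrix", labels = "character"),
         validity = function(object) {
  d <- dim(object@image)
  if (length(d) != 3 || d[3] != 3) return("image must be H x W x 3")
  b <- object@boxes
  if (nrow(b) != length(object@labels)) return("one label per box required")
  if (nrow(b)) {
    if (ncol(b) != 4) return("boxes must have 4 columns")
    if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2]))
      return("boxes must satisfy x2 > x1, y2 > y1")
    if (any(b[, 1] < 0) || any(b[, 2] < 0) ||
        any(b[, 3] > d[2]) || any(b[, 4] > d[1]))
      return("boxes must lie inside the image")
    if (!all(object@labels %in% wheatClasses()))
      return("unknown class label")
  }
  TRUE
})

#' Construct an annotated image
#'
#' @param image H x W x 3 array in [0, 1].
#' @param boxes matrix with columns `x1, y1, x2, y2` (0-based half-open).
#' @param labels character class names from [wheatClasses()].
#' @return [AnnotatedImage-class] object.
#' @export
annotatedImage <- function(image, boxes = matrix(0, 0, 4), labels = character(0)) {
  boxes <- matrix(as.numeric(boxes), ncol = 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  methods::new("AnnotatedImage", image = image, boxes = boxes,
               labels = as.character(labels))
}

#' @describeIn annotatedImage pixel array accessor.
#' @param x an `AnnotatedImage`.
#' @export
imgData <- function(x) x@image

#' @describeIn annotatedImage ground-truth box matrix accessor.
#' @export
gtBoxes <- function(x) x@boxes

#' @describeIn annotatedImage ground-truth label accessor.
#' @export
gtLabels <- function(x) x@labels

setMethod("show", "AnnotatedImage", function(object) {
  d <- dim(object@image)
  cat(sprintf("AnnotatedImage %d x %d, %d object(s)\n", d[2], d[1],
              nrow(object@boxes)))
  if (nrow(object@boxes))
    print(table(object@labels))
})

# image (H x W x 3, [0,1]) -> network input [1, 3, H, W]
imageToInput <- function(image) {
  d <- dim(image)
  x <- aperm(image, c(3, 1, 2))
  dim(x) <- c(1, 3, d[1], d[2])
  x
}

# ground truth of an AnnotatedImage as a detectionLoss target
annToTarget <- function(ann, classes = wheatClasses()) {
  list(boxes = ann@boxes, classes = match(ann@labels, classes))
}
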