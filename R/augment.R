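# Offline augmentation suite: random noise, brightness, occlusion patches,
# rotation, cropping, translation and mirroring, with consistent box
# transforms. Occlusion does not modify ground truth (it simulates leaf
# cover over still-annotated spikes); geometric transforms clip boxes and
# drop those whose surviving area falls below a quarter of the original.

#' Augmentation specification
#'
#' All effects default to "off"; set the fields you want. Ranges are
#' sampled uniformly per call.
#'
#' @param gaussianNoiseSd standard deviation of additive Gaussian noise on
#'   the [0, 1] intensity scale (0 disables).
#' @param saltPepperFrac fraction of pixels replaced by 0 or 1 (0 disables).
#' @param brightnessRange multiplicative brightness factor range.
#' @param occlusionCount number of occluding patches.
#' @param occlusionSize patch side range as a fraction of the shorter image
#'   side.
#' @param rotationDegrees maximum absolute rotation angle (degrees).
#' @param cropFraction maximum fraction of each side cropped away before
#'   resizing back (0 disables).
#' @param translateFraction maximum shift as a fraction of the image size.
#' @param mirrorProb probability of a horizontal mirror.
#' @param seed optional integer seed; when given, [augmentScene()] is
#'   deterministic.
#' @return specification list.
#' @export
augmentationSpec <- function(gaussianNoiseSd = 0, saltPepperFrac = 0,
                             brightnessRange = c(1, 1), occlusionCount = 0,
                             occlusionSize = c(0.08, 0.2),
                             rotationDegrees = 0, cropFraction = 0,
                             translateFraction = 0, mirrorProb = 0,
                             seed = NULL) {
  stopifnot(brightnessRange[1] <= brightnessRange[2],
            occlusionSize[1] <= occlusionSize[2],
            mirrorProb >= 0, mirrorProb <= 1,
            cropFraction >= 0, cropFraction < 1)
  list(gaussianNoiseSd = gaussianNoiseSd, saltPepperFrac = saltPepperFrac,
       brightnessRange = brightnessRange, occlusionCount = occlusionCount,
       occlusionSize = occlusionSize, rotationDegrees = rotationDegrees,
       cropFraction = cropFraction, translateFraction = translateFraction,
       mirrorProb = mirrorProb, seed = seed)
}

# clip boxes to [0,W]x[0,H]; drop those keeping < minKeep of their area
clipBoxes <- function(boxes, labels, W, H, minKeep = 0.25) {
  if (!nrow(boxes)) return(list(boxes = boxes, labels = labels))
  area0 <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
  cb <- cbind(pmax(boxes[, 1], 0), pmax(boxes[, 2], 0),
              pmin(boxes[, 3], W), pmin(boxes[, 4], H))
  area1 <- pmax(cb[, 3] - cb[, 1], 0) * pmax(cb[, 4] - cb[, 2], 0)
  keep <- area1 >= minKeep * area0 & area1 > 1
  list(boxes = matrix(cb[keep, ], ncol = 4), labels = labels[keep])
}

# nearest-neighbour sample of img at (real) coordinates; out-of-range -> fill
sampleImage <- function(img, ys, xs, fill) {
  H <- dim(img)[1]; W <- dim(img)[2]
  yi <- round(ys); xi <- round(xs)
  ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
  out <- array(0, c(length(ys), 3))
  for (c_ in 1:3) {
    v <- rep(fill[c_], length(ys))
    v[ok] <- img[cbind(yi[ok], xi[ok], c_)]
    out[, c_] <- v
  }
  out
}

#' Apply augmentations to an annotated scene
#'
#' Effects are applied in a fixed order: rotation, crop, translation,
#' mirror, brightness, noise, occlusion. Box coordinates are transformed
#' consistently (rotation takes the axis-aligned hull of the rotated
#' corners); pixel values are clipped to [0, 1].
#'
#' @param ann [AnnotatedImage-class].
#' @param spec [augmentationSpec()].
#' @return augmented [AnnotatedImage-class]; an empty annotation is a valid
#'   outcome (e.g. after an aggressive crop).
#' @export
augmentScene <- function(ann, spec = augmentationSpec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  img <- ann@image; boxes <- ann@boxes; labels <- ann@labels
  H <- dim(img)[1]; W <- dim(img)[2]
  fill <- apply(img, 3, mean)
  yg <- as.vector(matrix(seq_len(H), H, W))
  xg <- as.vector(matrix(seq_len(W), H, W, byrow = TRUE))

  if (spec$rotationDegrees > 0) {
    th <- stats::runif(1, -spec$rotationDegrees, spec$rotationDegrees) * pi / 180
    cx <- (W + 1) / 2; cy <- (H + 1) / 2
    # inverse map: output pixel -> input pixel (rotate by -th)
    xs <- cos(-th) * (xg - cx) - sin(-th) * (yg - cy) + cx
    ys <- sin(-th) * (xg - cx) + cos(-th) * (yg - cy) + cy
    sm <- sampleImage(img, ys, xs, fill)
    img <- array(sm, c(H, W, 3))
    if (nrow(boxes)) {
      nb <- t(apply(boxes, 1, function(b) {
        px <- c(b[1], b[3], b[1], b[3]) - cx + 0.5
        py <- c(b[2], b[2], b[4], b[4]) - cy + 0.5
        rx <- cos(th) * px - sin(th) * py + cx - 0.5
        ry <- sin(th) * px + cos(th) * py + cy - 0.5
        c(min(rx), min(ry), max(rx), max(ry))
      }))
      cl <- clipBoxes(nb, labels, W, H)
      boxes <- cl$boxes; labels <- cl$labels
    }
  }

  if (spec$cropFraction > 0) {
    fx <- stats::runif(1, 0, spec$cropFraction)
    fy <- stats::runif(1, 0, spec$cropFraction)
    cw <- max(2, round(W * (1 - fx))); chh <- max(2, round(H * (1 - fy)))
    x0 <- sample.int(W - cw + 1, 1) - 1    # 0-based crop origin
    y0 <- sample.int(H - chh + 1, 1) - 1
    # crop then resize back to W x H (nearest)
    xs <- x0 + (xg - 0.5) * cw / W + 0.5
    ys <- y0 + (yg - 0.5) * chh / H + 0.5
    sm <- sampleImage(img, ys, xs, fill)
    img <- array(sm, c(H, W, 3))
    if (nrow(boxes)) {
      nb <- cbind((boxes[, 1] - x0) * W / cw, (boxes[, 2] - y0) * H / chh,
                  (boxes[, 3] - x0) * W / cw, (boxes[, 4] - y0) * H / chh)
      cl <- clipBoxes(nb, labels, W, H)
      boxes <- cl$boxes; labels <- cl$labels
    }
  }

  if (spec$translateFraction > 0) {
    dx <- round(stats::runif(1, -1, 1) * spec$translateFraction * W)
    dy <- round(stats::runif(1, -1, 1) * spec$translateFraction * H)
    sm <- sampleImage(img, yg - dy, xg - dx, fill)
    img <- array(sm, c(H, W, 3))
    if (nrow(boxes)) {
      nb <- cbind(boxes[, 1] + dx, boxes[, 2] + dy,
                  boxes[, 3] + dx, boxes[, 4] + dy)
      cl <- clipBoxes(nb, labels, W, H)
      boxes <- cl$boxes; labels <- cl$labels
    }
  }

  if (spec$mirrorProb > 0 && stats::runif(1) < spec$mirrorProb) {
    img <- img[, W:1, , drop = FALSE]
    if (nrow(boxes))
      boxes <- cbind(W - boxes[, 3], boxes[, 2], W - boxes[, 1], boxes[, 4])
  }

  if (any(spec$brightnessRange != 1)) {
    f <- stats::runif(1, spec$brightnessRange[1], spec$brightnessRange[2])
    img <- pmin(pmax(img * f, 0), 1)
  }

  if (spec$gaussianNoiseSd > 0) {
    img <- pmin(pmax(img + array(stats::rnorm(length(img),
                                              sd = spec$gaussianNoiseSd),
                                 dim(img)), 0), 1)
  }
  if (spec$saltPepperFrac > 0) {
    npix <- H * W
    hit <- sample.int(npix, round(spec$saltPepperFrac * npix))
    val <- sample(c(0, 1), length(hit), replace = TRUE)
    for (c_ in 1:3) {
      ch <- img[, , c_]
      ch[hit] <- val
      img[, , c_] <- ch
    }
  }

  if (spec$occlusionCount > 0) {
    for (i in seq_len(spec$occlusionCount)) {
      sz <- round(stats::runif(1, spec$occlusionSize[1], spec$occlusionSize[2]) *
                    min(H, W))
      x0 <- sample.int(max(W - sz, 1), 1)
      y0 <- sample.int(max(H - sz, 1), 1)
      col <- c(stats::runif(1, 0.05, 0.2), stats::runif(1, 0.2, 0.4),
               stats::runif(1, 0.05, 0.15))
      for (c_ in 1:3)
        img[y0:min(y0 + sz, H), x0:min(x0 + sz, W), c_] <- col[c_]
    }
  }

  annotatedImage(img, boxes, labels)
}
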