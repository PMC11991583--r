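# Synthetic wheat-canopy scene generator. Emulates the salient structure of
# field images for offline testing: cluttered green background, several
# elongated textured spikes per image in three visually distinct growth
# stages, with exact bounding boxes.

#' Synthetic scene configuration
#'
#' @param imageSize `(H, W)` in pixels.
#' @param spikesRange inclusive range for the number of spikes per scene.
#' @param spikeLength range of spike major-axis length, pixels.
#' @param clutter background clutter level in [0, 1] (streak density and
#'   texture amplitude).
#' @param classAppearance per-class appearance: base RGB colour, texture
#'   amplitude and elongation (width/length) range. The defaults step from
#'   green-yellow (flowering) through yellow (filling) to gold (ripe).
#' @return configuration list.
#' @export
syntheticSceneConfig <- function(imageSize = c(320L, 320L),
                                 spikesRange = c(4L, 9L),
                                 spikeLength = c(34, 60),
                                 clutter = 0.5,
                                 classAppearance = list(
    flowerwheat  = list(rgb = c(0.47, 0.55, 0.22), texAmp = 0.10,
                        elong = c(0.24, 0.32)),
    fillingwheat = list(rgb = c(0.66, 0.62, 0.28), texAmp = 0.14,
                        elong = c(0.26, 0.34)),
    ripewheat    = list(rgb = c(0.80, 0.66, 0.33), texAmp = 0.18,
                        elong = c(0.28, 0.36)))) {
  stopifnot(length(imageSize) == 2, spikesRange[1] >= 0,
            spikesRange[2] >= spikesRange[1], clutter >= 0, clutter <= 1)
  list(imageSize = as.integer(imageSize), spikesRange = as.integer(spikesRange),
       spikeLength = spikeLength, clutter = clutter,
       classAppearance = classAppearance)
}

#' Generate one synthetic wheat scene
#'
#' Renders a cluttered green canopy background (low-frequency colour fields,
#' grass-like streaks, pixel grain) and a sampled number of spikes, each an
#' elongated textured ellipse with awn-like strokes at its tip and a
#' class-dependent hue. Spike centres are rejection-sampled away from each
#' other but a requested count is always honoured. The recorded boxes are
#' the exact extents of the painted pixels.
#'
#' @param cfg [syntheticSceneConfig()].
#' @param seed integer; the scene is a deterministic function of
#'   `(cfg, seed)`.
#' @return [AnnotatedImage-class].
#' @export
generateSyntheticScene <- function(cfg = syntheticSceneConfig(), seed = 1L) {
  set.seed(seed)
  H <- cfg$imageSize[1]; W <- cfg$imageSize[2]
  cl <- cfg$clutter
  yg <- matrix(seq_len(H), H, W)
  xg <- matrix(seq_len(W), H, W, byrow = TRUE)
  base <- c(0.16, 0.33, 0.11)
  img <- array(0, c(H, W, 3))
  # low-frequency colour fields
  nf <- 3
  field <- matrix(0, H, W)
  for (i in seq_len(nf)) {
    fx <- stats::runif(1, 1, 3) * 2 * pi / W
    fy <- stats::runif(1, 1, 3) * 2 * pi / H
    ph <- stats::runif(2, 0, 2 * pi)
    field <- field + sin(xg * fx + ph[1]) * sin(yg * fy + ph[2]) / nf
  }
  for (c_ in 1:3)
    img[, , c_] <- base[c_] * (1 + 0.25 * cl * field)
  # grass-like streaks
  nStreak <- round(24 * cl)
  for (i in seq_len(nStreak)) {
    x0 <- stats::runif(1, 1, W); y0 <- stats::runif(1, 1, H)
    th <- stats::runif(1, -0.5, 0.5) + pi / 2   # mostly vertical
    len <- stats::runif(1, 0.15, 0.5) * H
    wd <- stats::runif(1, 0.8, 2.0)
    u <- (xg - x0) * cos(th) + (yg - y0) * sin(th)
    v <- -(xg - x0) * sin(th) + (yg - y0) * cos(th)
    mask <- abs(v) < wd & u > 0 & u < len
    shade <- stats::runif(1, -0.35, 0.25)
    for (c_ in 1:3) {
      ch <- img[, , c_]
      ch[mask] <- pmin(pmax(ch[mask] * (1 + shade), 0), 1)
      img[, , c_] <- ch
    }
  }
  # pixel grain
  img <- img + array(stats::rnorm(H * W * 3, sd = 0.015 * (0.5 + cl)), c(H, W, 3))
  img <- pmin(pmax(img, 0), 1)

  k <- if (cfg$spikesRange[2] > cfg$spikesRange[1])
    sample(cfg$spikesRange[1]:cfg$spikesRange[2], 1) else cfg$spikesRange[1]
  classes <- wheatClasses()
  boxes <- matrix(0, 0, 4); labels <- character(0)
  centers <- matrix(0, 0, 2)
  margin <- min(max(cfg$spikeLength) * 0.75, min(H, W) / 2 - 2)
  for (i in seq_len(k)) {
    cls <- sample(classes, 1)
    ap <- cfg$classAppearance[[cls]]
    L <- stats::runif(1, cfg$spikeLength[1], cfg$spikeLength[2])
    Wd <- L * stats::runif(1, ap$elong[1], ap$elong[2])
    ok <- FALSE
    for (att in 1:40) {
      cx <- stats::runif(1, margin, W - margin)
      cy <- stats::runif(1, margin, H - margin)
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)) > 0.8 * L) {
        ok <- TRUE; break
      }
    }
    # placement always succeeds: after the attempt budget the last draw is used
    centers <- rbind(centers, c(cx, cy))
    th <- stats::rnorm(1, 0, 0.45) + pi / 2   # near-vertical spikes
    a <- L / 2; b <- Wd / 2
    u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
    v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
    mask <- (u / a)^2 + (v / b)^2 <= 1
    # spikelet banding along the axis plus cross-axis shading
    tex <- 1 + ap$texAmp * cos(u * (2 * pi / (L / stats::runif(1, 5, 8))))^2 -
      0.35 * (abs(v) / b)^2
    jit <- stats::rnorm(3, 0, 0.03)
    for (c_ in 1:3) {
      ch <- img[, , c_]
      val <- pmin(pmax((ap$rgb[c_] + jit[c_]) * tex[mask], 0), 1)
      ch[mask] <- val
      img[, , c_] <- ch
    }
    # awn strokes from the spike tip
    awnPix <- NULL
    nAwn <- sample(3:6, 1)
    tipx <- cx + a * cos(th); tipy <- cy + a * sin(th)
    for (j in seq_len(nAwn)) {
      phi <- th + stats::rnorm(1, 0, 0.25)
      len <- stats::runif(1, 0.15, 0.35) * L
      tt <- seq(0, len, by = 0.7)
      px <- round(tipx + tt * cos(phi)); py <- round(tipy + tt * sin(phi))
      keep <- px >= 1 & px <= W & py >= 1 & py <= H
      if (any(keep)) awnPix <- rbind(awnPix, cbind(py[keep], px[keep]))
    }
    if (!is.null(awnPix)) {
      for (c_ in 1:3)
        img[cbind(awnPix, c_)] <- pmin(ap$rgb[c_] * 1.15, 1)
    }
    # exact box over painted pixels (ellipse plus awns)
    ys <- yg[mask]; xs <- xg[mask]
    if (!is.null(awnPix)) { ys <- c(ys, awnPix[, 1]); xs <- c(xs, awnPix[, 2]) }
    boxes <- rbind(boxes, c(min(xs) - 1, min(ys) - 1, max(xs), max(ys)))
    labels <- c(labels, cls)
  }
  annotatedImage(img, boxes, labels)
}

#' Generate a synthetic dataset (optionally on disk in VOC layout)
#'
#' @param cfg [syntheticSceneConfig()].
#' @param n number of scenes.
#' @param dir optional output directory; when given, writes
#'   `images/scene_####.png`, `annotations/scene_####.xml`, a `manifest.csv`
#'   and a `classes.txt`.
#' @param seed integer; scene `i` uses seed `seed + i`.
#' @return list of [AnnotatedImage-class] (invisibly when writing to disk).
#' @export
generateSyntheticDataset <- function(cfg = syntheticSceneConfig(), n = 10,
                                     dir = NULL, seed = 1L) {
  scenes <- lapply(seq_len(n), function(i) generateSyntheticScene(cfg, seed + i))
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "annotations"), recursive = TRUE, showWarnings = FALSE)
    rows <- NULL
    for (i in seq_len(n)) {
      id <- sprintf("scene_%04d", i)
      ip <- file.path(dir, "images", paste0(id, ".png"))
      xp <- file.path(dir, "annotations", paste0(id, ".xml"))
      writeVOC(scenes[[i]], xp, ip)
      rows <- rbind(rows, data.frame(id = id, image = ip, xml = xp,
                                     objects = nrow(scenes[[i]]@boxes)))
    }
    utils::write.csv(rows, file.path(dir, "manifest.csv"), row.names = FALSE)
    writeLines(wheatClasses(), file.path(dir, "classes.txt"))
    return(invisible(scenes))
  }
  scenes
}
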