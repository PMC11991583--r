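# Slice grids, sliced prediction with coordinate remapping and merging,
# region counting.

test_that("slice grid follows the stated construction rule", {
  g1 <- computeSlices(256, 256)
  expect_equal(nrow(g1@windows), 1)
  expect_equal(as.numeric(g1@windows[1, ]), c(0, 0, 256, 256))
  # 1000 x 1000: step 230, starts {0, 230, 460, 690, 744} per axis
  g2 <- computeSlices(1000, 1000)
  expect_equal(sort(unique(g2@windows[, "x0"])), c(0, 230, 460, 690, 744))
  expect_equal(nrow(g2@windows), 25)
  # small images get a single window of the image size
  g3 <- computeSlices(100, 40)
  expect_equal(as.numeric(g3@windows[1, ]), c(0, 0, 100, 40))
})

test_that("slice grids cover every pixel with sufficient overlap", {
  set.seed(17)
  for (i in 1:500) {
    W <- sample(1:1500, 1); H <- sample(1:1500, 1)
    g <- computeSlices(W, H)
    xs <- sort(unique(g@windows[, "x0"]))
    xe <- xs + vapply(xs, function(s) max(g@windows[g@windows[, "x0"] == s, "w"]), numeric(1))
    expect_equal(xs[1], 0)
    expect_gte(min(xe[length(xe)]), W)
    if (length(xs) > 1) {
      # consecutive windows overlap by at least floor(S * r)
      expect_true(all(xe[-length(xe)] - xs[-1] >= floor(256 * 0.1)))
    }
    ys <- sort(unique(g@windows[, "y0"]))
    expect_true(max(ys) + max(g@windows[, "h"]) >= H)
  }
})

test_that("sliced prediction remaps exactly and merges duplicates", {
  # oracle detector: returns the ground truth clipped to its window
  gtBoxes <- rbind(c(100, 100, 140, 130), c(600, 610, 660, 650))
  gtCls <- c("ripewheat", "fillingwheat")
  stub <- function(crop) {
    wn <- attr(crop, "window")
    out <- NULL
    for (i in seq_len(nrow(gtBoxes))) {
      b <- gtBoxes[i, ]
      cb <- c(max(b[1], wn["x0"]), max(b[2], wn["y0"]),
              min(b[3], wn["x0"] + wn["w"]), min(b[4], wn["y0"] + wn["h"]))
      if (cb[3] > cb[1] && cb[4] > cb[2])
        out <- rbind(out, data.frame(class = gtCls[i], score = 0.9,
                                     x1 = cb[1] - wn["x0"], y1 = cb[2] - wn["y0"],
                                     x2 = cb[3] - wn["x0"], y2 = cb[4] - wn["y0"],
                                     stringsAsFactors = FALSE))
    }
    if (is.null(out)) LGWheatNet:::emptyDetections() else out
  }
  img <- array(0, c(800, 800, 3))
  d <- slicePredict(img, stub, computeSlices(800, 800))
  # both objects recovered exactly once at their source coordinates
  expect_equal(nrow(d), 2)
  for (i in 1:2) {
    row <- d[d$class == gtCls[i], ]
    expect_equal(as.numeric(row[1, c("x1", "y1", "x2", "y2")]), gtBoxes[i, ],
                 tolerance = 1e-12)
  }
  # empty scene
  none <- function(crop) LGWheatNet:::emptyDetections()
  expect_equal(nrow(slicePredict(img, none)), 0)
})

test_that("stub-detector recovery on a large synthetic scene is near total", {
  set.seed(71)
  W <- 2000; H <- 2000
  n <- 120
  x1 <- runif(n, 0, W - 40); y1 <- runif(n, 0, H - 40)
  boxes <- cbind(x1, y1, x1 + runif(n, 12, 36), y1 + runif(n, 12, 36))
  cls <- sample(wheatClasses(), n, replace = TRUE)
  stub <- function(crop) {
    wn <- attr(crop, "window")
    sel <- boxes[, 1] < wn["x0"] + wn["w"] & boxes[, 3] > wn["x0"] &
           boxes[, 2] < wn["y0"] + wn["h"] & boxes[, 4] > wn["y0"]
    if (!any(sel)) return(LGWheatNet:::emptyDetections())
    b <- boxes[sel, , drop = FALSE]
    cb <- cbind(pmax(b[, 1], wn["x0"]), pmax(b[, 2], wn["y0"]),
                pmin(b[, 3], wn["x0"] + wn["w"]), pmin(b[, 4], wn["y0"] + wn["h"]))
    data.frame(class = cls[sel], score = 0.9,
               x1 = cb[, 1] - wn["x0"], y1 = cb[, 2] - wn["y0"],
               x2 = cb[, 3] - wn["x0"], y2 = cb[, 4] - wn["y0"],
               stringsAsFactors = FALSE)
  }
  img <- array(0, c(H, W, 3))
  grid <- computeSlices(W, H, 256L, 0.1)
  d <- slicePredict(img, stub, grid)
  gt <- data.frame(class = cls, x1 = boxes[, 1], y1 = boxes[, 2],
                   x2 = boxes[, 3], y2 = boxes[, 4], stringsAsFactors = FALSE)
  # objects whose full box fits inside at least one window
  fits <- vapply(seq_len(n), function(i) {
    any(boxes[i, 1] >= grid@windows[, "x0"] &
        boxes[i, 3] <= grid@windows[, "x0"] + grid@windows[, "w"] &
        boxes[i, 2] >= grid@windows[, "y0"] &
        boxes[i, 4] <= grid@windows[, "y0"] + grid@windows[, "h"])
  }, logical(1))
  m <- matchDetections(d, gt[fits, ], 0.9)
  recovered <- sum(m$dets$tp)
  expect_gte(recovered / sum(fits), 0.99)
  # no duplicates: at most one detection matches each truth at high IoU
  expect_lte(nrow(d), n + round(0.01 * n))
})

test_that("region counting uses the half-open centre rule", {
  d <- data.frame(class = "ripewheat", score = 0.9,
                  x1 = c(10, 90), y1 = c(10, 40), x2 = c(30, 110), y2 = c(30, 60))
  regions <- rbind(c(0, 0, 50, 100), c(50, 0, 150, 100))
  rc <- countRegions(d, regions)
  expect_equal(rc$counts, c(1, 1))
  expect_equal(rc$total, 2)
  # whole image region counts every detection
  rc2 <- countRegions(d, imageSize = c(100, 150))
  expect_equal(rc2$counts, 2)
  # a centre exactly on the shared boundary belongs to the right-hand region
  d3 <- data.frame(class = "ripewheat", score = 0.9,
                   x1 = 40, y1 = 10, x2 = 60, y2 = 30)  # centre x = 50
  rc3 <- countRegions(d3, regions)
  expect_equal(rc3$counts, c(0, 1))
})
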