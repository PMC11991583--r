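# VOC reading/writing, dataset splitting, augmentation, synthetic scenes.

test_that("VOC files round-trip and follow the 1-based inclusive dialect", {
  td <- withr::local_tempdir()
  # hand-written XML: bndbox (10, 20, 110, 220) -> internal (9, 19, 110, 220)
  xml <- c("<annotation><filename>f.png</filename>",
           "<size><width>640</width><height>480</height><depth>3</depth></size>",
           "<object><name>ripewheat</name><bndbox>",
           "<xmin>10</xmin><ymin>20</ymin><xmax>110</xmax><ymax>220</ymax>",
           "</bndbox></object></annotation>")
  fp <- file.path(td, "hand.xml")
  writeLines(xml, fp)
  ann <- readVOC(fp)
  expect_equal(as.numeric(ann@boxes[1, ]), c(9, 19, 110, 220))
  expect_equal(ann@labels, "ripewheat")
  # zero objects
  writeLines(c("<annotation><filename>z.png</filename>",
               "<size><width>64</width><height>64</height><depth>3</depth></size>",
               "</annotation>"), file.path(td, "empty.xml"))
  expect_equal(nrow(readVOC(file.path(td, "empty.xml"))@boxes), 0)
  # unknown class rejected
  writeLines(gsub("ripewheat", "barley", xml), file.path(td, "bad.xml"))
  expect_error(readVOC(file.path(td, "bad.xml")), "unknown class")
  # write/read round trip over random synthetic scenes
  for (s in 1:3) {
    sc <- generateSyntheticScene(tinySceneConfig(), seed = s)
    xp <- file.path(td, sprintf("rt%d.xml", s))
    ip <- file.path(td, sprintf("rt%d.png", s))
    writeVOC(sc, xp, ip)
    rt <- readVOC(xp, ip)
    expect_equal(rt@boxes, round(sc@boxes), ignore_attr = TRUE)
    expect_identical(rt@labels, sc@labels)
    expect_equal(dim(rt@image), dim(sc@image))
  }
})

test_that("dataset split apportions 8:1:1 deterministically", {
  s10 <- splitDataset(1:10, seed = 1)
  expect_equal(lengths(s10), c(train = 8, val = 1, test = 1))
  s100 <- splitDataset(1:100, seed = 1)
  expect_equal(lengths(s100), c(train = 80, val = 10, test = 10))
  expect_setequal(unlist(s100), 1:100)       # disjoint and exhaustive
  expect_identical(splitDataset(1:100, seed = 7), splitDataset(1:100, seed = 7))
  expect_false(identical(splitDataset(1:100, seed = 7),
                         splitDataset(1:100, seed = 8)))
  expect_error(splitDataset(1:2), "at least 3")
})

test_that("augmentation identities and the mirror arithmetic hold", {
  sc <- generateSyntheticScene(tinySceneConfig(), seed = 9)
  idSpec <- augmentationSpec()       # everything off
  out <- augmentScene(sc, idSpec)
  expect_equal(out@image, sc@image)
  expect_equal(out@boxes, sc@boxes, ignore_attr = TRUE)
  # horizontal mirror of (10, 20, 110, 220) in a 640-wide image
  img <- array(0.5, c(480, 640, 3))
  ann <- annotatedImage(img, matrix(c(10, 20, 110, 220), 1), "ripewheat")
  mir <- augmentScene(ann, augmentationSpec(mirrorProb = 1, seed = 1))
  expect_equal(as.numeric(mir@boxes[1, ]), c(530, 20, 630, 220))
  # mirroring twice restores the original boxes
  mir2 <- augmentScene(mir, augmentationSpec(mirrorProb = 1, seed = 1))
  expect_equal(mir2@boxes, ann@boxes, ignore_attr = TRUE)
  expect_equal(mir2@image, ann@image)
})

test_that("augmentation keeps pixels and boxes in bounds", {
  set.seed(21)
  spec <- augmentationSpec(gaussianNoiseSd = 0.05, saltPepperFrac = 0.01,
                           brightnessRange = c(0.6, 1.5), occlusionCount = 2,
                           rotationDegrees = 25, cropFraction = 0.2,
                           translateFraction = 0.15, mirrorProb = 0.5)
  for (s in 1:6) {
    sc <- generateSyntheticScene(tinySceneConfig(), seed = s)
    out <- augmentScene(sc, spec)
    d <- dim(out@image)
    expect_true(all(out@image >= 0 & out@image <= 1))
    if (nrow(out@boxes)) {
      expect_true(all(out@boxes[, 1] >= 0 & out@boxes[, 2] >= 0))
      expect_true(all(out@boxes[, 3] <= d[2] & out@boxes[, 4] <= d[1]))
      expect_true(all(out@boxes[, 3] > out@boxes[, 1]))
    }
  }
})

test_that("synthetic scenes are deterministic with exact counts in range", {
  cfg <- tinySceneConfig()
  a <- generateSyntheticScene(cfg, seed = 123)
  b <- generateSyntheticScene(cfg, seed = 123)
  expect_identical(a@image, b@image)
  expect_identical(a@boxes, b@boxes)
  # requested zero spikes -> valid empty annotation
  z <- generateSyntheticScene(syntheticSceneConfig(imageSize = c(64, 64),
                                                   spikesRange = c(0, 0)),
                              seed = 1)
  expect_equal(nrow(z@boxes), 0)
  # spike counts follow the configured range exactly, boxes inside the image
  for (s in 1:100) {
    sc <- generateSyntheticScene(cfg, seed = s)
    k <- nrow(sc@boxes)
    expect_gte(k, cfg$spikesRange[1]); expect_lte(k, cfg$spikesRange[2])
    expect_true(all(sc@boxes[, 1] >= 0 & sc@boxes[, 2] >= 0 &
                    sc@boxes[, 3] <= dim(sc@image)[2] &
                    sc@boxes[, 4] <= dim(sc@image)[1]))
  }
})

test_that("a generated dataset validates and re-reads losslessly", {
  td <- withr::local_tempdir()
  scenes <- generateSyntheticDataset(tinySceneConfig(), 4, dir = td, seed = 2)
  man <- read.csv(file.path(td, "manifest.csv"))
  expect_equal(nrow(man), 4)
  for (i in 1:4) {
    rt <- readVOC(man$xml[i], man$image[i])
    expect_equal(rt@boxes, round(scenes[[i]]@boxes), ignore_attr = TRUE)
    expect_identical(rt@labels, scenes[[i]]@labels)
  }
})
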