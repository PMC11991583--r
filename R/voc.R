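# PASCAL VOC XML annotation input/output. On disk, bndbox coordinates are
# 1-based inclusive (xmin, ymin, xmax, ymax); internally boxes are 0-based
# half-open, so xmin maps to xmin - 1 and xmax stays (width = xmax - xmin + 1
# pixels either way).

#' Read a VOC annotation (and optionally its image)
#'
#' @param xmlPath path to the VOC `.xml` file.
#' @param imagePath optional image path (PNG); when `NULL`, the `filename`
#'   element resolved against the XML directory is tried, and a zero image of
#'   the annotated size is used if no file exists.
#' @param classes allowed class vocabulary; any other name is an error.
#' @return [AnnotatedImage-class].
#' @examples
#' ann <- readVOC(system.file("extdata", "example_annotation.xml",
#'                            package = "LGWheatNet"))
#' gtBoxes(ann)
#' @export
readVOC <- function(xmlPath, imagePath = NULL, classes = wheatClasses()) {
  doc <- xml2::read_xml(xmlPath)
  W <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
  H <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- matrix(0, 0, 4); labels <- character(0)
  for (ob in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(ob, "./name"))
    if (!nm %in% classes) stop("unknown class name in VOC file: ", nm)
    bb <- function(tag) as.numeric(xml2::xml_text(
      xml2::xml_find_first(ob, paste0("./bndbox/", tag))))
    b <- c(bb("xmin") - 1, bb("ymin") - 1, bb("xmax"), bb("ymax"))
    bc <- c(max(b[1], 0), max(b[2], 0), min(b[3], W), min(b[4], H))
    if (any(bc != b))
      warning("box outside image in ", xmlPath, "; clipped")
    boxes <- rbind(boxes, bc)
    labels <- c(labels, nm)
  }
  if (is.null(imagePath)) {
    fn <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
    cand <- file.path(dirname(xmlPath), fn)
    imagePath <- if (!is.na(fn) && file.exists(cand)) cand else NA
  }
  img <- if (!is.na(imagePath) && file.exists(imagePath)) {
    a <- png::readPNG(imagePath)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  } else array(0, c(H, W, 3))
  annotatedImage(img, boxes, labels)
}

#' Write a VOC annotation (and its image)
#'
#' Inverse of [readVOC()]: internal 0-based half-open boxes become 1-based
#' inclusive `bndbox` entries; field order is fixed so output is
#' deterministic.
#'
#' @param ann [AnnotatedImage-class].
#' @param xmlPath output `.xml` path.
#' @param imagePath optional output PNG path; written when given.
#' @return `xmlPath`, invisibly.
#' @export
writeVOC <- function(ann, xmlPath, imagePath = NULL) {
  d <- dim(ann@image)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", dirname(xmlPath))
  xml2::xml_add_child(doc, "filename",
                      if (is.null(imagePath)) "" else basename(imagePath))
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(d[2]))
  xml2::xml_add_child(sz, "height", as.character(d[1]))
  xml2::xml_add_child(sz, "depth", "3")
  for (i in seq_len(nrow(ann@boxes))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", ann@labels[i])
    xml2::xml_add_child(ob, "pose", "Unspecified")
    xml2::xml_add_child(ob, "truncated", "0")
    xml2::xml_add_child(ob, "difficult", "0")
    bb <- xml2::xml_add_child(ob, "bndbox")
    b <- ann@boxes[i, ]
    xml2::xml_add_child(bb, "xmin", as.character(round(b[1] + 1)))
    xml2::xml_add_child(bb, "ymin", as.character(round(b[2] + 1)))
    xml2::xml_add_child(bb, "xmax", as.character(round(b[3])))
    xml2::xml_add_child(bb, "ymax", as.character(round(b[4])))
  }
  xml2::write_xml(doc, xmlPath)
  if (!is.null(imagePath))
    png::writePNG(ann@image, imagePath)
  invisible(xmlPath)
}

#' Split items into train/validation/test sets
#'
#' Deterministic shuffled split with largest-remainder apportionment of the
#' ratio vector, so the three parts are disjoint, exhaustive, and their
#' sizes are the fairest integer division of `length(items)`.
#'
#' @param items vector or list to split.
#' @param ratios positive weights, default `c(8, 1, 1)`.
#' @param seed integer seed controlling the shuffle.
#' @return named list `train`, `val`, `test`.
#' @export
splitDataset <- function(items, ratios = c(8, 1, 1), seed = 0L) {
  n <- length(items)
  if (n < 3) stop("need at least 3 items to split")
  q <- n * ratios / sum(ratios)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  set.seed(seed)
  perm <- sample.int(n)
  list(train = items[perm[seq_len(base[1])]],
       val = items[perm[base[1] + seq_len(base[2])]],
       test = items[perm[base[1] + base[2] + seq_len(base[3])]])
}
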