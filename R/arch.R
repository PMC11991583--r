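# Architecture definition: block configurations, the width configuration
# (stage table), and the graph builder that assembles backbone, neck and head.

#' Ablation variant flags
#'
#' Three switches select which of the bespoke modules replace their plain
#' counterparts: SeCUIB (vs plain inverted bottleneck without attention or
#' shuffle), DWDown (vs plain stride-2 3x3 convolution in the neck), and
#' LightDetect (vs the standard decoupled detection head with full 3x3
#' convolutions). All three `TRUE` is the full detector; all `FALSE` is the
#' ablation baseline.
#'
#' @param secuib,dwdown,lightdetect logical switches.
#' @return named list of the three flags.
#' @export
variantFlags <- function(secuib = TRUE, dwdown = TRUE, lightdetect = TRUE) {
  stopifnot(is.logical(secuib), is.logical(dwdown), is.logical(lightdetect))
  list(secuib = secuib, dwdown = dwdown, lightdetect = lightdetect)
}

#' Detection head configuration
#'
#' @param numClasses number of object classes (default 3 growth stages).
#' @param regMax number of distribution-focal-loss bins per box side; the
#'   regression branch emits `4 * regMax` channels per level.
#' @param groups group count for the LightDetect group convolution.
#' @return named list.
#' @export
headConfig <- function(numClasses = 3L, regMax = 16L, groups = 4L) {
  list(numClasses = as.integer(numClasses), regMax = as.integer(regMax),
       groups = as.integer(groups))
}

#' Network width configuration (stage table)
#'
#' Declares every channel width and expansion size in the detector: the stem,
#' the four backbone stages (each one stride-2 block plus `blocks` stride-1
#' blocks), the SPPF terminator, the FPN+PAN neck and both head variants.
#' The defaults are the reference widths of the package; altering them changes
#' parameter and FLOP counts.
#'
#' @param stem stem convolution output channels.
#' @param stages list of four stage records: `out` (channels), `blocks`
#'   (stride-1 block count), `expandDown` / `expand` (expanded channels of the
#'   stride-2 and stride-1 blocks).
#' @param neck named widths of the top-down (`td4`, `td3`) and bottom-up
#'   (`bu4`, `bu5`) fusion blocks, the two downsampler outputs (`down1`,
#'   `down2`) and the four neck expansion sizes.
#' @param head widths of the two head variants: `regWidth`/`clsWidth`
#'   (standard decoupled head) and `lightRegWidth`/`lightClsWidth`
#'   (LightDetect branches).
#' @param downKernel,midKernel depthwise kernel sizes of the stride-2 and
#'   stride-1 block stages.
#' @param sppfPool SPPF pooling kernel.
#' @param shuffleGroups channel-shuffle group count; every expanded width must
#'   be divisible by it.
#' @param seRatio squeeze-excitation reduction ratio.
#' @return nested named list.
#' @export
widthConfig <- function(
    stem = 32L,
    stages = list(
      list(out = 24L,  blocks = 0L, expandDown = 64L,  expand = 72L),
      list(out = 48L,  blocks = 2L, expandDown = 120L, expand = 232L),
      list(out = 96L,  blocks = 2L, expandDown = 224L, expand = 456L),
      list(out = 144L, blocks = 3L, expandDown = 504L, expand = 688L)),
    neck = list(td4 = 84L, td3 = 48L, bu4 = 84L, bu5 = 128L,
                down1 = 54L, down2 = 58L,
                expandTd4 = 376L, expandTd3 = 216L,
                expandBu4 = 240L, expandBu5 = 528L),
    head = list(regWidth = 70L, clsWidth = 49L,
                lightRegWidth = 72L, lightClsWidth = 48L),
    downKernel = 3L, midKernel = 3L, sppfPool = 5L,
    shuffleGroups = 2L, seRatio = 0.25) {
  wc <- list(stem = stem, stages = stages, neck = neck, head = head,
             downKernel = downKernel, midKernel = midKernel,
             sppfPool = sppfPool, shuffleGroups = shuffleGroups,
             seRatio = seRatio)
  for (st in stages)
    if (st$expand %% shuffleGroups != 0 || st$expandDown %% shuffleGroups != 0)
      stop("expanded widths must be divisible by shuffleGroups")
  wc
}

#' SeCUIB block configuration
#'
#' Inverted bottleneck with optional initial and mid depthwise stages,
#' channel shuffle and squeeze-excitation. A depthwise kernel of 0 disables
#' that stage; the stride is carried by the mid depthwise convolution when
#' present, otherwise by the initial one.
#'
#' @param inChannels,outChannels channel counts.
#' @param expandRatio expansion ratio; expanded channels =
#'   `round(inChannels * expandRatio)` and must divide by `shuffleGroups`.
#' @param startKernel,midKernel depthwise kernel sizes (0 disables).
#' @param stride 1 or 2.
#' @param shuffleGroups channel shuffle groups.
#' @param seRatio squeeze-excitation reduction ratio in (0, 1].
#' @return validated configuration list.
#' @export
secuibConfig <- function(inChannels, outChannels, expandRatio = 2,
                         startKernel = 0L, midKernel = 3L, stride = 1L,
                         shuffleGroups = 2L, seRatio = 0.25) {
  expanded <- as.integer(round(inChannels * expandRatio))
  if (expanded %% shuffleGroups != 0)
    stop("expanded channel count ", expanded,
         " not divisible by shuffle groups ", shuffleGroups)
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  if (stride == 2L && startKernel == 0L && midKernel == 0L)
    stop("stride 2 requires at least one depthwise stage")
  if (seRatio <= 0 || seRatio > 1) stop("seRatio must lie in (0, 1]")
  list(inChannels = as.integer(inChannels), outChannels = as.integer(outChannels),
       expanded = expanded, startKernel = as.integer(startKernel),
       midKernel = as.integer(midKernel), stride = as.integer(stride),
       shuffleGroups = as.integer(shuffleGroups), seRatio = seRatio)
}

#' DWDown block configuration
#'
#' Pointwise channel adjustment, stride-2 depthwise feature extraction, batch
#' normalization.
#'
#' @param inChannels,outChannels channel counts.
#' @param dwKernel depthwise kernel size.
#' @return validated configuration list.
#' @export
dwdownConfig <- function(inChannels, outChannels, dwKernel = 3L) {
  stopifnot(outChannels >= 1)
  list(inChannels = as.integer(inChannels), outChannels = as.integer(outChannels),
       dwKernel = as.integer(dwKernel), stride = 2L)
}

#' SPPF block configuration
#'
#' @param inChannels,outChannels channel counts; hidden width is
#'   `inChannels %/% 2` and must be at least 1.
#' @param poolKernel max-pooling kernel (stride 1, applied three times).
#' @return validated configuration list.
#' @export
sppfConfig <- function(inChannels, outChannels, poolKernel = 5L) {
  if (inChannels %/% 2 < 1) stop("inChannels too small for SPPF")
  list(inChannels = as.integer(inChannels), outChannels = as.integer(outChannels),
       poolKernel = as.integer(poolKernel))
}

# ---- graph assembly -------------------------------------------------------

newGraph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$inputs <- list()
  g
}

addNode <- function(g, node, inputs = integer(0)) {
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- node
  g$inputs[[id]] <- as.integer(inputs)
  id
}

# Append an inverted-bottleneck block (UIB or SeCUIB) to the graph.
addUIB <- function(g, from, cfg, secuib) {
  act <- if (secuib) "silu" else "relu"
  cur <- from
  i <- cfg$inChannels; e <- cfg$expanded; o <- cfg$outChannels
  if (cfg$startKernel > 0) {
    s0 <- if (cfg$midKernel > 0) 1L else cfg$stride
    cur <- addNode(g, nodeConv(cfg$startKernel, i, i, stride = s0, groups = i,
                               bn = TRUE, act = "none", name = "uib.startdw"), cur)
  }
  cur <- addNode(g, nodeConv(1L, i, e, bn = TRUE, act = act, name = "uib.expand"), cur)
  if (cfg$midKernel > 0) {
    cur <- addNode(g, nodeConv(cfg$midKernel, e, e, stride = cfg$stride, groups = e,
                               bn = TRUE, act = act, name = "uib.middw"), cur)
    if (secuib)
      cur <- addNode(g, nodeSimple("shuffle", groups = cfg$shuffleGroups), cur)
  }
  cur <- addNode(g, nodeConv(1L, e, o, bn = TRUE, act = "none", name = "uib.project"), cur)
  if (secuib)
    cur <- addNode(g, nodeSE(o, cfg$seRatio), cur)
  if (cfg$stride == 1L && i == o)
    cur <- addNode(g, nodeSimple("add"), c(cur, from))
  cur
}

addSPPF <- function(g, from, cfg) {
  h <- cfg$inChannels %/% 2L
  cv1 <- addNode(g, nodeConv(1L, cfg$inChannels, h, bn = TRUE, act = "silu",
                             name = "sppf.cv1"), from)
  p1 <- addNode(g, nodeSimple("maxpool", k = cfg$poolKernel), cv1)
  p2 <- addNode(g, nodeSimple("maxpool", k = cfg$poolKernel), p1)
  p3 <- addNode(g, nodeSimple("maxpool", k = cfg$poolKernel), p2)
  cat4 <- addNode(g, nodeSimple("concat"), c(cv1, p1, p2, p3))
  addNode(g, nodeConv(1L, 4L * h, cfg$outChannels, bn = TRUE, act = "silu",
                      name = "sppf.cv2"), cat4)
}

addDown <- function(g, from, inC, outC, dwdown, act) {
  if (dwdown) {
    pw <- addNode(g, nodeConv(1L, inC, outC, bn = FALSE, act = "none",
                              name = "dwdown.pw"), from)
    addNode(g, nodeConv(3L, outC, outC, stride = 2L, groups = outC,
                        bn = TRUE, act = "none", name = "dwdown.dw"), pw)
  } else {
    addNode(g, nodeConv(3L, inC, outC, stride = 2L, bn = TRUE, act = act,
                        name = "convdown"), from)
  }
}

addHeadBranch <- function(g, from, inC, width, outC, light, groups, act = "silu") {
  if (light) {
    c1 <- addNode(g, nodeConv(3L, inC, width, groups = groups, bn = TRUE,
                              act = act, name = "head.group"), from)
    c2 <- addNode(g, nodeConv(3L, width, width, groups = width, bn = TRUE,
                              act = act, name = "head.dw"), c1)
    c3 <- addNode(g, nodeConv(1L, width, width, bn = TRUE, act = act,
                              name = "head.pw"), c2)
    addNode(g, nodeConv(1L, width, outC, bias = TRUE, bn = FALSE, act = "none",
                        name = "head.out"), c3)
  } else {
    c1 <- addNode(g, nodeConv(3L, inC, width, bn = TRUE, act = act,
                              name = "head.conv1"), from)
    c2 <- addNode(g, nodeConv(3L, width, width, bn = TRUE, act = act,
                              name = "head.conv2"), c1)
    addNode(g, nodeConv(1L, width, outC, bias = TRUE, bn = FALSE, act = "none",
                        name = "head.out"), c2)
  }
}

# Build the full node graph. Returns list(graph, outputs) where outputs is a
# named integer vector of node ids: reg3, cls3, reg4, cls4, reg5, cls5.
buildGraph <- function(flags, wc, hc) {
  g <- newGraph()
  sec <- flags$secuib
  act <- if (sec) "silu" else "relu"
  inp <- addNode(g, nodeSimple("identity", name = "input"))
  g$nodes[[inp]]$isInput <- TRUE
  cur <- addNode(g, nodeConv(3L, 3L, wc$stem, stride = 2L, bn = TRUE, act = act,
                             name = "stem"), inp)
  g$nodes[[cur]]$isInput <- TRUE  # no dx needed below the stem
  cin <- wc$stem
  taps <- integer(4)
  for (si in seq_along(wc$stages)) {
    st <- wc$stages[[si]]
    cfg <- secuibConfig(cin, st$out, st$expandDown / cin,
                        startKernel = wc$downKernel, midKernel = wc$midKernel,
                        stride = 2L, shuffleGroups = wc$shuffleGroups,
                        seRatio = wc$seRatio)
    cur <- addUIB(g, cur, cfg, sec)
    cin <- st$out
    if (st$blocks > 0) for (b in seq_len(st$blocks)) {
      cfg <- secuibConfig(cin, cin, st$expand / cin, startKernel = 0L,
                          midKernel = wc$midKernel, stride = 1L,
                          shuffleGroups = wc$shuffleGroups, seRatio = wc$seRatio)
      cur <- addUIB(g, cur, cfg, sec)
    }
    taps[si] <- cur
  }
  c3 <- wc$stages[[2]]$out; c4 <- wc$stages[[3]]$out; c5 <- wc$stages[[4]]$out
  p5 <- addSPPF(g, taps[4], sppfConfig(c5, c5, wc$sppfPool))
  nk <- wc$neck
  # top-down
  up1 <- addNode(g, nodeSimple("upsample"), p5)
  cat1 <- addNode(g, nodeSimple("concat"), c(up1, taps[3]))
  td4 <- addUIB(g, cat1, secuibConfig(c5 + c4, nk$td4, nk$expandTd4 / (c5 + c4),
                                      0L, wc$midKernel, 1L, wc$shuffleGroups,
                                      wc$seRatio), sec)
  up2 <- addNode(g, nodeSimple("upsample"), td4)
  cat2 <- addNode(g, nodeSimple("concat"), c(up2, taps[2]))
  td3 <- addUIB(g, cat2, secuibConfig(nk$td4 + c3, nk$td3,
                                      nk$expandTd3 / (nk$td4 + c3),
                                      0L, wc$midKernel, 1L, wc$shuffleGroups,
                                      wc$seRatio), sec)
  # bottom-up
  d1 <- addDown(g, td3, nk$td3, nk$down1, flags$dwdown, act)
  cat3 <- addNode(g, nodeSimple("concat"), c(d1, td4))
  bu4 <- addUIB(g, cat3, secuibConfig(nk$down1 + nk$td4, nk$bu4,
                                      nk$expandBu4 / (nk$down1 + nk$td4),
                                      0L, wc$midKernel, 1L, wc$shuffleGroups,
                                      wc$seRatio), sec)
  d2 <- addDown(g, bu4, nk$bu4, nk$down2, flags$dwdown, act)
  cat5 <- addNode(g, nodeSimple("concat"), c(d2, p5))
  bu5 <- addUIB(g, cat5, secuibConfig(nk$down2 + c5, nk$bu5,
                                      nk$expandBu5 / (nk$down2 + c5),
                                      0L, wc$midKernel, 1L, wc$shuffleGroups,
                                      wc$seRatio), sec)
  # heads on P3/P4/P5
  light <- flags$lightdetect
  hw <- wc$head
  regW <- if (light) hw$lightRegWidth else hw$regWidth
  clsW <- if (light) hw$lightClsWidth else hw$clsWidth
  regOut <- 4L * hc$regMax
  lvlIn <- c(nk$td3, nk$bu4, nk$bu5)
  lvlFrom <- c(td3, bu4, bu5)
  outs <- integer(0)
  for (li in 1:3) {
    r <- addHeadBranch(g, lvlFrom[li], lvlIn[li], regW, regOut, light, hc$groups)
    cl <- addHeadBranch(g, lvlFrom[li], lvlIn[li], clsW, hc$numClasses, light,
                        hc$groups)
    outs <- c(outs, r, cl)
  }
  names(outs) <- c("reg3", "cls3", "reg4", "cls4", "reg5", "cls5")
  list(graph = g, outputs = outs, input = inp)
}
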