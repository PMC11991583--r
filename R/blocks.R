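# Standalone block modules: a SeCUIB/UIB, DWDown or SPPF block wrapped in a
# minimal graph so it can be run, counted and inspected outside the full
# network. The full detector assembles the same node constructors.

blockModule <- function(build) {
  g <- newGraph()
  inp <- addNode(g, nodeSimple("identity", name = "input"))
  g$nodes[[inp]]$isInput <- TRUE
  out <- build(g, inp)
  structure(list(graph = g, input = inp, output = out), class = "WheatBlock")
}

#' Standalone block constructors
#'
#' Build a single SeCUIB (or plain UIB), DWDown or SPPF block as a runnable
#' module. Use [blockForward()] to apply it to a feature map and
#' [countParameters()] to count its trainable parameters.
#'
#' @param cfg the matching configuration ([secuibConfig()],
#'   [dwdownConfig()] or [sppfConfig()]).
#' @param secuib for `secuibModule`: `TRUE` builds the full SeCUIB
#'   (squeeze-excitation, channel shuffle, SiLU), `FALSE` the plain inverted
#'   bottleneck with ReLU.
#' @param init `"kaiming"` (random) or `"zero"` (all convolution and gate
#'   weights zero, identity-statistics batch norm) initialisation.
#' @param seed optional seed for random initialisation.
#' @return a `WheatBlock` module.
#' @export
secuibModule <- function(cfg, secuib = TRUE, init = c("kaiming", "zero"),
                         seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  m <- blockModule(function(g, inp) addUIB(g, inp, cfg, secuib))
  if (init == "zero") zeroBlockWeights(m)
  m
}

#' @rdname secuibModule
#' @export
dwdownModule <- function(cfg, init = c("kaiming", "zero"), seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  m <- blockModule(function(g, inp) {
    pw <- addNode(g, nodeConv(1L, cfg$inChannels, cfg$outChannels, bn = FALSE,
                              act = "none", name = "dwdown.pw"), inp)
    addNode(g, nodeConv(cfg$dwKernel, cfg$outChannels, cfg$outChannels,
                        stride = 2L, groups = cfg$outChannels, bn = TRUE,
                        act = "none", name = "dwdown.dw"), pw)
  })
  if (init == "zero") zeroBlockWeights(m)
  m
}

#' @rdname secuibModule
#' @export
sppfModule <- function(cfg, init = c("kaiming", "zero"), seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  m <- blockModule(function(g, inp) addSPPF(g, inp, cfg))
  if (init == "zero") zeroBlockWeights(m)
  m
}

zeroBlockWeights <- function(m) {
  for (nd in m$graph$nodes)
    for (pn in nodeParamNames(nd))
      if (pn != "gamma") nd[[pn]][] <- 0
  invisible(m)
}

#' Run a standalone block
#'
#' @param module a `WheatBlock` from [secuibModule()], [dwdownModule()] or
#'   [sppfModule()].
#' @param x feature map array `[N, C, H, W]`.
#' @param training use batch statistics in batch norm.
#' @return output feature map array.
#' @export
blockForward <- function(module, x, training = FALSE) {
  g <- module$graph
  xh <- ft_from_r(x)
  outs <- vector("list", length(g$nodes))
  for (id in seq_along(g$nodes)) {
    ins <- g$inputs[[id]]
    xs <- if (length(ins)) outs[ins] else list(xh)
    outs[[id]] <- nodeForward(g$nodes[[id]], xs, training)
  }
  ft_to_r(outs[[module$output]])
}
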