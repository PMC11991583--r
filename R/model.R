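#' @import methods
NULL

#' Wheat spike detector model
#'
#' S4 wrapper around the layer graph of the detector. Build with
#' [buildWheatNet()]; run with [wheatnetForward()] or [detectImage()].
#'
#' @slot graph environment holding the ordered node list and their inputs.
#' @slot flags ablation variant flags, see [variantFlags()].
#' @slot widthCfg width configuration, see [widthConfig()].
#' @slot headCfg head configuration, see [headConfig()].
#' @slot outputs named integer vector of output node ids.
#' @slot strides integer strides of the three pyramid levels.
#' @export
setClass("WheatNet",
         representation(graph = "environment", flags = "list",
                        widthCfg = "list", headCfg = "list",
                        outputs = "integer", strides = "integer"))

#' Build a detector variant
#'
#' Assembles backbone (stride-2 stem, four inverted-bottleneck stages, SPPF),
#' FPN+PAN neck and detection head according to the variant flags, and
#' initializes all weights (Kaiming convolutions, identity batch norm).
#'
#' @param flags [variantFlags()] selecting SeCUIB / DWDown / LightDetect.
#' @param widthCfg [widthConfig()] channel plan.
#' @param headCfg [headConfig()].
#' @param seed optional integer; when given, weight initialization is seeded.
#' @return a [WheatNet-class] object.
#' @export
buildWheatNet <- function(flags = variantFlags(), widthCfg = widthConfig(),
                          headCfg = headConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- buildGraph(flags, widthCfg, headCfg)
  initHeadBiases(b, headCfg)
  methods::new("WheatNet", graph = b$graph, flags = flags, widthCfg = widthCfg,
               headCfg = headCfg, outputs = b$outputs,
               strides = c(8L, 16L, 32L))
}

# Detection-prior initialization: class logits start near a small positive
# rate, box-distribution logits near 1, so early training is stable.
initHeadBiases <- function(b, hc) {
  for (nm in names(b$outputs)) {
    nd <- b$graph$nodes[[b$outputs[[nm]]]]
    if (startsWith(nm, "cls")) nd$b[] <- -4 else nd$b[] <- 1
  }
}

setMethod("show", "WheatNet", function(object) {
  fl <- object@flags
  cat("WheatNet detector\n")
  cat(sprintf("  variant: SeCUIB=%s DWDown=%s LightDetect=%s\n",
              fl$secuib, fl$dwdown, fl$lightdetect))
  cat(sprintf("  parameters: %s\n",
              format(countParameters(object), big.mark = ",")))
  cat(sprintf("  GFLOPs @640: %.1f\n", countFlops(object, c(640L, 640L))))
  cat(sprintf("  pyramid strides: %s\n", paste(object@strides, collapse = "/")))
})

#' Count trainable parameters
#'
#' Sums the lengths of every trainable array in the model: convolution
#' weights and biases, batch-norm scale/shift, squeeze-excitation gates.
#' Running batch-norm statistics are not trainable and are excluded.
#'
#' @param model a [WheatNet-class].
#' @return integer scalar.
#' @export
countParameters <- function(model) {
  g <- if (isS4(model)) model@graph else model$graph
  tot <- 0
  for (nd in g$nodes)
    for (pn in nodeParamNames(nd)) tot <- tot + length(nd[[pn]])
  as.integer(tot)
}

#' Count forward FLOPs
#'
#' Counts 2 x multiply-accumulates over all convolution and linear layers for
#' one image at the given input size, in GFLOPs. Elementwise and pooling
#' operations are not counted, following the usual detector convention.
#'
#' @param model a [WheatNet-class].
#' @param inputSize integer `(H, W)`, each divisible by 32.
#' @return numeric GFLOPs.
#' @export
countFlops <- function(model, inputSize = c(640L, 640L)) {
  if (any(inputSize %% 32 != 0)) stop("input size must be divisible by 32")
  g <- model@graph
  shapes <- vector("list", length(g$nodes))
  macs <- 0
  for (id in seq_along(g$nodes)) {
    nd <- g$nodes[[id]]
    ins <- g$inputs[[id]]
    sh <- if (length(ins)) shapes[[ins[1]]] else c(3L, inputSize)
    shapes[[id]] <- switch(nd$type,
      conv = {
        ho <- ceiling(sh[2] / nd$stride); wo <- ceiling(sh[3] / nd$stride)
        macs <- macs + ho * wo * nd$k^2 * (nd$cin / nd$groups) * nd$cout
        c(nd$cout, ho, wo)
      },
      se = { macs <- macs + 2 * nd$cin * nd$r; sh },
      upsample = c(sh[1], sh[2] * 2L, sh[3] * 2L),
      concat = c(sum(vapply(ins, function(i) shapes[[i]][1], numeric(1))),
                 sh[2], sh[3]),
      sh)
  }
  2 * macs / 1e9
}

#' Forward pass
#'
#' Runs the graph on a batch and returns the raw per-level head outputs.
#' In training mode batch-norm uses batch statistics and every node caches
#' what its backward pass needs.
#'
#' @param model a [WheatNet-class].
#' @param x input array `[N, 3, H, W]` with `H`, `W` divisible by 32.
#' @param training logical.
#' @return list with elements `reg3`, `cls3`, `reg4`, `cls4`, `reg5`, `cls5`
#'   (raw logits, `[N, C, H_l, W_l]`).
#' @export
wheatnetForward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 4 || d[2] != 3) stop("input must be [N, 3, H, W]")
  if (any(d[3:4] %% 32 != 0)) stop("H and W must be divisible by 32")
  g <- model@graph
  xh <- ft_from_r(x)
  outs <- vector("list", length(g$nodes))
  consumers <- nodeConsumerCount(g, model@outputs)
  for (id in seq_along(g$nodes)) {
    ins <- g$inputs[[id]]
    xs <- if (length(ins)) outs[ins] else list(xh)
    outs[[id]] <- nodeForward(g$nodes[[id]], xs, training)
    if (!training) {
      for (i in ins) {
        consumers[i] <- consumers[i] - 1L
        if (consumers[i] == 0L && !(i %in% model@outputs)) outs[[i]] <- NA
      }
    }
  }
  if (training) g$outs <- outs
  stats::setNames(lapply(outs[model@outputs], ft_to_r), names(model@outputs))
}

nodeConsumerCount <- function(g, outputs) {
  cc <- integer(length(g$nodes))
  for (id in seq_along(g$nodes)) for (i in g$inputs[[id]]) cc[i] <- cc[i] + 1L
  cc[outputs] <- cc[outputs] + 1L
  cc
}

# Backward pass from head gradients. grads: named list matching model@outputs.
# Accumulates parameter gradients inside the nodes.
wheatnetBackward <- function(model, grads) {
  g <- model@graph
  n <- length(g$nodes)
  gacc <- vector("list", n)
  for (nm in names(model@outputs)) {
    id <- model@outputs[[nm]]
    gacc[[id]] <- ft_from_r(grads[[nm]])
  }
  for (id in rev(seq_len(n))) {
    if (is.null(gacc[[id]])) next
    din <- nodeBackward(g$nodes[[id]], gacc[[id]])
    gacc[[id]] <- NULL
    ins <- g$inputs[[id]]
    for (j in seq_along(ins)) {
      if (is.null(din[[j]])) next
      i <- ins[j]
      gacc[[i]] <- if (is.null(gacc[[i]])) din[[j]] else ft_add(gacc[[i]], din[[j]])
    }
  }
  g$outs <- NULL
  invisible(NULL)
}

zeroGradients <- function(model) {
  for (nd in model@graph$nodes)
    for (pn in nodeParamNames(nd)) nd[[nodeGradName(pn)]] <- NULL
  invisible(NULL)
}

clearCaches <- function(model) {
  for (nd in model@graph$nodes) clearNodeCaches(nd)
  model@graph$outs <- NULL
  invisible(NULL)
}

#' Save / load model weights
#'
#' Weights (including batch-norm running statistics) are stored as a plain
#' named list in RDS format.
#'
#' @param model a [WheatNet-class].
#' @param path file path.
#' @return `loadWeights` returns the model, invisibly, with weights replaced.
#' @export
saveWeights <- function(model, path) {
  state <- list()
  for (id in seq_along(model@graph$nodes)) {
    nd <- model@graph$nodes[[id]]
    pns <- c(nodeParamNames(nd), if (isTRUE(nd$useBN)) c("rmean", "rvar"))
    for (pn in pns) state[[paste0("n", id, ".", pn)]] <- nd[[pn]]
  }
  saveRDS(state, path)
  invisible(path)
}

#' @rdname saveWeights
#' @export
loadWeights <- function(model, path) {
  state <- readRDS(path)
  for (id in seq_along(model@graph$nodes)) {
    nd <- model@graph$nodes[[id]]
    pns <- c(nodeParamNames(nd), if (isTRUE(nd$useBN)) c("rmean", "rvar"))
    for (pn in pns) {
      key <- paste0("n", id, ".", pn)
      if (is.null(state[[key]])) stop("missing weight ", key, " in ", path)
      if (length(state[[key]]) != length(nd[[pn]]))
        stop("shape mismatch for ", key)
      nd[[pn]] <- state[[key]]
    }
  }
  invisible(model)
}

#' Save / load an architecture description as YAML
#'
#' Serialises the variant flags, width configuration and head configuration
#' so a model with the same structure can be rebuilt (weights are stored
#' separately, see [saveWeights()]).
#'
#' @param model a [WheatNet-class].
#' @param path YAML file path.
#' @return `loadArchitecture` returns a freshly built [WheatNet-class].
#' @export
saveArchitecture <- function(model, path) {
  yaml::write_yaml(list(flags = model@flags, widthCfg = model@widthCfg,
                        headCfg = model@headCfg), path)
  invisible(path)
}

#' @rdname saveArchitecture
#' @param seed optional seed for the rebuilt model's initialisation.
#' @export
loadArchitecture <- function(path, seed = NULL) {
  a <- yaml::read_yaml(path)
  wc <- a$widthCfg
  wc$stages <- lapply(wc$stages, function(st) lapply(st, as.integer))
  buildWheatNet(do.call(variantFlags, a$flags), do.call(widthConfig, wc),
                do.call(headConfig, a$headCfg), seed = seed)
}
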