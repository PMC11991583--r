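# SGD training loop with warmup and linear learning-rate decay, parameter
# grouping (weight decay on convolution/linear weights only, a separate
# warmup schedule for biases), per-epoch validation and best-checkpoint
# retention.

#' Training configuration
#'
#' Defaults are the reference recipe: 300 epochs, initial learning rate
#' 0.01 decaying linearly to `lr0 * lrf`, momentum 0.937, weight decay
#' 5e-4, a 3-epoch warmup starting from momentum 0.8 and bias learning rate
#' 0.1.
#'
#' @param epochs total epochs.
#' @param lr0 initial learning rate.
#' @param lrf final learning rate as a fraction of `lr0`.
#' @param momentum SGD momentum after warmup.
#' @param weightDecay L2 decay on convolution/linear weights.
#' @param warmupEpochs warmup length in epochs.
#' @param warmupMomentum momentum at the start of warmup.
#' @param warmupBiasLr bias-group learning rate at the start of warmup.
#' @param batchSize images per step.
#' @param imgSize training resolution (square, multiple of 32).
#' @param seed integer seed for shuffling.
#' @return configuration list.
#' @export
trainConfig <- function(epochs = 300L, lr0 = 0.01, lrf = 0.01,
                        momentum = 0.937, weightDecay = 5e-4,
                        warmupEpochs = 3L, warmupMomentum = 0.8,
                        warmupBiasLr = 0.1, batchSize = 16L,
                        imgSize = 640L, seed = 0L) {
  stopifnot(epochs >= 1, lr0 > 0, lrf > 0, lrf <= 1, momentum > 0,
            weightDecay >= 0, batchSize >= 1, imgSize %% 32 == 0)
  list(epochs = as.integer(epochs), lr0 = lr0, lrf = lrf, momentum = momentum,
       weightDecay = weightDecay, warmupEpochs = warmupEpochs,
       warmupMomentum = warmupMomentum, warmupBiasLr = warmupBiasLr,
       batchSize = as.integer(batchSize), imgSize = as.integer(imgSize),
       seed = as.integer(seed))
}

#' Learning-rate and momentum schedule
#'
#' During the warmup iterations the weight-group learning rate ramps
#' linearly from 0 (bias group: from `warmupBiasLr`) to the scheduled value
#' and momentum from `warmupMomentum` to `momentum`; afterwards the rate
#' follows a linear decay from `lr0` at epoch 0 to `lr0 * lrf` at the final
#' epoch.
#'
#' @param epoch 0-based epoch index.
#' @param step 0-based step within the epoch.
#' @param stepsPerEpoch steps per epoch.
#' @param cfg [trainConfig()].
#' @return list `lrWeights`, `lrBias`, `momentum`.
#' @export
lrSchedule <- function(epoch, step, stepsPerEpoch, cfg) {
  lf <- if (cfg$epochs > 1)
    1 - (1 - cfg$lrf) * epoch / (cfg$epochs - 1) else cfg$lrf
  target <- cfg$lr0 * lf
  ni <- epoch * stepsPerEpoch + step
  nw <- cfg$warmupEpochs * stepsPerEpoch
  if (nw > 0 && ni <= nw) {
    xi <- ni / nw
    list(lrWeights = xi * target,
         lrBias = cfg$warmupBiasLr + xi * (target - cfg$warmupBiasLr),
         momentum = cfg$warmupMomentum + xi * (cfg$momentum - cfg$warmupMomentum))
  } else {
    list(lrWeights = target, lrBias = target, momentum = cfg$momentum)
  }
}

# parameter group of one node array: "weights" (decayed), "gamma", "bias"
paramGroup <- function(nd, pn) {
  if (pn %in% c("W", "W1", "W2")) "weights"
  else if (pn == "gamma") "gamma"
  else "bias"
}

sgdStep <- function(model, lrW, lrB, mom, decay) {
  for (nd in model@graph$nodes) {
    for (pn in nodeParamNames(nd)) {
      gn <- nodeGradName(pn)
      g <- nd[[gn]]
      if (is.null(g)) next
      grp <- paramGroup(nd, pn)
      if (grp == "weights" && decay > 0) g <- g + decay * nd[[pn]]
      bn <- paste0("mom_", pn)
      v <- nd[[bn]]
      v <- if (is.null(v)) g else mom * v + g
      nd[[bn]] <- v
      lr <- if (grp == "bias") lrB else lrW
      nd[[pn]] <- nd[[pn]] - lr * v
    }
  }
  invisible(NULL)
}

getModelState <- function(model) {
  st <- list()
  for (id in seq_along(model@graph$nodes)) {
    nd <- model@graph$nodes[[id]]
    for (pn in c(nodeParamNames(nd), if (isTRUE(nd$useBN)) c("rmean", "rvar")))
      st[[paste0("n", id, ".", pn)]] <- nd[[pn]]
  }
  st
}

setModelState <- function(model, st) {
  for (id in seq_along(model@graph$nodes)) {
    nd <- model@graph$nodes[[id]]
    for (pn in c(nodeParamNames(nd), if (isTRUE(nd$useBN)) c("rmean", "rvar")))
      nd[[pn]] <- st[[paste0("n", id, ".", pn)]]
  }
  invisible(model)
}

padTo32 <- function(image) {
  d <- dim(image)
  hp <- ceiling(d[1] / 32) * 32; wp <- ceiling(d[2] / 32) * 32
  if (hp == d[1] && wp == d[2]) return(image)
  out <- array(0, c(hp, wp, 3))
  out[seq_len(d[1]), seq_len(d[2]), ] <- image
  out
}

#' Train the detector
#'
#' Stochastic gradient descent with momentum and weight decay (no decay on
#' batch-norm scales or biases), warmup and linear decay per [lrSchedule()],
#' fully seeded. Validation mAP50 is computed every `valEvery` epochs (and
#' at the end) and the weights with the best validation mAP50 are restored
#' into the model before returning; without a validation set the final
#' weights are kept. A non-finite loss aborts with a diagnostic.
#'
#' @param model a [WheatNet-class] (modified in place).
#' @param trainScenes list of [AnnotatedImage-class].
#' @param valScenes optional validation list.
#' @param cfg [trainConfig()].
#' @param valEvery validate every this many epochs.
#' @param verbose print a line per epoch.
#' @return list with `history` (data.frame: epoch, loss and components,
#'   validation mAP50) and `bestMap50`.
#' @export
trainWheatNet <- function(model, trainScenes, valScenes = NULL,
                          cfg = trainConfig(), valEvery = 5L, verbose = TRUE) {
  stopifnot(length(trainScenes) >= 1)
  set.seed(cfg$seed)
  inputs <- lapply(trainScenes, function(s) imageToInput(padTo32(s@image)))
  targets <- lapply(trainScenes, annToTarget)
  n <- length(trainScenes)
  stepsPerEpoch <- ceiling(n / cfg$batchSize)
  history <- NULL
  bestMap <- -Inf; bestState <- NULL
  for (epoch in seq_len(cfg$epochs) - 1L) {
    ord <- sample.int(n)
    eLoss <- c(total = 0, box = 0, cls = 0, dfl = 0)
    for (step in seq_len(stepsPerEpoch) - 1L) {
      idx <- ord[(step * cfg$batchSize + 1):min((step + 1) * cfg$batchSize, n)]
      xb <- abind4(inputs[idx])
      raw <- wheatnetForward(model, xb, training = TRUE)
      ls <- detectionLoss(raw, targets[idx], model@headCfg, model@strides,
                          gradients = TRUE)
      if (!is.finite(ls$total))
        stop(sprintf("training diverged at epoch %d step %d (loss=%g)",
                     epoch, step, ls$total))
      zeroGradients(model)
      wheatnetBackward(model, ls$grads)
      sc <- lrSchedule(epoch, step, stepsPerEpoch, cfg)
      sgdStep(model, sc$lrWeights, sc$lrBias, sc$momentum, cfg$weightDecay)
      eLoss <- eLoss + c(ls$total, ls$box, ls$cls, ls$dfl)
    }
    eLoss <- eLoss / stepsPerEpoch
    valMap <- NA_real_
    if (!is.null(valScenes) &&
        (epoch %% valEvery == valEvery - 1L || epoch == cfg$epochs - 1L)) {
      ev <- evaluateWheatNet(model, valScenes)
      valMap <- ev$map50
      if (is.finite(valMap) && valMap >= bestMap) {
        bestMap <- valMap
        bestState <- getModelState(model)
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = eLoss[1],
                                         box = eLoss[2], cls = eLoss[3],
                                         dfl = eLoss[4], valMap50 = valMap))
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f (box %.3f cls %.3f dfl %.3f)%s\n",
                  epoch, eLoss[1], eLoss[2], eLoss[3], eLoss[4],
                  if (is.na(valMap)) "" else sprintf("  val mAP50 %.3f", valMap)))
  }
  if (!is.null(bestState)) setModelState(model, bestState)
  clearCaches(model)
  rownames(history) <- NULL
  list(history = history, bestMap50 = if (is.finite(bestMap)) bestMap else NA_real_)
}

# bind a list of [1,3,H,W] arrays into [N,3,H,W]
abind4 <- function(xs) {
  if (length(xs) == 1) return(xs[[1]])
  d <- dim(xs[[1]])
  out <- array(0, c(length(xs), d[2], d[3], d[4]))
  for (i in seq_along(xs)) out[i, , , ] <- xs[[i]][1, , , ]
  out
}

#' Evaluate the detector on a dataset
#'
#' Runs inference on every scene (low confidence threshold so the full
#' precision-recall sweep is available) and computes the detection metric
#' suite.
#'
#' @param model a [WheatNet-class].
#' @param scenes list of [AnnotatedImage-class].
#' @param confThreshold decoding threshold (low default for PR sweeps).
#' @param iouThreshold NMS threshold.
#' @param mode mAP threshold protocol, see [mapSuite()].
#' @return [mapSuite()] result with the per-image detections attached as
#'   `detections`.
#' @export
evaluateWheatNet <- function(model, scenes, confThreshold = 0.001,
                             iouThreshold = 0.5, mode = "standard10") {
  dets <- lapply(scenes, function(s)
    detectImage(model, s, confThreshold = confThreshold,
                iouThreshold = iouThreshold))
  out <- mapSuite(dets, scenes, mode = mode)
  out$detections <- dets
  out
}

#' Count spikes in an image
#'
#' The per-image count is the number of post-NMS detections above the
#' confidence threshold (default 0.25).
#'
#' @param model a [WheatNet-class].
#' @param image image array or [AnnotatedImage-class].
#' @param confThreshold confidence threshold.
#' @return named integer: total and per-class counts.
#' @export
countSpikes <- function(model, image, confThreshold = 0.25) {
  d <- detectImage(model, image, confThreshold = confThreshold)
  c(total = nrow(d), table(factor(d$class, levels = wheatClasses())))
}
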