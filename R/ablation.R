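#' Ablation table: parameters and GFLOPs per variant
#'
#' Builds all eight combinations of the three module flags with the same
#' width configuration and reports trainable parameter totals and forward
#' GFLOPs at the given input size, in the conventional ablation ordering
#' (baseline, single modules, pairs, full model).
#'
#' @param widthCfg [widthConfig()].
#' @param headCfg [headConfig()].
#' @param inputSize `(H, W)` for the FLOP count.
#' @return data.frame with columns `secuib`, `dwdown`, `lightdetect`,
#'   `parameters`, `gflops`.
#' @export
runAblation <- function(widthCfg = widthConfig(), headCfg = headConfig(),
                        inputSize = c(640L, 640L)) {
  combos <- list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                 c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
                 c(FALSE, TRUE, TRUE), c(TRUE, TRUE, FALSE),
                 c(TRUE, FALSE, TRUE), c(TRUE, TRUE, TRUE))
  rows <- lapply(combos, function(fl) {
    m <- buildWheatNet(variantFlags(fl[1], fl[2], fl[3]), widthCfg, headCfg)
    data.frame(secuib = fl[1], dwdown = fl[2], lightdetect = fl[3],
               parameters = countParameters(m),
               gflops = round(countFlops(m, inputSize), 1))
  })
  do.call(rbind, rows)
}
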