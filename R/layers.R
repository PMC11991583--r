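# Internal layer-node machinery. Each node is an environment holding its
# configuration, parameter arrays, gradient accumulators and forward caches.
# Nodes are assembled into a topologically ordered graph by the architecture
# builder; nodeForward/nodeBackward dispatch on node$type.
#
# Feature maps are arrays [N, C, H, W]. Per-channel vectors broadcast against
# them via rep(v, each = N) and R recycling (the first two dims are fastest).

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.03

kaimingConv <- function(k, cing, cout) {
  fan_in <- k * k * cing
  array(stats::rnorm(k * k * cing * cout, sd = sqrt(2 / fan_in)), c(k, k, cing, cout))
}

# Convolution node: conv (+ optional BN, optional activation).
# groups == cin == cout with k > 1 dispatches the depthwise kernel.
nodeConv <- function(k, cin, cout, stride = 1L, groups = 1L,
                     bias = FALSE, bn = TRUE, act = "silu", name = "conv") {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$name <- name
  e$k <- as.integer(k); e$cin <- as.integer(cin); e$cout <- as.integer(cout)
  e$stride <- as.integer(stride); e$groups <- as.integer(groups)
  e$useBias <- bias; e$useBN <- bn; e$act <- act
  e$W <- kaimingConv(k, cin %/% groups, cout)
  if (bias) e$b <- numeric(cout)
  if (bn) {
    e$gamma <- rep(1, cout); e$beta <- numeric(cout)
    e$rmean <- numeric(cout); e$rvar <- rep(1, cout)
  }
  e
}

isDepthwise <- function(nd) nd$groups == nd$cin && nd$cin == nd$cout && nd$k > 1L

actCode <- function(act) switch(act, none = 0L, silu = 1L, relu = 2L)

convForward <- function(nd, x, training) {
  nd$x_in <- if (training) x else NULL
  r <- ft_conv_block_fw(x, nd$W, if (nd$useBias) nd$b else NULL,
                     nd$stride, nd$groups, nd$useBN,
                     if (nd$useBN) nd$gamma, if (nd$useBN) nd$beta,
                     if (nd$useBN) nd$rmean, if (nd$useBN) nd$rvar,
                     training, actCode(nd$act), BN_EPS)
  if (training) {
    nd$z_conv <- r$z
    if (nd$useBN) {
      nd$bn_mu <- r$mean; nd$bn_var <- r$var
      d <- ft_dim(r$y)
      M <- d[1] * d[3] * d[4]
      ub <- if (M > 1) r$var * M / (M - 1) else r$var
      nd$rmean <- (1 - BN_MOMENTUM) * nd$rmean + BN_MOMENTUM * r$mean
      nd$rvar  <- (1 - BN_MOMENTUM) * nd$rvar  + BN_MOMENTUM * ub
    }
  }
  r$y
}

convBackward <- function(nd, dy, needDx = TRUE) {
  r <- ft_conv_block_bw(nd$x_in, nd$W, dy, nd$z_conv, nd$stride, nd$groups,
                     nd$useBN, if (nd$useBN) nd$gamma, if (nd$useBN) nd$beta,
                     if (nd$useBN) nd$bn_mu, if (nd$useBN) nd$bn_var,
                     actCode(nd$act), BN_EPS, needDx, nd$useBias)
  nd$gW <- (nd$gW %||% 0) + r$dw
  if (nd$useBias) nd$gb <- (nd$gb %||% 0) + r$db
  if (nd$useBN) {
    nd$ggamma <- (nd$ggamma %||% 0) + r$dgamma
    nd$gbeta <- (nd$gbeta %||% 0) + r$dbeta
  }
  if (needDx) r$dx else NULL
}

# Squeeze-excitation node.
nodeSE <- function(channels, ratio = 0.25, name = "se") {
  e <- new.env(parent = emptyenv())
  e$type <- "se"; e$name <- name
  e$cin <- as.integer(channels)
  e$r <- max(1L, as.integer(round(channels * ratio)))
  w <- seInit(channels, ratio)
  e$W1 <- w$W1; e$b1 <- w$b1; e$W2 <- w$W2; e$b2 <- w$b2
  e
}

seForward <- function(nd, x, training) {
  p <- ft_chan_mean(x)
  h <- sweep(p %*% nd$W1, 2, nd$b1, "+")
  a <- pmax(h, 0)
  zg <- sweep(a %*% nd$W2, 2, nd$b2, "+")
  g <- sigmoid(zg)
  if (training) { nd$x_in <- x; nd$p <- p; nd$h <- h; nd$a <- a; nd$g <- g }
  ft_scale_channels(x, g, NULL)
}

seBackward <- function(nd, dy) {
  d <- ft_dim(dy); HW <- d[3] * d[4]
  g <- nd$g
  dg <- ft_chan_dot(dy, nd$x_in) * g * (1 - g)
  nd$gW2 <- (nd$gW2 %||% 0) + crossprod(nd$a, dg)
  nd$gb2 <- (nd$gb2 %||% 0) + colSums(dg)
  da <- dg %*% t(nd$W2)
  dh <- da * (nd$h > 0)
  nd$gW1 <- (nd$gW1 %||% 0) + crossprod(nd$p, dh)
  nd$gb1 <- (nd$gb1 %||% 0) + colSums(dh)
  dp <- dh %*% t(nd$W1)
  ft_scale_channels(dy, g, dp / HW)
}

nodeSimple <- function(type, name = type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type; e$name <- name
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nodeForward <- function(nd, xs, training) {
  switch(nd$type,
    conv = convForward(nd, xs[[1]], training),
    se = seForward(nd, xs[[1]], training),
    add = ft_add(xs[[1]], xs[[2]]),
    shuffle = {
      nd$perm <- shufflePermutation(ft_dim(xs[[1]])[2], nd$groups)
      ft_perm_channels(xs[[1]], nd$perm)
    },
    upsample = ft_upsample2_fw(xs[[1]]),
    concat = {
      nd$splits <- vapply(xs, function(a) ft_dim(a)[2], integer(1))
      ft_concat(xs)
    },
    maxpool = {
      r <- ft_maxpool_fw(xs[[1]], nd$k)
      if (training) nd$arg <- r$arg
      r$y
    },
    identity = xs[[1]],
    stop("unknown node type ", nd$type)
  )
}

nodeBackward <- function(nd, dy) {
  switch(nd$type,
    conv = list(convBackward(nd, dy, needDx = !isTRUE(nd$isInput))),
    se = list(seBackward(nd, dy)),
    add = list(dy, dy),
    shuffle = list(ft_perm_channels(dy, order(nd$perm))),
    upsample = list(ft_upsample2_bw(dy)),
    concat = {
      out <- vector("list", length(nd$splits))
      at <- 0L
      for (i in seq_along(nd$splits)) {
        out[[i]] <- ft_slice_channels(dy, at + 1L, at + nd$splits[i])
        at <- at + nd$splits[i]
      }
      out
    },
    maxpool = list(ft_maxpool_bw(dy, nd$arg)),
    identity = list(dy),
    stop("unknown node type ", nd$type)
  )
}

# Trainable parameter array names per node type.
nodeParamNames <- function(nd) {
  switch(nd$type,
    conv = c("W", if (nd$useBias) "b", if (nd$useBN) c("gamma", "beta")),
    se = c("W1", "b1", "W2", "b2"),
    character(0)
  )
}

nodeGradName <- function(pn) paste0("g", pn)

clearNodeCaches <- function(nd) {
  for (f in c("x_in", "preact", "z_conv", "bn_mu", "bn_var", "p", "h", "a", "g", "arg"))
    if (!is.null(nd[[f]])) nd[[f]] <- NULL
  invisible(NULL)
}
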