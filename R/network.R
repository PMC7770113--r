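# Convolutional digit-in-noise classifier.
#
# Architecture: C1 (5x5) -> LRN -> maxpool -> C2 (3x3) -> LRN -> maxpool ->
# C3 -> C4 -> C5 (3x3) -> maxpool -> F1..F5 -> 10 log-probabilities, with
# ReLU after every convolutional and hidden fully connected layer. Channel
# depths dilate and constrict by a factor of two ([C, 2C, 4C, 2C, C]); the
# fully connected widths decrease geometrically to the 10 classes. Training
# uses log-softmax + negative log likelihood with Adam (learning rate and
# weight decay both 1e-3 by default). All parameters are initialized from a
# normal distribution. The engine is written in vectorized base R: im2col
# convolutions, local response normalization across channels, and 2x2
# max-pooling, each with exact hand-derived backward passes.

#' Network configuration
#'
#' @slot inputShape (nCF, nFrames) of the finalized neurograms.
#' @slot baseChannels Base convolutional channel count C.
#' @slot convKernels Kernel sizes of the five convolutional layers.
#' @slot nFcLayers Number of fully connected layers (5).
#' @slot nClasses Output classes (10 digits).
#' @slot lrnSize,lrnAlpha,lrnBeta,lrnK Local-response-normalization constants.
#' @slot poolSize Max-pool window/stride (2).
#' @slot batchSize Training batch size.
#' @slot learningRate,weightDecay Adam hyperparameters.
#' @slot initStd Standard deviation of the normal initializer.
#' @seealso [networkConfig()], [buildNetwork()]
#' @export
setClass("NetworkConfig", representation(
  inputShape = "integer", baseChannels = "integer", convKernels = "integer",
  nFcLayers = "integer", nClasses = "integer", lrnSize = "integer",
  lrnAlpha = "numeric", lrnBeta = "numeric", lrnK = "numeric",
  poolSize = "integer", batchSize = "integer", learningRate = "numeric",
  weightDecay = "numeric", initStd = "numeric"))

setValidity("NetworkConfig", function(object) {
  if (length(object@convKernels) != 5L) return("exactly 5 convolutional layers")
  if (any(object@convKernels %% 2L != 1L)) return("odd kernel sizes required")
  if (object@nFcLayers != 5L) return("5 fully connected layers required")
  if (object@nClasses != 10L) return("10 digit classes required")
  TRUE
})

#' Network state: parameters, architecture and optimizer moments
#'
#' Holds the 20 parameter tensors (weight + bias for C1-C5, F1-F5), the
#' layer-shape bookkeeping, Adam moments, and the training-step counter.
#'
#' @slot config A [NetworkConfig-class].
#' @slot arch Layer descriptor list (internal).
#' @slot params Named list of the 20 parameter tensors ("C1.weight", ...).
#' @slot adamM,adamV Adam first/second moments, same names as params.
#' @slot step Training-step counter.
#' @slot seed Initialization seed.
#' @export
setClass("NetworkState", representation(
  config = "NetworkConfig", arch = "list", params = "list",
  adamM = "list", adamV = "list", step = "integer", seed = "integer"))

setValidity("NetworkState", function(object) {
  if (length(object@params) != 20L) return("network must hold 20 parameter tensors")
  TRUE
})

#' Create a network configuration
#'
#' Defaults follow the architecture contract: five conv layers (first 5x5,
#' rest 3x3) with factor-2 channel dilation/constriction, LRN (size 5,
#' alpha 1e-4, beta 0.75, k 2) and 2x2 max-pooling after the first two conv
#' layers and after the fifth, five FC layers shrinking to 10 classes,
#' batch 256, Adam with learning rate and weight decay 1e-3, normal(0, 0.01)
#' initialization.
#'
#' @param inputShape (nCF, nFrames), e.g. c(128, 70) paper preset.
#' @param baseChannels Base channel count C (conv depths [C, 2C, 4C, 2C, C]).
#' @param batchSize,learningRate,weightDecay Training hyperparameters.
#' @param initStd Standard deviation of the normal initializer. The default
#'   NA scales each weight tensor by its fan-in (sd = sqrt(2 / fan_in),
#'   biases sd 0.01): a fixed tiny scale starves the ten-layer stack of
#'   signal and the network cannot learn in reasonable budgets.
#' @return A [NetworkConfig-class].
#' @export
networkConfig <- function(inputShape, baseChannels = 16L, batchSize = 256L,
                          learningRate = 1e-3, weightDecay = 1e-3,
                          initStd = NA_real_) {
  methods::new("NetworkConfig", inputShape = as.integer(inputShape),
               baseChannels = as.integer(baseChannels),
               convKernels = c(5L, 3L, 3L, 3L, 3L), nFcLayers = 5L,
               nClasses = 10L, lrnSize = 5L, lrnAlpha = 1e-4, lrnBeta = 0.75,
               lrnK = 2, poolSize = 2L, batchSize = as.integer(batchSize),
               learningRate = learningRate, weightDecay = weightDecay,
               initStd = initStd)
}

# Resolve the layer stack and all spatial shapes; stop with a layer-by-layer
# report if pooling exhausts a dimension.
resolveArchitecture <- function(config) {
  H <- config@inputShape[1]; W <- config@inputShape[2]
  C <- config@baseChannels
  depths <- C * c(1L, 2L, 4L, 2L, 1L)
  inCh <- c(1L, depths[-5])
  layers <- list(); report <- character()
  pushConv <- function(i) {
    layers[[length(layers) + 1L]] <<- list(
      name = paste0("C", i), type = "conv", k = config@convKernels[i],
      inCh = inCh[i], outCh = depths[i], H = H, W = W)
    report <<- c(report, sprintf("C%d: %dx%d kernel, %d -> %d ch, %dx%d",
      i, config@convKernels[i], config@convKernels[i], inCh[i], depths[i], H, W))
    layers[[length(layers) + 1L]] <<- list(name = paste0("C", i, ".relu"), type = "relu")
  }
  pushPool <- function() {
    H2 <- H %/% config@poolSize; W2 <- W %/% config@poolSize
    report <<- c(report, sprintf("maxpool: %dx%d -> %dx%d", H, W, H2, W2))
    if (H2 < 1L || W2 < 1L)
      stop("pooling leaves a non-positive spatial dimension:\n",
           paste(report, collapse = "\n"))
    H <<- H2; W <<- W2
    layers[[length(layers) + 1L]] <<- list(name = "pool", type = "pool")
  }
  pushConv(1L)
  layers[[length(layers) + 1L]] <- list(name = "lrn1", type = "lrn")
  pushPool()
  pushConv(2L)
  layers[[length(layers) + 1L]] <- list(name = "lrn2", type = "lrn")
  pushPool()
  pushConv(3L); pushConv(4L); pushConv(5L)
  pushPool()
  flat <- H * W * depths[5]
  widths <- round(exp(seq(log(flat), log(config@nClasses), length.out = 6L)))[-1]
  widths[5] <- config@nClasses
  for (i in 4:1) widths[i] <- max(widths[i], widths[i + 1] + 1L)
  if (flat <= widths[1])
    stop("flattened size ", flat, " too small for decreasing FC widths:\n",
         paste(report, collapse = "\n"))
  fcIn <- c(flat, widths[-5])
  for (i in 1:5) {
    layers[[length(layers) + 1L]] <- list(name = paste0("F", i), type = "fc",
                                          inN = fcIn[i], outN = widths[i])
    if (i < 5L)
      layers[[length(layers) + 1L]] <- list(name = paste0("F", i, ".relu"),
                                            type = "relu")
  }
  list(layers = layers, flat = flat, fcWidths = widths, convDepths = depths,
       report = report, idx = new.env(parent = emptyenv()))
}

#' Build and initialize a network
#'
#' All 20 parameter tensors are drawn from Normal(0, initStd); deterministic
#' given the seed. Incompatible shapes are rejected with a layer-by-layer
#' shape report.
#'
#' @param config A [NetworkConfig-class].
#' @param seed Initialization seed.
#' @return A [NetworkState-class].
#' @export
buildNetwork <- function(config, seed = 1L) {
  arch <- resolveArchitecture(config)
  params <- list()
  sdW <- function(fanIn) if (is.na(config@initStd)) sqrt(2 / fanIn) else config@initStd
  sdB <- if (is.na(config@initStd)) 0.01 else config@initStd
  withSeed(seed, {
    for (lay in arch$layers) {
      if (identical(lay$type, "conv")) {
        fanIn <- lay$k^2 * lay$inCh
        params[[paste0(lay$name, ".weight")]] <-
          matrix(stats::rnorm(lay$outCh * fanIn, 0, sdW(fanIn)), lay$outCh, fanIn)
        params[[paste0(lay$name, ".bias")]] <- stats::rnorm(lay$outCh, 0, sdB)
      } else if (identical(lay$type, "fc")) {
        params[[paste0(lay$name, ".weight")]] <-
          matrix(stats::rnorm(lay$outN * lay$inN, 0, sdW(lay$inN)), lay$outN, lay$inN)
        params[[paste0(lay$name, ".bias")]] <- stats::rnorm(lay$outN, 0, sdB)
      }
    }
  })
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  methods::new("NetworkState", config = config, arch = arch, params = params,
               adamM = zeros, adamV = zeros, step = 0L, seed = as.integer(seed))
}

#' Names of the 20 parameter tensors
#'
#' @param state A [NetworkState-class].
#' @return Character vector of tensor names.
#' @export
tensorNames <- function(state) names(state@params)

#' Trainable-tensor masks
#'
#' "all" selects every tensor (unconstrained adaptation); "f5" selects only
#' the final fully connected layer's weight and bias (constrained adaptation).
#'
#' @param state A [NetworkState-class].
#' @param type "all" or "f5", or a character vector of tensor names.
#' @return Character vector of trainable tensor names.
#' @export
tensorMask <- function(state, type = "all") {
  if (length(type) > 1L || !type %in% c("all", "f5")) {
    bad <- setdiff(type, tensorNames(state))
    if (length(bad)) stop("unknown tensors in mask: ", paste(bad, collapse = ", "))
    return(type)
  }
  if (type == "all") tensorNames(state) else c("F5.weight", "F5.bias")
}

## ---- layer primitives ------------------------------------------------------
#
# Internal activation layout is (H, W, N, C): flattening the first three
# dimensions gives the (H*W*N) x C matrices the im2col convolution and the
# channel-window LRN operate on without transposes.

# Cached linear-index gather matrix for im2col: rows index the (H, W, N)
# output positions, columns the (k, k, C) patch offsets, into the padded
# (H+2p, W+2p, N, C) array.
convIndex <- function(H, W, N, C, k, env) {
  key <- paste(H, W, N, C, k, sep = "x")
  got <- env[[key]]
  if (!is.null(got)) return(got)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  I0 <- outer(outer(seq_len(H), (seq_len(W) - 1L) * Hp, `+`),
              (seq_len(N) - 1L) * (Hp * Wp), `+`)
  off <- integer(k * k * C)
  for (cc in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k))
    off[(cc - 1L) * k * k + (dj - 1L) * k + di] <-
      (di - 1L) + (dj - 1L) * Hp + (cc - 1L) * (Hp * Wp * N)
  IDX <- outer(as.integer(I0), off, `+`)
  env[[key]] <- IDX
  IDX
}

convFwd <- function(A, Wm, b, k, idxEnv, needX = FALSE) {
  d <- dim(A); H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  p <- (k - 1L) %/% 2L
  if (p > 0L) {
    Apad <- array(0, c(H + 2L * p, W + 2L * p, N, Cin))
    Apad[p + seq_len(H), p + seq_len(W), , ] <- A
  } else Apad <- A
  IDX <- convIndex(H, W, N, Cin, k, idxEnv)
  X <- Apad[IDX]
  dim(X) <- dim(IDX)
  Z <- X %*% t(Wm)
  for (co in seq_len(ncol(Z))) Z[, co] <- Z[, co] + b[co]
  out <- array(Z, c(H, W, N, nrow(Wm)))
  list(out = out, X = if (needX) X else NULL, dims = d, k = k, p = p)
}

# Gradient w.r.t. the conv input: correlation of the output gradient with the
# spatially flipped kernel (stride-1, same padding), via the same gather.
convBwdData <- function(dZarr, Wm, Cin, k, idxEnv) {
  d <- dim(dZarr); H <- d[1]; W <- d[2]; N <- d[3]; Cout <- d[4]
  kk <- k * k
  Wk <- Wm; dim(Wk) <- c(Cout, kk, Cin)
  Wk <- Wk[, kk:1, , drop = FALSE]            # flip both spatial dims
  Wflip <- aperm(Wk, c(3, 2, 1)); dim(Wflip) <- c(Cin, kk * Cout)
  p <- (k - 1L) %/% 2L
  if (p > 0L) {
    Zpad <- array(0, c(H + 2L * p, W + 2L * p, N, Cout))
    Zpad[p + seq_len(H), p + seq_len(W), , ] <- dZarr
  } else Zpad <- dZarr
  IDX <- convIndex(H, W, N, Cout, k, idxEnv)
  Xb <- Zpad[IDX]
  dim(Xb) <- dim(IDX)
  array(Xb %*% t(Wflip), c(H, W, N, Cin))
}

convBwd <- function(dOut, cache, Wm, idxEnv, needDx = TRUE) {
  H <- cache$dims[1]; W <- cache$dims[2]; N <- cache$dims[3]; Cin <- cache$dims[4]
  Cout <- nrow(Wm)
  dZ <- dOut; dim(dZ) <- c(H * W * N, Cout)
  dW <- crossprod(dZ, cache$X)        # (Cout x kk*Cin)
  db <- colSums(dZ)
  if (!needDx) return(list(dA = NULL, dW = dW, db = db))
  dA <- convBwdData(dOut, Wm, Cin, cache$k, idxEnv)
  list(dA = dA, dW = dW, db = db)
}

# Banded channel-window matrix for local response normalization.
lrnBand <- function(C, size) {
  half <- size %/% 2L
  B <- matrix(0, C, C)
  for (i in seq_len(C)) B[max(1L, i - half):min(C, i + half), i] <- 1
  B
}

lrnFwd <- function(A, size, alpha, beta, kk) {
  d <- dim(A); C <- d[4]
  M <- A; dim(M) <- c(prod(d[1:3]), C)
  S <- (M * M) %*% lrnBand(C, size)
  z <- kk + (alpha / size) * S
  zb <- z^(-beta)
  y <- M * zb
  out <- y; dim(out) <- d
  list(out = out, M = M, z = z, zb = zb, y = y, d = d)
}

lrnBwd <- function(dOut, cache, size, alpha, beta) {
  d <- cache$d; C <- d[4]
  dY <- dOut; dim(dY) <- c(prod(d[1:3]), C)
  G <- dY * cache$y / cache$z
  WS <- G %*% lrnBand(C, size)         # window is symmetric
  dM <- dY * cache$zb - 2 * beta * (alpha / size) * cache$M * WS
  dim(dM) <- d
  dM
}

poolFwd <- function(A, s = 2L) {
  d <- dim(A); H2 <- d[1] %/% s; W2 <- d[2] %/% s
  ri <- seq_len(H2) * s; ci <- seq_len(W2) * s
  a11 <- A[ri - 1L, ci - 1L, , , drop = FALSE]
  a21 <- A[ri, ci - 1L, , , drop = FALSE]
  a12 <- A[ri - 1L, ci, , , drop = FALSE]
  a22 <- A[ri, ci, , , drop = FALSE]
  M <- pmax(a11, a21, a12, a22)
  m11 <- a11 == M
  m21 <- (a21 == M) & !m11
  m12 <- (a12 == M) & !(m11 | m21)
  m22 <- !(m11 | m21 | m12)
  list(out = M, masks = list(m11, m21, m12, m22), inDim = d, ri = ri, ci = ci)
}

poolBwd <- function(dOut, cache) {
  dA <- array(0, cache$inDim)
  ri <- cache$ri; ci <- cache$ci
  dA[ri - 1L, ci - 1L, , ] <- dOut * cache$masks[[1]]
  dA[ri, ci - 1L, , ] <- dOut * cache$masks[[2]]
  dA[ri - 1L, ci, , ] <- dOut * cache$masks[[3]]
  dA[ri, ci, , ] <- dOut * cache$masks[[4]]
  dA
}

logSoftmax <- function(Z) {
  Zs <- sweep(Z, 2, apply(Z, 2, max))
  sweep(Zs, 2, log(colSums(exp(Zs))))
}

# Full forward pass; x is an array (H, W, N). With keepCache the per-layer
# caches needed for the backward pass are retained; convX marks conv layers
# whose im2col matrix must be kept (those with trainable weights).
netForward <- function(state, x, keepCache = FALSE, convX = character()) {
  cfg <- state@config
  d <- dim(x)
  if (length(d) == 2L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] != cfg@inputShape[1] || d[2] != cfg@inputShape[2])
    stop(sprintf("input shape (%d, %d) does not match network input (%d, %d)",
                 d[1], d[2], cfg@inputShape[1], cfg@inputShape[2]))
  N <- d[3]
  A <- array(x, c(d[1], d[2], N, 1L))
  caches <- list()
  flatDims <- NULL
  for (li in seq_along(state@arch$layers)) {
    lay <- state@arch$layers[[li]]
    if (lay$type == "conv") {
      cc <- convFwd(A, state@params[[paste0(lay$name, ".weight")]],
                    state@params[[paste0(lay$name, ".bias")]], lay$k,
                    state@arch$idx,
                    needX = keepCache && lay$name %in% convX)
      A <- cc$out
      if (keepCache) { cc$out <- NULL; caches[[li]] <- cc }
    } else if (lay$type == "relu") {
      if (keepCache) caches[[li]] <- list(pos = A > 0)
      A <- pmax(A, 0)
    } else if (lay$type == "lrn") {
      cc <- lrnFwd(A, cfg@lrnSize, cfg@lrnAlpha, cfg@lrnBeta, cfg@lrnK)
      A <- cc$out
      if (keepCache) { cc$out <- NULL; caches[[li]] <- cc }
    } else if (lay$type == "pool") {
      cc <- poolFwd(A, cfg@poolSize)
      A <- cc$out
      if (keepCache) { cc$out <- NULL; caches[[li]] <- cc }
    } else if (lay$type == "fc") {
      if (is.null(flatDims)) {
        flatDims <- dim(A)                       # (H, W, N, C)
        A <- aperm(A, c(1, 2, 4, 3))             # features contiguous per sample
        dim(A) <- c(prod(flatDims[c(1, 2, 4)]), N)
      }
      if (keepCache) caches[[li]] <- list(x = A)
      A <- state@params[[paste0(lay$name, ".weight")]] %*% A +
        state@params[[paste0(lay$name, ".bias")]]
    }
  }
  logp <- logSoftmax(A)
  list(logp = logp, caches = caches, logits = A, n = N, flatDims = flatDims)
}

#' Forward pass: class log-probabilities
#'
#' @param state A [NetworkState-class].
#' @param x Batch array (nCF, nFrames, n), a single nCF x nFrames matrix, or
#'   a [NeurogramSet-class]. Inputs are expected z-scored; visibly
#'   un-normalized input triggers a warning.
#' @return n x 10 matrix of log-probabilities (rows sum to 1 after exp).
#' @export
networkForward <- function(state, x) {
  if (methods::is(x, "NeurogramSet")) x <- x@values
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  gm <- mean(x); gs <- stats::sd(as.vector(x))
  if (abs(gm) > 0.25 || abs(gs - 1) > 0.5)
    warning("input does not appear z-scored (mean ", signif(gm, 2), ", sd ",
            signif(gs, 2), "); the classifier is trained on z-scored neurograms")
  t(netForward(state, x)$logp)
}

#' Predicted digits for a batch
#'
#' @param state A [NetworkState-class].
#' @param x Batch array or [NeurogramSet-class].
#' @param chunk Evaluation chunk size.
#' @return Integer vector of predicted digits (0-9).
#' @export
networkPredict <- function(state, x, chunk = 256L) {
  if (methods::is(x, "NeurogramSet")) x <- x@values
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  N <- dim(x)[3]
  out <- integer(N)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(N, start + chunk - 1L)
    lp <- netForward(state, x[, , idx, drop = FALSE])$logp
    out[idx] <- max.col(t(lp)) - 1L
  }
  out
}

# Layer names (C1..C5, F1..F5) that own tensors in `mask`.
maskLayers <- function(mask) unique(sub("\\..*$", "", mask))

# Backward pass: gradients for the tensors of the layers in `layersNeeded`
# (backpropagation stops once the deepest needed layer is reached).
netBackward <- function(state, fwd, labels, layersNeeded = NULL) {
  cfg <- state@config
  layers <- state@arch$layers
  paramLayers <- vapply(layers, function(l)
    if (l$type %in% c("conv", "fc")) l$name else "", character(1))
  if (is.null(layersNeeded)) layersNeeded <- setdiff(unique(paramLayers), "")
  stopIdx <- min(which(paramLayers %in% layersNeeded))
  N <- fwd$n
  Y <- matrix(0, cfg@nClasses, N)
  Y[cbind(labels + 1L, seq_len(N))] <- 1
  loss <- -mean(fwd$logp[cbind(labels + 1L, seq_len(N))])
  dA <- (exp(fwd$logp) - Y) / N
  grads <- list()
  for (li in rev(seq_len(length(layers)))) {
    if (li < stopIdx) break
    lay <- layers[[li]]
    atStop <- li == stopIdx
    if (lay$type == "fc") {
      cc <- fwd$caches[[li]]
      if (lay$name %in% layersNeeded) {
        grads[[paste0(lay$name, ".weight")]] <- tcrossprod(dA, cc$x)
        grads[[paste0(lay$name, ".bias")]] <- rowSums(dA)
      }
      if (!atStop)
        dA <- crossprod(state@params[[paste0(lay$name, ".weight")]], dA)
    } else if (lay$type == "relu") {
      dA <- dA * fwd$caches[[li]]$pos
    } else if (lay$type == "pool") {
      if (is.matrix(dA)) {                       # crossing the flatten boundary
        fd <- fwd$flatDims
        dim(dA) <- c(fd[1], fd[2], fd[4], fd[3])
        dA <- aperm(dA, c(1, 2, 4, 3))
      }
      dA <- poolBwd(dA, fwd$caches[[li]])
    } else if (lay$type == "lrn") {
      dA <- lrnBwd(dA, fwd$caches[[li]], cfg@lrnSize, cfg@lrnAlpha, cfg@lrnBeta)
    } else if (lay$type == "conv") {
      bb <- convBwd(dA, fwd$caches[[li]],
                    state@params[[paste0(lay$name, ".weight")]],
                    state@arch$idx, needDx = !atStop)
      if (lay$name %in% layersNeeded) {
        grads[[paste0(lay$name, ".weight")]] <- bb$dW
        grads[[paste0(lay$name, ".bias")]] <- bb$db
      }
      dA <- bb$dA
    }
  }
  list(grads = grads, loss = loss)
}

#' One Adam training step
#'
#' Computes cross-entropy loss (log-softmax + negative log likelihood) on the
#' batch, backpropagates, and updates only the tensors selected by the
#' trainable mask (weight decay added to the gradient, PyTorch-Adam style).
#' Masked-out tensors and their optimizer moments are bit-identical after the
#' step.
#'
#' @param state A [NetworkState-class].
#' @param x Batch array (nCF, nFrames, n) of z-scored neurograms.
#' @param labels Integer digits 0-9, length n.
#' @param trainableMask "all", "f5", or a character vector of tensor names.
#' @return List: `state` (updated [NetworkState-class]) and `loss`.
#' @export
trainStep <- function(state, x, labels, trainableMask = "all") {
  if (methods::is(x, "NeurogramSet")) x <- x@values
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] == 0L || length(labels) == 0L) stop("empty batch")
  stopifnot(length(labels) == dim(x)[3])
  mask <- tensorMask(state, trainableMask)
  needed <- maskLayers(mask)
  fwd <- netForward(state, x, keepCache = TRUE,
                    convX = grep("^C", needed, value = TRUE))
  bwd <- netBackward(state, fwd, as.integer(labels), layersNeeded = needed)
  cfg <- state@config
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- state@step + 1L
  params <- state@params; m <- state@adamM; v <- state@adamV
  for (nm in mask) {
    g <- bwd$grads[[nm]] + cfg@weightDecay * params[[nm]]
    m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
    v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g * g
    mh <- m[[nm]] / (1 - b1^t)
    vh <- v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - cfg@learningRate * mh / (sqrt(vh) + eps)
  }
  state@params <- params; state@adamM <- m; state@adamV <- v; state@step <- t
  list(state = state, loss = bwd$loss)
}

setMethod("show", "NetworkState", function(object) {
  cat(sprintf(
    "NetworkState: input %dx%d, conv depths [%s], FC widths [%s], step %d\n",
    object@config@inputShape[1], object@config@inputShape[2],
    paste(object@arch$convDepths, collapse = ","),
    paste(object@arch$fcWidths, collapse = ","), object@step))
})
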