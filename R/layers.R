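## R-side layer primitives of the classifier. Convolution and pooling hot
## loops live in src/layers.cpp; batch normalization, ReLU, the fully
## connected head, softmax cross-entropy and the RMSProp update are cheap
## vectorized operations and stay in R. Internal activation layout is
## (channels, height, width, batch), column-major.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

## batch normalization over channels; x is (C, ...) so a (C x n) matrix
## view puts each channel in a row
.bnForward <- function(x, gamma, beta, rmean, rvar, training) {
  d <- dim(x)
  C <- d[1L]
  xm <- matrix(x, nrow = C)
  n <- ncol(xm)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    invstd <- 1 / sqrt(v + .BN_EPS)
    xhat <- xc * invstd
    corr <- if (n > 1L) n / (n - 1L) else 1
    rmean <- .BN_MOMENTUM * rmean + (1 - .BN_MOMENTUM) * mu
    rvar <- .BN_MOMENTUM * rvar + (1 - .BN_MOMENTUM) * v * corr
  } else {
    invstd <- 1 / sqrt(rvar + .BN_EPS)
    xhat <- (xm - rmean) * invstd
  }
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, xhat = xhat, invstd = invstd, rmean = rmean, rvar = rvar)
}

.bnBackward <- function(dy, cache, gamma) {
  d <- dim(dy)
  C <- d[1L]
  dym <- matrix(dy, nrow = C)
  n <- ncol(dym)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  dx <- (gamma * cache$invstd / n) *
    (n * dym - dbeta - cache$xhat * dgamma)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Softmax probabilities from logits
#'
#' Column-wise numerically stable softmax: `exp(z_j) / sum_k exp(z_k)`.
#'
#' @param z numeric matrix of logits, classes in rows, samples in columns
#'   (a vector is treated as one column).
#' @return Matrix of the same shape; every column is a probability vector
#'   summing to 1.
#' @export
#' @examples
#' softmaxProb(c(2, 1, 0))
softmaxProb <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  zs <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(zs)
  e / rep(colSums(e), each = nrow(z))
}

## cross-entropy loss + gradient w.r.t. logits; yIdx are 1-based classes
.softmaxXent <- function(logits, yIdx) {
  probs <- softmaxProb(logits)
  B <- ncol(probs)
  picked <- probs[cbind(yIdx, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlogits <- probs
  dlogits[cbind(yIdx, seq_len(B))] <-
    dlogits[cbind(yIdx, seq_len(B))] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / B)
}

#' One RMSProp update step
#'
#' The optimizer primitive used for every network parameter: an
#' exponential moving average of squared gradients rescales the step,
#' `cache <- decay * cache + (1 - decay) * grad^2`, then
#' `param <- param - learningRate * grad / (sqrt(cache) + epsilon)`.
#'
#' @param param,grad,cache numeric arrays of identical shape (`cache`
#'   starts at zero).
#' @param learningRate,decay,epsilon RMSProp hyperparameters.
#' @return List with updated `param` and `cache`.
#' @export
#' @examples
#' rmspropStep(1, 2, 0, learningRate = 0.1, decay = 0.9, epsilon = 1e-8)
rmspropStep <- function(param, grad, cache, learningRate = 1e-3,
                        decay = 0.9, epsilon = 1e-8) {
  cache <- decay * cache + (1 - decay) * grad * grad
  list(param = param - learningRate * grad / (sqrt(cache) + epsilon),
       cache = cache)
}

## ---------------------------------------------------------------------------
## whole-network forward / backward over the internal (C,H,W,B) layout
## ---------------------------------------------------------------------------

.forwardPass <- function(params, state, cfg, x, training = FALSE) {
  nb <- length(cfg@blockChannels)
  k <- cfg@kernelSize
  pad <- (k - 1L) %/% 2L
  caches <- vector("list", nb)
  cur <- x
  for (i in seq_len(nb)) {
    dIn <- dim(cur)
    cf <- .convForwardC(cur, params[[paste0("W", i)]],
                        params[[paste0("b", i)]], dIn, k, pad)
    bn <- .bnForward(cf$y, params[[paste0("gamma", i)]],
                     params[[paste0("beta", i)]],
                     state[[paste0("rmean", i)]],
                     state[[paste0("rvar", i)]], training)
    if (training) {
      state[[paste0("rmean", i)]] <- bn$rmean
      state[[paste0("rvar", i)]] <- bn$rvar
    }
    r <- pmax(bn$y, 0)
    cache <- list(dimIn = dIn, cols = cf$cols, bn = bn, reluIn = bn$y)
    if (i < nb) {
      pl <- .poolForwardC(r, dim(r))
      cache$poolWhich <- pl$which
      cache$poolDim <- dim(r)
      cur <- pl$y
    } else {
      cur <- r
    }
    caches[[i]] <- cache
  }
  B <- dim(cur)[4L]
  xf <- matrix(cur, ncol = B)
  logits <- params$Wfc %*% xf + params$bfc
  list(logits = logits, caches = caches, flat = xf,
       flatDim = dim(cur), state = state)
}

.backwardPass <- function(fw, params, cfg, dlogits) {
  nb <- length(cfg@blockChannels)
  k <- cfg@kernelSize
  pad <- (k - 1L) %/% 2L
  grads <- list(
    Wfc = dlogits %*% t(fw$flat),
    bfc = rowSums(dlogits))
  dflat <- t(params$Wfc) %*% dlogits
  cur <- array(dflat, fw$flatDim)
  for (i in rev(seq_len(nb))) {
    cache <- fw$caches[[i]]
    if (i < nb)
      cur <- .poolBackwardC(cur, cache$poolWhich, cache$poolDim)
    cur <- cur * (cache$reluIn > 0)
    bb <- .bnBackward(cur, cache$bn, params[[paste0("gamma", i)]])
    grads[[paste0("gamma", i)]] <- bb$dgamma
    grads[[paste0("beta", i)]] <- bb$dbeta
    cb <- .convBackwardC(bb$dx, cache$cols, params[[paste0("W", i)]],
                         cache$dimIn, k, pad)
    grads[[paste0("W", i)]] <- cb$dW
    grads[[paste0("b", i)]] <- cb$db
    cur <- cb$dx
  }
  grads
}

## user layout (H,W,C,N) 8-bit -> internal (C,H,W,N) in [0,1]
.toInternal <- function(px) {
  aperm(px, c(3L, 1L, 2L, 4L)) / 255
}
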