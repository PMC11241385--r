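## The network primitives against brute-force oracles and finite
## differences. Internal kernels are reached through `:::` on purpose:
## they are implementation details with exact numeric contracts.

## drop the batch dimension of a (C,H,W,B) array, keeping 3-d shape
slice3 <- function(x, b) array(x[, , , b], dim(x)[1:3])

test_that("convolution equals the sliding-window multiply-and-sum", {
  set.seed(51)
  for (r in 1:40) {
    C <- sample(1:3, 1); H <- sample(3:6, 1); W <- sample(3:6, 1)
    Cout <- sample(1:3, 1); B <- sample(1:2, 1)
    x <- array(rnorm(C * H * W * B), c(C, H, W, B))
    w <- array(rnorm(Cout * C * 9), c(Cout, C, 3, 3))
    bias <- rnorm(Cout)
    got <- neosono:::.convForwardC(x, flattenKernel(w), bias,
                                   dim(x), 3L, 1L)$y
    for (b in seq_len(B))
      expect_equal(slice3(got, b), naiveConv(slice3(x, b), w, bias, 1L),
                   tolerance = 1e-12)
  }
})

test_that("a fixed 3x3 kernel on a 5x5 image matches the hand loop", {
  set.seed(52)
  x <- array(rnorm(25), c(1, 5, 5, 1))
  w <- array(c(0, 1, 0, 1, -4, 1, 0, 1, 0), c(1, 1, 3, 3))  # laplacian
  got <- neosono:::.convForwardC(x, flattenKernel(w), 0, dim(x), 3L, 1L)$y
  expect_equal(slice3(got, 1), naiveConv(slice3(x, 1), w, 0, 1L),
               tolerance = 1e-12)
})

test_that("max pooling equals the block-max loop, with floor division", {
  set.seed(53)
  for (r in 1:40) {
    C <- sample(1:3, 1)
    H <- sample(2:7, 1); W <- sample(2:7, 1)  # odd sizes exercise floor
    x <- array(rnorm(C * H * W), c(C, H, W, 1))
    got <- neosono:::.poolForwardC(x, dim(x))$y
    expect_equal(slice3(got, 1), naivePool(slice3(x, 1)), tolerance = 1e-12)
  }
  x25 <- array(rnorm(25 * 25), c(1, 25, 25, 1))
  expect_equal(dim(neosono:::.poolForwardC(x25, dim(x25))$y)[2:3],
               c(12L, 12L))
})

test_that("pooling backward routes gradient to the (first) argmax", {
  x <- array(0, c(1, 2, 2, 1))  # all ties: gradient goes to the first cell
  fw <- neosono:::.poolForwardC(x, dim(x))
  dx <- neosono:::.poolBackwardC(array(1, c(1, 1, 1, 1)), fw$which, dim(x))
  expect_equal(as.vector(dx), c(1, 0, 0, 0))
})

test_that("softmax matches direct evaluation and stays on the simplex", {
  expect_equal(as.vector(softmaxProb(c(0, 0, 0))), rep(1 / 3, 3))
  z <- c(2, 1, 0)
  expect_equal(as.vector(softmaxProb(z)), exp(z) / sum(exp(z)),
               tolerance = 1e-12)
  set.seed(54)
  for (r in 1:100) {
    z <- matrix(rnorm(3 * 4, 0, sample(c(1, 10, 100), 1)), 3)
    p <- softmaxProb(z)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(colSums(p), rep(1, 4), tolerance = 1e-9)
  }
})

test_that("ReLU activations are nonnegative and preserve positives", {
  set.seed(55)
  cfg <- tinyNetworkConfig()
  model <- buildNetwork(cfg, seed = 5)
  x <- neosono:::.toInternal(array(sample(0:255, 12 * 12 * 3 * 2, TRUE),
                                   c(12, 12, 3, 2)))
  fw <- neosono:::.forwardPass(model@params, model@state, cfg, x)
  for (cache in fw$caches) {
    r <- pmax(cache$reluIn, 0)
    expect_true(all(r >= 0))
    pos <- cache$reluIn > 0
    expect_identical(r[pos], cache$reluIn[pos])
  }
})

test_that("backpropagated gradients match finite differences", {
  set.seed(56)
  cfg <- networkConfig(inputHeight = 6, inputWidth = 6, inputChannels = 1,
                       blockChannels = c(2, 3), kernelSize = 3, nClasses = 3)
  model <- buildNetwork(cfg, seed = 6)
  params <- model@params
  state <- model@state
  x <- array(runif(6 * 6 * 2), c(1, 6, 6, 2))
  y <- c(1L, 3L)
  lossAt <- function(p) {
    fw <- neosono:::.forwardPass(p, state, cfg, x, training = TRUE)
    neosono:::.softmaxXent(fw$logits, y)$loss
  }
  fw <- neosono:::.forwardPass(params, state, cfg, x, training = TRUE)
  sx <- neosono:::.softmaxXent(fw$logits, y)
  grads <- neosono:::.backwardPass(fw, params, cfg, sx$dlogits)
  eps <- 1e-6
  for (nm in c("W1", "b1", "gamma1", "beta1", "W2", "Wfc", "bfc")) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("RMSProp reproduces a hand-stepped scalar recursion", {
  ## quadratic loss J(w) = w^2, grad = 2w, from w0 = 1,
  ## lr = 0.1, decay = 0.9, eps = 0 for clean arithmetic:
  ## c1 = 0.1*4 = 0.4,      w1 = 1 - 0.1*2/sqrt(0.4)
  ## c2 = 0.9*c1 + 0.1*(2 w1)^2, w2 = w1 - 0.1*(2 w1)/sqrt(c2), ...
  w <- 1; cache <- 0
  traj <- numeric(3)
  for (t in 1:3) {
    up <- rmspropStep(w, 2 * w, cache, learningRate = 0.1, decay = 0.9,
                      epsilon = 0)
    w <- up$param; cache <- up$cache
    traj[t] <- w
  }
  wh <- 1; ch <- 0
  hand <- numeric(3)
  for (t in 1:3) {
    g <- 2 * wh
    ch <- 0.9 * ch + 0.1 * g^2
    wh <- wh - 0.1 * g / sqrt(ch)
    hand[t] <- wh
  }
  expect_equal(traj, hand, tolerance = 1e-15)
  ## first step analytically: 1 - 0.2/sqrt(0.4)
  expect_equal(traj[1], 1 - 0.2 / sqrt(0.4), tolerance = 1e-15)
})
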