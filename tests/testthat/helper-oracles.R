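## Independent brute-force oracles used to validate the package's
## implementations. These deliberately avoid the code paths they check:
## plain loops and direct textbook formulas only.

## per-pixel sRGB (D65) -> CIE Lab by the published formulas
refLab <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  r <- xyz / c(0.95047, 1, 1.08883)
  f <- ifelse(r > (6 / 29)^3, r^(1 / 3), r * (29 / 6)^2 / 3 + 4 / 29)
  c(L = 116 * f[2] - 16, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}

## element-wise crop by explicit double loop
naiveCrop <- function(px, r1, r2, c1, c2) {
  out <- array(0, c(r2 - r1 + 1L, c2 - c1 + 1L, dim(px)[3]))
  for (i in r1:r2) for (j in c1:c2) for (ch in seq_len(dim(px)[3]))
    out[i - r1 + 1L, j - c1 + 1L, ch] <- px[i, j, ch]
  out
}

## channel means by explicit accumulation
naiveChannelMeans <- function(px) {
  sums <- numeric(3)
  n <- 0L
  for (i in seq_len(dim(px)[1])) for (j in seq_len(dim(px)[2])) {
    n <- n + 1L
    for (ch in 1:3) sums[ch] <- sums[ch] + px[i, j, ch]
  }
  sums / n
}

## bilinear resample at half-pixel centers, coded independently
naiveBilinear <- function(x, P, Q) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, P, Q)
  for (i in seq_len(P)) for (j in seq_len(Q)) {
    sr <- (i - 0.5) * H / P + 0.5
    sc <- (j - 0.5) * W / Q + 0.5
    r0 <- min(max(floor(sr), 1), H); r1 <- min(r0 + 1, H)
    c0 <- min(max(floor(sc), 1), W); c1 <- min(c0 + 1, W)
    wr <- min(max(sr - r0, 0), 1); wc <- min(max(sc - c0, 0), 1)
    out[i, j] <- (1 - wr) * (1 - wc) * x[r0, c0] + wr * (1 - wc) * x[r1, c0] +
      (1 - wr) * wc * x[r0, c1] + wr * wc * x[r1, c1]
  }
  out
}

## same-padded stride-1 multi-channel sliding-window multiply-and-sum;
## x is (C,H,W), w is (Cout, Cin, k, k)
naiveConv <- function(x, w, bias, pad) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  Cout <- dim(w)[1]; k <- dim(w)[3]
  y <- array(0, c(Cout, H, W))
  for (co in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- bias[co]
    for (a in seq_len(k)) for (b in seq_len(k)) {
      r <- i + a - 1L - pad; cc <- j + b - 1L - pad
      if (r >= 1 && r <= H && cc >= 1 && cc <= W)
        for (ci in seq_len(C))
          acc <- acc + x[ci, r, cc] * w[co, ci, a, b]
    }
    y[co, i, j] <- acc
  }
  y
}

## 2x2 stride-2 block max with floor division; x is (C,H,W)
naivePool <- function(x) {
  C <- dim(x)[1]; Ho <- dim(x)[2] %/% 2L; Wo <- dim(x)[3] %/% 2L
  y <- array(0, c(C, Ho, Wo))
  for (c in seq_len(C)) for (i in seq_len(Ho)) for (j in seq_len(Wo))
    y[c, i, j] <- max(x[c, 2 * i - 1, 2 * j - 1], x[c, 2 * i, 2 * j - 1],
                      x[c, 2 * i - 1, 2 * j], x[c, 2 * i, 2 * j])
  y
}

## confusion counts by explicit tally loop
naiveConfusion <- function(truth, predicted, classes) {
  K <- length(classes)
  m <- matrix(0L, K, K, dimnames = list(truth = classes,
                                        predicted = classes))
  for (s in seq_along(truth)) {
    i <- which(classes == truth[s]); j <- which(classes == predicted[s])
    m[i, j] <- m[i, j] + 1L
  }
  m
}

## AUC as the exhaustively counted fraction of correctly ordered
## positive-negative pairs (ties count 1/2)
allPairsAuc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## weight matrix layout used by the conv kernels: row = output channel,
## column index = ci + Cin*((a-1) + k*(b-1))
flattenKernel <- function(w) {
  Cout <- dim(w)[1]; Cin <- dim(w)[2]; k <- dim(w)[3]
  m <- matrix(0, Cout, Cin * k * k)
  for (co in seq_len(Cout)) for (a in seq_len(k)) for (b in seq_len(k))
    for (ci in seq_len(Cin))
      m[co, ci + Cin * ((a - 1) + k * (b - 1))] <- w[co, ci, a, b]
  m
}

## small labeled dataset with constant-intensity classes, for fast
## network tests at reduced input size
tinyDataset <- function(nPerClass, side = 12L, seed = 1) {
  n <- 3L * nPerClass
  px <- array(0, c(side, side, 3L, n))
  lab <- character(n)
  set.seed(seed)
  means <- c(Normal = 40, Moderate = 120, Intensive = 220)
  i <- 0L
  for (cls in gradeLevels()) for (s in seq_len(nPerClass)) {
    i <- i + 1L
    base <- pmin(pmax(round(means[[cls]] + stats::rnorm(side * side, 0, 12)),
                      0), 255)
    px[, , , i] <- array(rep(base, 3L), c(side, side, 3L))
    lab[i] <- cls
  }
  new("CompositeDataset", pixels = px,
      labels = factor(lab, levels = gradeLevels()),
      manifest = data.frame(id = sprintf("t%03d", seq_len(n)), label = lab,
                            stringsAsFactors = FALSE))
}

tinyNetworkConfig <- function(side = 12L)
  networkConfig(inputHeight = side, inputWidth = side, inputChannels = 3,
                blockChannels = c(4, 6), kernelSize = 3, nClasses = 3)
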