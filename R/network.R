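## Stage two of the pipeline: build, train and apply the compact
## convolutional classifier, plus the data-splitting protocol and k-fold
## cross-validation.

#' Per-layer output shapes of a network configuration
#'
#' Tabulates the layer sequence and its output dimensions: repeated
#' same-padded convolution / batch-norm / ReLU blocks with 2x2 stride-2
#' max pooling (floor division) after every block but the last, then the
#' fully connected softmax head. With the defaults the feature-map sides
#' are 100, 50, 25 and 12.
#'
#' @param cfg a [NetworkConfig-class].
#' @return data.frame with columns `layer`, `height`, `width`, `channels`.
#' @export
#' @examples
#' layerShapes(networkConfig())
layerShapes <- function(cfg = networkConfig()) {
  stopifnot(is(cfg, "NetworkConfig"))
  validObject(cfg)
  h <- cfg@inputHeight; w <- cfg@inputWidth
  rows <- list(data.frame(layer = "Input", height = h, width = w,
                          channels = cfg@inputChannels))
  nb <- length(cfg@blockChannels)
  for (i in seq_len(nb)) {
    ch <- cfg@blockChannels[i]
    for (nm in c("Conv", "BatchNorm", "ReLU"))
      rows[[length(rows) + 1L]] <-
        data.frame(layer = paste0(nm, i), height = h, width = w,
                   channels = ch)
    if (i < nb) {
      h <- h %/% 2L; w <- w %/% 2L
      rows[[length(rows) + 1L]] <-
        data.frame(layer = paste0("MaxPool", i), height = h, width = w,
                   channels = ch)
    }
  }
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "FullyConnected", height = 1L, width = 1L,
               channels = cfg@nClasses)
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "Softmax", height = 1L, width = 1L,
               channels = cfg@nClasses)
  do.call(rbind, rows)
}

#' Build an untrained network
#'
#' Allocates and initializes all parameters of the configured
#' architecture: seeded He-style normal initialization for convolution
#' and fully connected weights (sd `sqrt(2 / fanIn)`), zero biases,
#' unit batch-norm scales and zero offsets.
#'
#' @param cfg a [NetworkConfig-class].
#' @param seed integer seed for the weight draw.
#' @return An untrained [TrainedModel-class].
#' @export
#' @examples
#' model <- buildNetwork(networkConfig(), seed = 1)
#' model
buildNetwork <- function(cfg = networkConfig(), seed = 1) {
  stopifnot(is(cfg, "NetworkConfig"))
  validObject(cfg)
  k <- cfg@kernelSize
  .withSeed(seed, {
    params <- list()
    state <- list()
    cin <- cfg@inputChannels
    h <- cfg@inputHeight; w <- cfg@inputWidth
    nb <- length(cfg@blockChannels)
    for (i in seq_len(nb)) {
      cout <- cfg@blockChannels[i]
      fanIn <- cin * k * k
      params[[paste0("W", i)]] <-
        matrix(stats::rnorm(cout * fanIn, sd = sqrt(2 / fanIn)), cout, fanIn)
      params[[paste0("b", i)]] <- numeric(cout)
      params[[paste0("gamma", i)]] <- rep(1, cout)
      params[[paste0("beta", i)]] <- numeric(cout)
      state[[paste0("rmean", i)]] <- numeric(cout)
      state[[paste0("rvar", i)]] <- rep(1, cout)
      if (i < nb) { h <- h %/% 2L; w <- w %/% 2L }
      cin <- cout
    }
    d <- cin * h * w
    params$Wfc <- matrix(stats::rnorm(cfg@nClasses * d, sd = sqrt(2 / d)),
                         cfg@nClasses, d)
    params$bfc <- numeric(cfg@nClasses)
    new("TrainedModel", params = params, state = state, config = cfg,
        history = data.frame(), trained = FALSE)
  })
}

#' Stratified train/validation/test split
#'
#' Partitions a dataset into disjoint, exhaustive train, validation and
#' test sets, stratified by class. Split sizes follow the fractions by
#' largest remainder globally (200 samples at 0.70/0.15/0.15 give exactly
#' 140/30/30) while per-class counts stay within one sample of
#' proportional. Reproducible under the same seed.
#'
#' @param dataset a [CompositeDataset-class].
#' @param fractions three nonnegative numbers summing to 1.
#' @param seed integer seed.
#' @return List with `train`, `validation`, `test`
#'   ([CompositeDataset-class], possibly empty) and `assignments`
#'   (factor over samples).
#' @export
splitDataset <- function(dataset, fractions = c(0.70, 0.15, 0.15),
                         seed = 1) {
  stopifnot(is(dataset, "CompositeDataset"))
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three nonnegative numbers summing to 1")
  y <- dataset@labels
  if (anyNA(y)) stop("all samples must be labeled")
  counts <- table(y)
  nParts <- sum(fractions > 0)
  if (any(counts < nParts))
    stop("every class needs at least as many samples as nonempty partitions")
  sizes <- .splitSizes(as.integer(counts), fractions)
  splitNames <- c("train", "validation", "test")
  assign <- character(length(y))
  .withSeed(seed, {
    for (k in seq_along(levels(y))) {
      idx <- sample(which(y == levels(y)[k]))
      at <- 0L
      for (s in 1:3) {
        take <- sizes[k, s]
        if (take > 0L)
          assign[idx[at + seq_len(take)]] <- splitNames[s]
        at <- at + take
      }
    }
  })
  assign <- factor(assign, levels = splitNames)
  list(train = dataset[assign == "train"],
       validation = dataset[assign == "validation"],
       test = dataset[assign == "test"],
       assignments = assign)
}

## per-class split counts: global sizes by largest remainder, per-class
## floors, leftovers to the split with the largest outstanding deficit
.splitSizes <- function(classCounts, fractions) {
  nTot <- sum(classCounts)
  gq <- nTot * fractions
  gt <- floor(gq)
  rem <- nTot - sum(gt)
  if (rem > 0) {
    ord <- order(gq - gt, decreasing = TRUE)
    gt[ord[seq_len(rem)]] <- gt[ord[seq_len(rem)]] + 1L
  }
  fl <- floor(outer(classCounts, fractions))
  def <- gt - colSums(fl)
  for (k in seq_along(classCounts)) {
    left <- classCounts[k] - sum(fl[k, ])
    while (left > 0L) {
      j <- which.max(def)
      fl[k, j] <- fl[k, j] + 1L
      def[j] <- def[j] - 1L
      left <- left - 1L
    }
  }
  storage.mode(fl) <- "integer"
  fl
}

#' Train the classifier with minibatch RMSProp
#'
#' Runs up to `maxEpochs` epochs of minibatch RMSProp on the softmax
#' cross-entropy, with per-epoch shuffling, batch-norm running-statistic
#' updates and a per-epoch history of training loss/accuracy (running
#' average over minibatches) and validation loss/accuracy. Deterministic
#' given the seed in `tcfg`.
#'
#' @param model an (untrained or trained) [TrainedModel-class].
#' @param train training [CompositeDataset-class] (labels required).
#' @param validation optional validation [CompositeDataset-class].
#' @param tcfg a [TrainingConfig-class].
#' @return The trained [TrainedModel-class] with filled `history`.
#' @export
trainNetwork <- function(model, train, validation = NULL,
                         tcfg = trainingConfig()) {
  stopifnot(is(model, "TrainedModel"), is(train, "CompositeDataset"),
            is(tcfg, "TrainingConfig"))
  validObject(tcfg)
  cfg <- model@config
  if (length(train) < 1L) stop("training set is empty")
  .checkInput(train, cfg)
  x <- .toInternal(train@pixels)
  y <- as.integer(train@labels)
  if (anyNA(y)) stop("all training samples must be labeled")
  hasVal <- !is.null(validation) && length(validation) > 0L
  if (hasVal) {
    .checkInput(validation, cfg)
    xv <- .toInternal(validation@pixels)
    yv <- as.integer(validation@labels)
  }
  params <- model@params
  state <- model@state
  cache <- lapply(params, function(p) p * 0)
  n <- length(y)
  bs <- min(tcfg@batchSize, n)
  hist <- vector("list", tcfg@maxEpochs)
  .withSeed(tcfg@seed, {
    for (epoch in seq_len(tcfg@maxEpochs)) {
      perm <- sample.int(n)
      lossSum <- 0; accSum <- 0; seen <- 0L
      for (start in seq(1L, n, by = bs)) {
        take <- perm[start:min(start + bs - 1L, n)]
        xb <- x[, , , take, drop = FALSE]
        yb <- y[take]
        fw <- .forwardPass(params, state, cfg, xb, training = TRUE)
        state <- fw$state
        sx <- .softmaxXent(fw$logits, yb)
        if (!is.finite(sx$loss))
          stop("training diverged: non-finite loss at epoch ", epoch)
        grads <- .backwardPass(fw, params, cfg, sx$dlogits)
        for (nm in names(params)) {
          up <- rmspropStep(params[[nm]], grads[[nm]], cache[[nm]],
                            tcfg@learningRate, tcfg@decay, tcfg@epsilon)
          params[[nm]] <- up$param
          cache[[nm]] <- up$cache
        }
        nb <- length(take)
        lossSum <- lossSum + sx$loss * nb
        accSum <- accSum +
          sum(max.col(t(sx$probs), ties.method = "first") == yb)
        seen <- seen + nb
      }
      row <- data.frame(epoch = epoch, trainLoss = lossSum / seen,
                        trainAcc = accSum / seen,
                        valLoss = NA_real_, valAcc = NA_real_)
      if (hasVal) {
        ev <- .evalPass(params, state, cfg, xv, yv)
        row$valLoss <- ev$loss
        row$valAcc <- ev$acc
      }
      hist[[epoch]] <- row
    }
  })
  new("TrainedModel", params = params, state = state, config = cfg,
      history = do.call(rbind, hist), trained = TRUE)
}

.checkInput <- function(dataset, cfg) {
  d <- dim(dataset@pixels)
  if (d[1L] != cfg@inputHeight || d[2L] != cfg@inputWidth ||
      d[3L] != cfg@inputChannels)
    stop(sprintf("shape error: samples are %d x %d x %d, network expects %d x %d x %d",
                 d[1L], d[2L], d[3L], cfg@inputHeight, cfg@inputWidth,
                 cfg@inputChannels))
  invisible(TRUE)
}

## inference-mode loss/accuracy over a full (C,H,W,N) tensor, in batches
.evalPass <- function(params, state, cfg, x, y, batch = 32L) {
  n <- dim(x)[4L]
  lossSum <- 0; acc <- 0L
  for (start in seq(1L, n, by = batch)) {
    take <- start:min(start + batch - 1L, n)
    fw <- .forwardPass(params, state, cfg, x[, , , take, drop = FALSE],
                       training = FALSE)
    sx <- .softmaxXent(fw$logits, y[take])
    lossSum <- lossSum + sx$loss * length(take)
    acc <- acc + sum(max.col(t(sx$probs), ties.method = "first") == y[take])
  }
  list(loss = lossSum / n, acc = acc / n)
}

#' Predict grades for composite samples
#'
#' Applies the trained network in inference mode (batch-norm running
#' statistics) and returns class probabilities and argmax labels, ties
#' broken toward the lower class index.
#'
#' @param object a trained [TrainedModel-class].
#' @param newdata a [CompositeDataset-class] or a `height x width x
#'   channels x n` 8-bit array at the configured input size.
#' @param ... unused.
#' @return List with `probabilities` (n x K matrix, rows summing to 1)
#'   and `classes` (factor with levels [gradeLevels()]).
#' @export
setMethod("predict", "TrainedModel", function(object, newdata, ...) {
  px <- if (is(newdata, "CompositeDataset")) newdata@pixels else newdata
  if (length(dim(px)) == 3L) px <- array(px, c(dim(px), 1L))
  if (length(dim(px)) != 4L)
    stop("shape error: newdata must be a height x width x channels x n array")
  cfg <- object@config
  d <- dim(px)
  if (d[1L] != cfg@inputHeight || d[2L] != cfg@inputWidth ||
      d[3L] != cfg@inputChannels)
    stop(sprintf("shape error: input is %d x %d x %d, network expects %d x %d x %d",
                 d[1L], d[2L], d[3L], cfg@inputHeight, cfg@inputWidth,
                 cfg@inputChannels))
  x <- .toInternal(px)
  n <- d[4L]
  probs <- matrix(NA_real_, n, cfg@nClasses)
  for (start in seq(1L, n, by = 32L)) {
    take <- start:min(start + 31L, n)
    fw <- .forwardPass(object@params, object@state, cfg,
                       x[, , , take, drop = FALSE], training = FALSE)
    probs[take, ] <- t(softmaxProb(fw$logits))
  }
  cls <- gradeLevels()[seq_len(cfg@nClasses)]
  colnames(probs) <- if (cfg@nClasses == 3L) cls else
    paste0("class", seq_len(cfg@nClasses))
  classes <- max.col(probs, ties.method = "first")
  list(probabilities = probs,
       classes = if (cfg@nClasses == 3L)
         .gradeFactor(gradeLevels()[classes]) else factor(classes))
})

#' Save or load a model checkpoint
#'
#' `saveModel()` writes the parameters, batch-norm state and history to a
#' single RDS file plus a human-readable JSON sidecar
#' (`<path>.json`) describing the architecture and training record;
#' `loadModel()` restores the model.
#'
#' @param model a [TrainedModel-class].
#' @param path checkpoint file path (e.g. `model.rds`).
#' @return `saveModel()` returns `path` invisibly; `loadModel()` returns
#'   the [TrainedModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  saveRDS(list(params = model@params, state = model@state,
               config = list(
                 inputHeight = model@config@inputHeight,
                 inputWidth = model@config@inputWidth,
                 inputChannels = model@config@inputChannels,
                 blockChannels = model@config@blockChannels,
                 kernelSize = model@config@kernelSize,
                 nClasses = model@config@nClasses),
               history = model@history, trained = model@trained),
          path)
  jsonlite::write_json(
    list(config = list(
           inputHeight = model@config@inputHeight,
           inputWidth = model@config@inputWidth,
           inputChannels = model@config@inputChannels,
           blockChannels = model@config@blockChannels,
           kernelSize = model@config@kernelSize,
           nClasses = model@config@nClasses),
         trained = model@trained,
         epochs = nrow(model@history),
         nParameters = sum(vapply(model@params, length, integer(1L)))),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(networkConfig, x$config)
  new("TrainedModel", params = x$params, state = x$state, config = cfg,
      history = x$history, trained = x$trained)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Partitions the dataset into k stratified folds, trains a fresh network
#' on each k-1-fold complement (fold f uses seed `tcfg@seed + f`), tests
#' on the held-out fold so every sample is tested exactly once, and
#' aggregates the per-fold metric suites into mean and sample-sd tables
#' via [cvAggregate()].
#'
#' @param dataset a labeled [CompositeDataset-class].
#' @param k number of folds, >= 2 (default 5).
#' @param cfg a [NetworkConfig-class].
#' @param tcfg a [TrainingConfig-class].
#' @return List with `folds` (per-fold [EvaluationReport-class]s),
#'   `assignments` (fold index per sample) and `summary` (the
#'   [cvAggregate()] mean/sd tables).
#' @export
crossValidate <- function(dataset, k = 5, cfg = networkConfig(),
                          tcfg = trainingConfig()) {
  stopifnot(is(dataset, "CompositeDataset"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  y <- dataset@labels
  if (any(table(y) < k))
    stop("every class needs at least k samples")
  folds <- integer(length(y))
  .withSeed(tcfg@seed, {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    trainDs <- dataset[folds != f]
    testDs <- dataset[folds == f]
    foldSeed <- tcfg@seed + f
    model <- buildNetwork(cfg, seed = foldSeed)
    ftcfg <- tcfg
    ftcfg@seed <- as.integer(foldSeed)
    model <- trainNetwork(model, trainDs, validation = NULL, tcfg = ftcfg)
    pr <- predict(model, testDs)
    reports[[f]] <- evaluationReport(testDs@labels, pr$classes,
                                     pr$probabilities)
  }
  list(folds = reports, assignments = folds,
       summary = cvAggregate(reports))
}
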