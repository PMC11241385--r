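test_that("the default architecture reports the published layer shapes", {
  sh <- layerShapes(networkConfig())
  expect_equal(sh$height[sh$layer == "Input"], 100L)
  expect_equal(sh[sh$layer == "Conv1", c("height", "channels")],
               data.frame(height = 100L, channels = 16L),
               ignore_attr = TRUE)
  expect_equal(sh$height[sh$layer %in% paste0("MaxPool", 1:3)],
               c(50L, 25L, 12L))
  expect_equal(sh[sh$layer == "Conv4", c("height", "width", "channels")],
               data.frame(height = 12L, width = 12L, channels = 128L),
               ignore_attr = TRUE)
  expect_equal(sh$channels[sh$layer == "FullyConnected"], 3L)
})

test_that("a forward pass yields a probability vector over the grades", {
  model <- buildNetwork(networkConfig(), seed = 2)
  x <- array(sample(0:255, 100 * 100 * 3, TRUE), c(100, 100, 3, 1))
  pr <- predict(model, x)
  expect_equal(dim(pr$probabilities), c(1L, 3L))
  expect_equal(sum(pr$probabilities), 1, tolerance = 1e-6)
  expect_true(all(pr$probabilities >= 0))
  expect_error(predict(model, array(0, c(50, 50, 3, 1))), "shape error")
})

test_that("equal logits resolve ties toward the lower class index", {
  cfg <- tinyNetworkConfig()
  model <- buildNetwork(cfg, seed = 3)
  model@params$Wfc[] <- 0
  model@params$bfc[] <- 0
  pr <- predict(model, array(sample(0:255, 12 * 12 * 3 * 4, TRUE),
                             c(12, 12, 3, 4)))
  expect_equal(pr$probabilities, matrix(1 / 3, 4, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(pr$classes == "Normal"))
})

test_that("the stratified split honors the protocol sizes", {
  ## 200 samples at 0.70/0.15/0.15 must give exactly 140/30/30
  ds <- tinyDataset(67, seed = 4)[1:200]
  sp <- splitDataset(ds, seed = 4)
  expect_equal(length(sp$train), 140L)
  expect_equal(length(sp$validation), 30L)
  expect_equal(length(sp$test), 30L)
  ## disjoint and exhaustive
  expect_equal(as.vector(table(sp$assignments)), c(140L, 30L, 30L))
  expect_equal(length(sp$train) + length(sp$validation) + length(sp$test),
               length(ds))
  ## stratification: per-class counts within one of proportional
  for (lev in gradeLevels()) {
    nTrain <- sum(labels(sp$train) == lev)
    expect_lte(abs(nTrain - 0.7 * sum(labels(ds) == lev)), 1)
  }
})

test_that("degenerate fractions and reproducibility behave as specified", {
  ds <- tinyDataset(5, seed = 5)
  all <- splitDataset(ds, c(1, 0, 0), seed = 1)
  expect_equal(length(all$train), 15L)
  expect_equal(length(all$test), 0L)
  a <- splitDataset(ds, seed = 8)
  b <- splitDataset(ds, seed = 8)
  expect_identical(a$assignments, b$assignments)
  c3 <- splitDataset(ds, seed = 9)
  expect_false(identical(a$assignments, c3$assignments))
  expect_equal(table(a$assignments), table(c3$assignments))
  expect_error(splitDataset(tinyDataset(1), c(0.4, 0.3, 0.3)),
               "at least as many samples")
})

test_that("a zero learning rate leaves every weight unchanged", {
  ds <- tinyDataset(4, seed = 6)
  cfg <- tinyNetworkConfig()
  model <- buildNetwork(cfg, seed = 6)
  before <- model@params
  trained <- trainNetwork(model, ds, tcfg = trainingConfig(
    learningRate = 0, maxEpochs = 3, batchSize = 4, seed = 6))
  expect_identical(trained@params, before)
  expect_equal(nrow(trainHistory(trained)), 3L)
})

test_that("training is reproducible under a fixed seed", {
  ds <- tinyDataset(4, seed = 7)
  cfg <- tinyNetworkConfig()
  tcfg <- trainingConfig(maxEpochs = 3, batchSize = 6, seed = 7)
  m1 <- trainNetwork(buildNetwork(cfg, seed = 7), ds, tcfg = tcfg)
  m2 <- trainNetwork(buildNetwork(cfg, seed = 7), ds, tcfg = tcfg)
  expect_identical(m1@params, m2@params)
  expect_identical(trainHistory(m1), trainHistory(m2))
})

test_that("training separates well-separated classes at reduced scale", {
  ds <- tinyDataset(10, seed = 8)
  sp <- splitDataset(ds, seed = 8)
  tcfg <- trainingConfig(maxEpochs = 12, batchSize = 8, seed = 8)
  model <- trainNetwork(buildNetwork(tinyNetworkConfig(), seed = 8),
                        sp$train, sp$validation, tcfg)
  h <- trainHistory(model)
  expect_equal(nrow(h), 12L)
  expect_gt(tail(h$trainAcc, 1), 0.9)
  pr <- predict(model, sp$test)
  expect_gt(mean(pr$classes == labels(sp$test)), 0.8)
})

test_that("model checkpoints round trip through disk", {
  ds <- tinyDataset(4, seed = 10)
  model <- trainNetwork(buildNetwork(tinyNetworkConfig(), seed = 10), ds,
                        tcfg = trainingConfig(maxEpochs = 2, batchSize = 6,
                                              seed = 10))
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- loadModel(f)
  expect_identical(back@params, model@params)
  expect_identical(back@state, model@state)
  px <- pixels(ds)
  expect_equal(predict(back, px)$probabilities,
               predict(model, px)$probabilities)
})

test_that("cross-validation partitions every sample exactly once", {
  ds <- tinyDataset(6, seed = 9)
  cv <- suppressWarnings(  # 3-epoch folds may leave a class unpredicted
    crossValidate(ds, k = 3, cfg = tinyNetworkConfig(),
                  tcfg = trainingConfig(maxEpochs = 3, batchSize = 6,
                                        seed = 9)))
  expect_equal(length(cv$folds), 3L)
  expect_equal(sort(unique(cv$assignments)), 1:3)
  expect_equal(as.vector(table(cv$assignments)), rep(6L, 3))
  ## every fold report covers exactly its fold size
  for (f in 1:3)
    expect_equal(sum(cv$folds[[f]]@confusion), sum(cv$assignments == f))
  ## summary rows: three classes plus Overall
  expect_equal(rownames(cv$summary$mean),
               c(gradeLevels(), "Overall"))
  ## the overall mean is the mean of the per-class means
  expect_equal(unname(unlist(cv$summary$mean["Overall", ])),
               unname(colMeans(as.matrix(cv$summary$mean[1:3, ]))))
  expect_error(crossValidate(ds, k = 1), "k must be >= 2")
  expect_error(crossValidate(tinyDataset(2), k = 3,
                             cfg = tinyNetworkConfig()),
               "at least k samples")
})
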