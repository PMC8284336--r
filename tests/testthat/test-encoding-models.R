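test_that("the fitted LN nonlinearity is monotone over its upper range", {
  fx <- fxRecovery()
  m <- fitLN(fx$movie, fx$train)
  expect_s4_class(m, "LNModel")
  upper <- m@nlRate[m@nlInput > stats::quantile(m@nlInput, 0.5)]
  expect_true(all(diff(upper) > -1e-6))
  expect_gt(max(upper), min(m@nlRate) + 1)
})

test_that("LN refuses to fit on too few training spikes", {
  mov <- generateWhiteNoise(c(3000, 4, 4), frameRate = 30, seed = 21)
  sparse <- spikeTrain(seq(5, 90, length.out = 50), 100)
  expect_error(fitLN(mov, sparse), "training spikes")
})

test_that("LN predictions reproduce the simulated rate of a noiseless cell", {
  mov <- generateWhiteNoise(c(54000, 4, 4), frameRate = 30, seed = 2)
  cell <- groundTruthCell(center = c(2.5, 2.5), sigmaCenter = 0.9,
                          sigmaSurround = 1.8, gain = 60, baselineRate = 0.5,
                          frameRate = 30)
  tr <- simulateCell(cell, mov, seed = 3)
  m <- fitLN(mov, tr, split = trainTestSplit(54000, 1, 0))
  pred <- predictRate(m, mov)
  expect_true(all(pred >= 0))
  k <- cellKernel(cell, c(4, 4))
  S <- retfidelity:::flattenFrames(stimFrames(mov)) - 0.5
  drive <- retfidelity:::cellDrive(k, S)
  trueRate <- 60 * pmax(0, drive - 0.2) + 0.5
  ok <- !is.na(drive)
  expect_gt(cor(pred[ok], trueRate[ok]), 0.95)
})

test_that("a constant nonlinearity predicts a constant trace", {
  mov <- generateWhiteNoise(c(500, 3, 3), frameRate = 30, seed = 22)
  m <- new("LNModel", kernel = array(rnorm(24 * 9), c(24, 3, 3)),
           nlInput = c(-1, 1), nlRate = c(4, 4), frameRate = 30,
           cellId = "const")
  expect_identical(length(unique(predictRate(m, mov))), 1L)
})

test_that("window preparation follows the per-modality protocols", {
  vis <- generateWhiteNoise(c(900, 4, 4), frameRate = 30, seed = 23)
  set.seed(24)
  tr <- spikeTrain(sort(runif(200, 0, 30)), 30)
  pv <- windowPairs(vis, tr)
  expect_identical(pv$windowLen, 20L)               # 20 frames at 30 Hz
  expect_identical(length(pv$starts), (nrow(pv$S) - 1L) - pv$windowLen + 1L)
  ele <- generateWhiteNoise(c(400, 4, 4), frameRate = 20,
                            modality = "electrical", seed = 25)
  tre <- spikeTrain(sort(runif(100, 0, 20)), 20)
  pe <- windowPairs(ele, tre)
  expect_equal(pe$effRate / pe$nativeRate, 12.5)    # 20 -> 250 Hz
  expect_identical(pe$windowLen, 62L)               # 5 frames ~ 250 ms
  expect_equal(nrow(pe$S), 5000)
  # up-sampled stimulus interpolates between frame values
  expect_true(all(pe$S >= 0 & pe$S <= 1))
})

test_that("evaluation correlation behaves as a similarity score", {
  set.seed(26)
  rate <- rgamma(2000, 2, 0.5)
  tr <- spikeTrain(sort(runif(3000, 0, 2000 / 30)), 2000 / 30)
  obs <- binSpikes(tr, 30, nBins = 2000)
  # a prediction equal to the observed counts scores r = 1
  expect_equal(evaluateModel(obs, tr, 30), 1)
  # affine rescaling leaves r unchanged
  r1 <- evaluateModel(rate, tr, 30)
  r2 <- evaluateModel(3 * rate + 7, tr, 30)
  expect_equal(r1, r2)
  # independent Poisson activity scores ~ 0
  expect_lt(abs(r1), 0.1)
})

test_that("five-fold splits partition the recording into equal fifths", {
  sp3 <- trainTestSplit(1000, fold = 3)
  expect_identical(sp3$train, 401:600)
  expect_identical(sp3$test, 601:800)
  sp5 <- trainTestSplit(1000, fold = 5)
  expect_identical(sp5$test, 1:200)                 # cyclic wrap
  expect_error(trainTestSplit(1000, fold = 6), "fold")
  # default protocol: contiguous 20/20/60
  sp <- trainTestSplit(1000)
  expect_identical(sp$train, 1:200)
  expect_identical(sp$test, 201:400)
})

test_that("CNN configurations default to the per-modality architectures", {
  v <- cnnConfig("visual")
  expect_identical(c(v$conv1Filters, v$conv1Size, v$conv2Filters, v$conv2Size),
                   c(8L, 13L, 16L, 9L))
  e <- cnnConfig("electrical")
  expect_identical(c(e$conv1Filters, e$conv1Size, e$conv2Filters, e$conv2Size),
                   c(16L, 5L, 32L, 5L))
})

test_that("CNN gradients match finite differences", {
  mov <- generateWhiteNoise(c(300, 6, 6), frameRate = 30, seed = 3)
  cell <- groundTruthCell(center = c(3, 3), gain = 60, frameRate = 30)
  tr <- simulateCell(cell, mov, seed = 4)
  pairs <- windowPairs(mov, tr, windowFrames = 5)
  cfg <- cnnConfig("visual", conv1Filters = 3, conv1Size = 2,
                   conv2Filters = 4, conv2Size = 2, dropout = 0,
                   epochs = 1, batchSize = 16)
  net <- retfidelity:::initCNN(cfg, pairs$dims, 1L, seed = 5)
  Xb <- retfidelity:::buildWindows(pairs, 1:16)
  yb <- pairs$targets[1:16, , drop = FALSE]
  cache <- retfidelity:::cnnForward(Xb, net$params, net$state, cfg,
                                    training = TRUE)
  grads <- retfidelity:::cnnBackward(cache, yb, net$params, net$state, cfg)
  fwd <- function(p) retfidelity:::cnnLoss(
    retfidelity:::cnnForward(Xb, p, net$state, cfg, training = TRUE)$pred,
    yb, p, cfg)
  set.seed(6)
  for (nm in names(grads)) {
    p2 <- net$params
    i <- sample(length(p2[[nm]]), 1)
    eps <- 1e-5
    p2[[nm]][i] <- p2[[nm]][i] + eps; up <- fwd(p2)
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; dn <- fwd(p2)
    expect_equal(unname(grads[[nm]][i]), (up - dn) / (2 * eps),
                 tolerance = 1e-4, label = paste("gradient of", nm))
  }
})

test_that("CNN training reduces the loss and matches LN on LN-generated data", {
  mov <- generateWhiteNoise(c(12000, 8, 8), frameRate = 30, seed = 3)
  cell <- groundTruthCell(center = c(4.5, 4.5), gain = 40, baselineRate = 0.5,
                          frameRate = 30)
  tr <- simulateCell(cell, mov, seed = 4)
  sp <- trainTestSplit(12000)
  rLN <- evaluateModel(predictRate(fitLN(mov, tr, split = sp), mov), tr, 30,
                       segment = sp$test)
  pairs <- windowPairs(mov, tr)
  cfg <- cnnConfig("visual", conv1Filters = 4, conv1Size = 5,
                   conv2Filters = 8, conv2Size = 3, epochs = 6,
                   batchSize = 64, dropout = 0.3, learningRate = 2e-3)
  trainIdx <- which(pairs$starts + pairs$windowLen <= max(sp$train))
  mdl <- buildAndTrainCNN(pairs, cfg, seed = 6, sampleIdx = trainIdx)
  expect_lt(mdl@lossHistory[length(mdl@lossHistory)], mdl@lossHistory[1])
  rCNN <- evaluateCNN(mdl, pairs, tr, segment = sp$test)
  # the CNN is a superset model of the generating LN cascade
  expect_gt(rCNN, rLN - 0.05)
})

test_that("with no regularization the CNN approaches a deterministic linear target", {
  set.seed(27)
  mov <- generateWhiteNoise(c(2000, 4, 4), frameRate = 30, seed = 28)
  w <- rnorm(5 * 16, sd = 0.3)
  pairs <- windowPairs(mov, spikeTrain(numeric(0) + 0.5, 2000 / 30),
                       windowFrames = 5)
  X <- retfidelity:::buildWindows(pairs, seq_along(pairs$starts))
  pairs$targets <- matrix(pmax(0.05, X %*% w + 2), ncol = 1)
  cfg <- cnnConfig("visual", conv1Filters = 4, conv1Size = 2,
                   conv2Filters = 4, conv2Size = 2, alpha = 0, beta = 0,
                   dropout = 0, epochs = 40, batchSize = 64,
                   learningRate = 5e-3)
  mdl <- buildAndTrainCNN(pairs, cfg, seed = 29,
                          sampleIdx = seq_len(1500))
  pred <- predictCNN(mdl, pairs, sampleIdx = 1501:1970)
  expect_gt(cor(pred[, 1], pairs$targets[1501:1970, 1]), 0.9)
})

test_that("random hyperparameter search respects bounds and trial counts", {
  mov <- generateWhiteNoise(c(1500, 6, 6), frameRate = 30, seed = 30)
  cell <- groundTruthCell(center = c(3.5, 3.5), gain = 60, frameRate = 30)
  tr <- simulateCell(cell, mov, seed = 31)
  pairs <- windowPairs(mov, tr, windowFrames = 5)
  out <- randomSearchCNN(pairs, tr, trainIdx = 1:600, testIdx = 601:1000,
                         testSegment = 700:1100, nTrials = 2, seed = 32,
                         epochs = 1)
  expect_lte(nrow(out$results), 2L)
  best <- out$best
  expect_true(best$conv1Filters >= 4 && best$conv1Filters <= 16)
  expect_true(best$learningRate >= 1e-4 && best$learningRate <= 1e-2)
  expect_true(best$dropout >= 0.1 && best$dropout <= 0.6)
  # 13 searchable hyperparameters are exposed through the bounds list
  expect_identical(length(formals(cnnConfig)) - 3L, 13L)
})
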