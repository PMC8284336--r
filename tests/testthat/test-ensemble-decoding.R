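test_that("input strength is a linear inner product with shape checking", {
  set.seed(50)
  w <- array(rnorm(24 * 16), c(24, 4, 4))
  blk <- array(runif(24 * 16), c(24, 4, 4))
  expect_identical(inputStrength(array(0, dim(w)), blk), 0)
  expect_equal(inputStrength(w, 3 * blk), 3 * inputStrength(w, blk))
  expect_error(inputStrength(w, array(0, c(24, 4, 5))), "dimensions")
  # Cauchy-Schwarz: the filter itself maximizes strength among unit blocks
  wn <- w / sqrt(sum(w^2))
  strengths <- sapply(1:20, function(i) {
    b <- array(rnorm(24 * 16), c(24, 4, 4))
    inputStrength(wn, b / sqrt(sum(b^2)))
  })
  expect_true(all(strengths <= inputStrength(wn, wn) + 1e-12))
})

test_that("block matching finds exact members and matches the exhaustive scan", {
  mov <- generateWhiteNoise(c(500, 5, 5), frameRate = 30, seed = 51)
  set.seed(52)
  w <- array(rnorm(24 * 25, sd = 0.2), c(24, 5, 5))
  # target equal to an actual block's strength: ranked first, residual 0
  blk <- stimFrames(mov)[101:124, , ]
  tgt <- inputStrength(w, blk)
  found <- findMatchingBlocks(mov, w, tgt, k = 10)
  expect_identical(found$starts[1L], 101L)
  expect_lt(found$residuals[1L], 1e-9)
  expect_true(all(diff(found$residuals) >= 0))
  # k = 1 equals the brute-force arg-min
  tgt2 <- 0.3
  oracle <- oracleBestBlock(mov, w, tgt2)
  found2 <- findMatchingBlocks(mov, w, tgt2, k = 1)
  expect_identical(found2$starts[1L], oracle$start)
  expect_equal(found2$residuals[1L], oracle$resid, tolerance = 1e-12)
  expect_error(findMatchingBlocks(mov, w, 0, k = 1000), "exceeds")
  # disjoint mode returns non-overlapping blocks
  dj <- findMatchingBlocks(mov, w, tgt2, k = 5, disjoint = TRUE)
  expect_true(all(diff(sort(dj$starts)) >= 24))
})

test_that("templates have 6 bins per cell and separate tuned orientations", {
  mov <- generateWhiteNoise(c(6000, 12, 12), frameRate = 30, seed = 53)
  # cells parked on the four gap positions of a centred letter
  mkCell <- function(id, r, c) groundTruthCell(
    cellId = id, center = c(r, c), sigmaCenter = 0.8, sigmaSurround = 1.6,
    gain = 120, baselineRate = 0.5, frameRate = 30)
  cells <- list(mkCell("n", 3.5, 6.5), mkCell("s", 9.5, 6.5),
                mkCell("w", 6.5, 3.5), mkCell("e", 6.5, 9.5))
  trains <- simulatePopulation(cells, mov, seed = 54, applyNoise = FALSE)
  kernels <- lapply(cells, cellKernel, canvas = c(12, 12))
  tpl <- buildTemplates(kernels, trains, mov, sizePx = 8, k = 100)
  expect_named(tpl, c("up", "down", "left", "right"))
  expect_identical(dim(tpl$up@rates), c(4L, 6L))
  expect_true(all(sapply(tpl, function(t) all(t@rates >= 0))))
  tv <- sapply(tpl, templateVector)
  # orientation-tuned population: templates differ across orientations
  offDiag <- cor(tv)[upper.tri(diag(4))]
  expect_true(all(offDiag < 0.999))
  # identical cells produce identical template rows
  kernels2 <- list(kernels[[1]], kernels[[1]])
  trains2 <- list(trains[[1]], trains[[1]])
  tpl2 <- buildTemplates(kernels2, trains2, mov, sizePx = 8, k = 100)
  expect_identical(tpl2$up@rates[1, ], tpl2$up@rates[2, ])
})

test_that("trial simulation is Poisson with flash additivity", {
  tpl <- new("ResponseTemplate", orientation = "up",
             rates = matrix(c(40, 0, 10, 80, 0, 20), 1), binWidth = 0.005)
  zero <- new("ResponseTemplate", orientation = "up",
              rates = matrix(0, 1, 6), binWidth = 0.005)
  expect_identical(simulateTrial(zero, 5, seed = 1), rep(0L, 6))
  set.seed(55)
  many <- replicate(4000, simulateTrial(tpl, 1))
  lam <- as.vector(t(tpl@rates)) * 0.005
  expect_lt(max(abs(rowMeans(many) - lam)), 0.03)
  expect_lt(max(abs(apply(many, 1, var) - lam)), 0.05)   # variance ~ mean
  set.seed(56)
  many8 <- replicate(1000, simulateTrial(tpl, 8))
  expect_lt(max(abs(rowMeans(many8) - 8 * lam)), 0.2)    # linear in flashes
})

test_that("template decoding picks the self-match and is scale invariant", {
  set.seed(57)
  tpls <- lapply(c("up", "down", "left", "right"), function(o)
    new("ResponseTemplate", orientation = o,
        rates = matrix(rgamma(30, 2, 0.1), 5), binWidth = 0.005))
  names(tpls) <- c("up", "down", "left", "right")
  trial <- templateVector(tpls$left)
  expect_identical(decodeTrial(trial, tpls), "left")
  scaled <- lapply(tpls, function(t)
    new("ResponseTemplate", orientation = t@orientation, rates = 7 * t@rates,
        binWidth = t@binWidth))
  expect_identical(decodeTrial(trial, scaled), "left")
})

test_that("identical templates decode at chance", {
  one <- new("ResponseTemplate", orientation = "up",
             rates = matrix(rep(30, 24), 4), binWidth = 0.005)
  tpls <- list(up = one,
               down = new("ResponseTemplate", orientation = "down",
                          rates = one@rates, binWidth = 0.005),
               left = new("ResponseTemplate", orientation = "left",
                          rates = one@rates, binWidth = 0.005),
               right = new("ResponseTemplate", orientation = "right",
                           rates = one@rates, binWidth = 0.005))
  res <- runDecodingTrials(tpls, nTrials = 2000, seed = 58)
  expect_lt(abs(accuracy(res) - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
  # true labels are drawn uniformly
  freq <- table(res@trueOrientation) / 2000
  expect_lt(max(abs(freq - 0.25)), 3 * sqrt(0.25 * 0.75 / 2000))
})

test_that("experiments scan their axis and gain accuracy with flashes", {
  mov <- generateWhiteNoise(c(6000, 12, 12), frameRate = 30, seed = 53)
  mkCell <- function(id, r, c) groundTruthCell(
    cellId = id, center = c(r, c), sigmaCenter = 0.8, sigmaSurround = 1.6,
    gain = 120, baselineRate = 0.5, frameRate = 30)
  cells <- list(mkCell("n", 3.5, 6.5), mkCell("s", 9.5, 6.5),
                mkCell("w", 6.5, 3.5), mkCell("e", 6.5, 9.5))
  trains <- simulatePopulation(cells, mov, seed = 54, applyNoise = FALSE)
  kernels <- lapply(cells, cellKernel, canvas = c(12, 12))
  out <- runExperiment(kernels, trains, mov, axis = "n_flashes",
                       grid = c(1, 8, 32), nTrials = 300, seed = 59,
                       cSizePx = 8, k = 100)
  acc <- out$summary$accuracy
  se <- sqrt(acc * (1 - acc) / 300)
  # information accumulates over presentations (within binomial error)
  expect_true(all(diff(acc) > -3 * se[-length(se)]))
  expect_gt(acc[3], acc[1])
  expect_identical(out$summary$axisValue, c(1, 8, 32))
  # the cell-count axis defaults to a 14 px letter
  expect_identical(formals(runExperiment)$cSizePx, 14)
})
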