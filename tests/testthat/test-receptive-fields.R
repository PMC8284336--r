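test_that("the STA of a fixed-pattern responder equals the pattern exactly", {
  fx <- fxPerfectResponder(nSpikes = 20)
  sta <- computeSTA(fx$train, fx$movie)
  expect_equal(staKernel(sta), fx$pattern * 1.0, tolerance = 1e-12)
  expect_identical(sta@spikeCountUsed, 20L)
})

test_that("incremental STA matches the brute-force oracle", {
  mov <- generateWhiteNoise(c(800, 5, 5), frameRate = 30, seed = 14)
  set.seed(15)
  tr <- spikeTrain(sort(runif(60, 1, 800 / 30)), 800 / 30)
  expect_equal(staKernel(computeSTA(tr, mov)), oracleSTA(tr, mov, 24),
               tolerance = 1e-12)
})

test_that("uniformly random spikes drive all kernel values toward the mean", {
  mov <- generateWhiteNoise(c(30000, 4, 4), frameRate = 30, seed = 16)
  set.seed(17)
  tr <- spikeTrain(sort(runif(4000, 1, 1000)), 1000)
  expect_lt(max(abs(staKernel(computeSTA(tr, mov)) - 0.5)), 0.05)
})

test_that("computeSTA is linear in the stimulus", {
  mov <- generateWhiteNoise(c(1200, 4, 4), frameRate = 30, seed = 18)
  scaled <- new("StimulusMovie", frames = 0.5 * stimFrames(mov) + 0.25,
                frameRate = 30, pixelPitch = 60, modality = "visual")
  set.seed(19)
  tr <- spikeTrain(sort(runif(100, 1, 40)), 40)
  expect_equal(staKernel(computeSTA(tr, scaled)),
               0.5 * staKernel(computeSTA(tr, mov)) + 0.25,
               tolerance = 1e-12)
})

test_that("first- and second-half STAs agree for a clean well-sampled cell", {
  mov <- generateWhiteNoise(c(54000, 6, 6), frameRate = 30, seed = 2)
  cell <- groundTruthCell(center = c(3.5, 3.5), sigmaCenter = 1.0,
                          sigmaSurround = 2.0, gain = 40, baselineRate = 0.5,
                          frameRate = 30)
  tr <- simulateCell(cell, mov, seed = 3)
  expect_gt(nSpikes(tr), 5000)
  st <- spikeTimes(tr)
  n <- length(st)
  s1 <- computeSTA(spikeTrain(st[1:(n %/% 2)], duration(tr)), mov)
  s2 <- computeSTA(spikeTrain(st[(n %/% 2 + 1):n], duration(tr)), mov)
  expect_gt(cor(as.vector(staKernel(s1)), as.vector(staKernel(s2))), 0.8)
})

test_that("time courses carry the cell polarity in the lobe nearest the spike", {
  fx <- fxRecovery()
  tc <- extractTimeCourse(fx$sta)
  expect_length(tc@values, 24L)
  expect_gt(tc@peakValue, 0)                       # ON ground truth
  expect_identical(classifyPolarity(tc), "ON")
  # the electrical-polarity convention inverts healthy-retina labels
  expect_identical(classifyPolarity(tc, modality = "electrical",
                                    retinaType = "LE"), "OFF")
  expect_identical(classifyPolarity(tc, modality = "electrical",
                                    retinaType = "RCS"), "ON")
  # negating the time course flips the label
  neg <- new("TimeCourse", values = -tc@values, peakValue = -tc@peakValue,
             snr = tc@snr)
  expect_identical(classifyPolarity(neg), "OFF")
  # a flat time course is unclassifiable
  flat <- new("TimeCourse", values = numeric(24), peakValue = 0, snr = 0)
  expect_identical(classifyPolarity(flat), NA_character_)
})

test_that("SNR is peak over early-lag RMS and is scale invariant", {
  v <- c(rnorm(10, 0, 0.01), rep(0, 10), 0.02, -0.2, 0.3, 0.05)
  set.seed(20)
  tc <- new("TimeCourse", values = v, peakValue = 0.3, snr = NA_real_)
  snr <- computeSNR(tc)
  expect_equal(snr, 0.3 / sqrt(mean(v[1:10]^2)))
  tc2 <- new("TimeCourse", values = 5 * v, peakValue = 1.5, snr = NA_real_)
  expect_equal(computeSNR(tc2), snr)
  zero <- new("TimeCourse", values = c(rep(0, 23), 1), peakValue = 1,
              snr = NA_real_)
  expect_identical(computeSNR(zero), Inf)
})

test_that("cell selection applies the contamination and SNR criteria with audit", {
  rec <- data.frame(cellId = c("a", "b", "c", "d"),
                    contamination = c(0.02, 0.12, 0.05, 0.01),
                    snr = c(8, 7, 2.9, 3.1))
  out <- selectCells(rec)
  expect_identical(out$records$cellId, c("a", "d"))
  expect_identical(
    out$audit$criterion[out$audit$cellId == "b" &
                        out$audit$decision == "excluded"], "contamination")
  expect_identical(
    out$audit$criterion[out$audit$cellId == "c" &
                        out$audit$decision == "excluded"], "snr")
  # idempotent
  again <- selectCells(out$records)
  expect_identical(again$records, out$records)
  # empty input, empty audit
  empty <- selectCells(rec[0, ])
  expect_identical(nrow(empty$records), 0L)
  expect_identical(nrow(empty$audit), 0L)
})

test_that("the RF ellipse fit recovers centre and width of the ground truth", {
  fx <- fxRecovery()
  fit <- fitRFEllipse(fx$sta)
  expect_lt(max(abs(fit$center - fx$cell@center)), 1)
  sigma <- sqrt(fit$sigmaMajor * fit$sigmaMinor)
  expect_lt(abs(sigma - fx$cell@sigmaCenter) / fx$cell@sigmaCenter, 0.25)
  # isotropic ground truth: near-unit axis ratio
  expect_lt(fit$sigmaMajor / fit$sigmaMinor, 1.35)
})
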