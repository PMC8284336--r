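# synthetic trace helpers: Gaussian noise + optional artifacts and spikes
makeTrace <- function(n = 40000, sd = 10, seed = 1, pulses = numeric(),
                      sr = 20000) {
  set.seed(seed)
  voltageTrace(rnorm(n, 0, sd), sampleRate = sr, pulseTimes = pulses)
}

addSpikes <- function(trace, times, amp) {
  x <- trace@samples
  # 0.5 ms biphasic spike template
  tpl <- -amp * exp(-((seq(-5, 14)) / 4)^2)
  for (tt in times) {
    i <- round(tt * trace@sampleRate)
    x[i:(i + 19)] <- x[i:(i + 19)] + tpl
  }
  voltageTrace(x, trace@sampleRate, trace@pulseTimes)
}

test_that("blanking replaces the post-pulse window with level-matched noise", {
  tr <- makeTrace(pulses = c(0.5, 1.0), seed = 2)
  # strong artifact in the blanked windows
  x <- tr@samples
  for (p in c(0.5, 1.0)) {
    i <- round(p * 20000)
    x[i:(i + 164)] <- 800
  }
  tr <- voltageTrace(x, 20000, c(0.5, 1.0))
  out <- blankArtifact(tr, blankMs = 8.25, seed = 3)
  idx <- retfidelity:::blankIndices(tr, 8.25)
  expect_lt(abs(sd(out@samples[idx]) / 10 - 1), 0.2)
  expect_identical(out@samples[-idx], tr@samples[-idx])
  expect_lt(max(abs(out@samples[idx])), 100)
})

test_that("blanking is a no-op without pulses and merges overlapping windows", {
  tr <- makeTrace(seed = 4)
  expect_identical(blankArtifact(tr)@samples, tr@samples)
  tr2 <- makeTrace(pulses = c(0.500, 0.504), seed = 5)
  expect_warning(blankArtifact(tr2), "overlap")
})

test_that("detrending removes an exact 7th-order polynomial to machine precision", {
  x <- seq(0, 1, length.out = 5000)
  poly7 <- 50 + 30 * x - 80 * x^2 + 25 * x^3 - 7 * x^4 + 90 * x^5 -
    40 * x^6 + 15 * x^7
  tr <- voltageTrace(poly7, 20000)
  out <- detrendDecay(tr, order = 7)
  expect_lt(max(abs(out@samples)), 1e-6)
})

test_that("detrending removes capacitive decay while preserving spikes", {
  base <- makeTrace(n = 30000, sd = 5, seed = 6, pulses = c(0.3, 0.9))
  decay <- numeric(30000)
  for (p in c(0.3, 0.9)) {
    i <- round(p * 20000)
    t <- seq_len(30000 - i + 1)
    decay[i:30000] <- decay[i:30000] + 400 * exp(-t / 3000)
  }
  spikeTimes <- c(0.5, 0.6, 0.7, 1.1, 1.25)
  dirty <- addSpikes(voltageTrace(base@samples + decay, 20000, c(0.3, 0.9)),
                     spikeTimes, amp = 60)
  clean <- detrendDecay(blankArtifact(dirty, seed = 7), order = 7)
  # baseline RMS (spike-free region) reduced at least 5-fold
  mask <- rep(TRUE, 30000)
  for (tt in spikeTimes) mask[round(tt * 20000) + (-40:60)] <- FALSE
  mask[retfidelity:::blankIndices(dirty, 8.25)] <- FALSE
  rmsDirty <- sqrt(mean((dirty@samples[mask] - mean(dirty@samples[mask]))^2))
  rmsClean <- sqrt(mean(clean@samples[mask]^2))
  expect_gt(rmsDirty / rmsClean, 5)
  # spike troughs preserved (template depth 60 uV, on top of sd-5 noise)
  for (tt in spikeTimes) {
    i <- round(tt * 20000) + 0:19
    expect_lt(abs(min(clean@samples[i]) + 60) / 60, 0.2)
  }
})

test_that("threshold detection recovers injected spikes and nothing on silence", {
  tr <- addSpikes(makeTrace(n = 60000, sd = 10, seed = 8),
                  times = seq(0.2, 2.8, by = 0.2), amp = 40)  # 4 x RMS
  det <- detectSpikes(tr)
  injected <- seq(0.2, 2.8, by = 0.2)
  hits <- sapply(injected, function(tt)
    any(abs(spikeTimes(det) - tt) < 0.002))
  expect_true(all(hits))                      # recall = 1
  expect_identical(nSpikes(detectSpikes(voltageTrace(numeric(1000), 20000))), 0L)
})

test_that("false positives on pure noise match the 3-sigma exceedance rate", {
  tr <- makeTrace(n = 200000, sd = 10, seed = 9)
  det <- detectSpikes(tr)
  # expected down-crossing count for iid Gaussian samples
  p <- pnorm(-3) * (1 - pnorm(-3))
  expected <- 200000 * p
  expect_gt(nSpikes(det), expected * 0.5)
  expect_lt(nSpikes(det), expected * 1.5)
})

test_that("the detection threshold scales with the noise level", {
  tr <- makeTrace(n = 50000, sd = 10, seed = 10)
  tr2 <- voltageTrace(tr@samples * 2, 20000)
  expect_equal(retfidelity:::robustRMS(tr2@samples),
               2 * retfidelity:::robustRMS(tr@samples))
  # identical spike times: the decision is scale-equivariant
  expect_identical(spikeTimes(detectSpikes(tr)), spikeTimes(detectSpikes(tr2)))
})

test_that("blank + detrend + detect are invariant to a constant offset", {
  tr <- addSpikes(makeTrace(n = 30000, sd = 10, seed = 11, pulses = 0.5),
                  times = c(0.8, 1.1), amp = 50)
  shifted <- voltageTrace(tr@samples + 250, 20000, 0.5)
  pipe <- function(v) spikeTimes(detectSpikes(detrendDecay(
    blankArtifact(v, seed = 12), order = 7)))
  expect_identical(pipe(tr), pipe(shifted))
})

test_that("contamination is zero for refractory trains and ~0.5 for 50/50 merges", {
  set.seed(13)
  mkDead <- function() {
    tt <- cumsum(rexp(8000, 20))
    tt <- tt[tt < 300]
    spikeTrain(tt[c(TRUE, diff(tt) >= 0.002)], 300)
  }
  a <- mkDead(); b <- mkDead()
  expect_identical(estimateContamination(a), 0)
  merged <- spikeTrain(sort(c(spikeTimes(a), spikeTimes(b))), 300)
  expect_lt(abs(estimateContamination(merged) - 0.5), 0.15)
  expect_identical(estimateContamination(spikeTrain(c(0.5), 1)), 0)
  # a memoryless train is indistinguishable from full contamination
  pois <- spikeTrain(sort(runif(6000, 0, 300)), 300)
  expect_gt(estimateContamination(pois), 0.8)
})
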