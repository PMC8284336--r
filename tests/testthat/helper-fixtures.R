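# Shared fixtures (memoised: several test files reuse the same simulated
# recordings) and independent brute-force oracles.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# 30-minute binary white noise on a compact 8 x 8 canvas (visual, 30 Hz)
fxMovie8 <- function() memo("movie8", function()
  generateWhiteNoise(c(54000, 8, 8), frameRate = 30, seed = 2))

# strongly driven cell for filter-recovery checks (~9300 spikes, nr = 0)
fxRecovery <- function() memo("recovery", function() {
  mov <- fxMovie8()
  cell <- groundTruthCell(cellId = "rec", center = c(4.5, 4.5), gain = 40,
                          baselineRate = 0.5, frameRate = 30)
  train <- simulateCell(cell, mov, seed = 3)
  list(movie = mov, cell = cell, train = train,
       kernel = cellKernel(cell, c(8, 8)),
       sta = computeSTA(train, mov))
})

# weaker reference cell for noise-ratio estimation (~5800 spikes)
fxReference <- function() memo("reference", function() {
  mov <- fxMovie8()
  cell <- groundTruthCell(cellId = "ref", center = c(4.5, 4.5), gain = 15,
                          baselineRate = 1.5, frameRate = 30)
  train <- simulateCell(cell, mov, seed = 8)
  list(movie = mov, cell = cell, train = train,
       cropBox = computeSTA(train, mov)@cropBox)
})

# 30-minute movie on the 16 x 16 decoding canvas
fxMovie16 <- function() memo("movie16", function()
  generateWhiteNoise(c(54000, 16, 16), frameRate = 30, seed = 11))

# dense complete mosaic with spike trains, STAs and centred kernels
fxMosaic <- function() memo("mosaic", function() {
  mov <- fxMovie16()
  cells <- buildPopulation("mosaic", canvas = c(16, 16), seed = 12)
  trains <- simulatePopulation(cells, mov, seed = 13)
  stas <- lapply(trains, computeSTA, stimulus = mov)
  list(movie = mov, cells = cells, trains = trains,
       kernels = lapply(stas, function(s) s@kernel - s@stimulusMean))
})

# MEA-sampled retinas for the cells-vs-flashes tradeoff
fxRetina <- function(nCells, nr, seed) {
  key <- sprintf("retina_%d_%g", nCells, nr)
  memo(key, function() {
    mov <- fxMovie16()
    cells <- buildPopulation("LE", canvas = c(16, 16), nCells = nCells,
                             noiseRatio = nr, seed = seed)
    trains <- simulatePopulation(cells, mov, seed = seed + 1L)
    stas <- lapply(trains, computeSTA, stimulus = mov)
    list(movie = mov, cells = cells, trains = trains,
         kernels = lapply(stas, function(s) s@kernel - s@stimulusMean))
  })
}

# a movie where every spike is preceded by one identical 24-frame pattern:
# `pattern` blocks alternate with random filler, one spike after each block
fxPerfectResponder <- function(nSpikes = 60L, depth = 24L, seed = 21L) {
  set.seed(seed)
  px <- 6L
  pattern <- array(rbinom(depth * px * px, 1L, 0.5), c(depth, px, px))
  filler <- 6L
  blockLen <- depth + filler
  Tn <- nSpikes * blockLen + filler
  frames <- array(rbinom(Tn * px * px, 1L, 0.5), c(Tn, px, px))
  fr <- 30
  spikes <- numeric(nSpikes)
  for (i in seq_len(nSpikes)) {
    start <- (i - 1L) * blockLen + filler + 1L
    frames[start:(start + depth - 1L), , ] <- pattern
    # spike lands in the frame right after the pattern block
    spikes[i] <- (start + depth - 1L + 0.5) / fr
  }
  movie <- new("StimulusMovie", frames = frames, frameRate = fr,
               pixelPitch = 60, modality = "visual")
  list(movie = movie, train = spikeTrain(spikes, Tn / fr), pattern = pattern)
}

# ---- independent oracles -------------------------------------------------

# STA by naive per-spike loops
oracleSTA <- function(train, movie, depth) {
  frames <- stimFrames(movie)
  fr <- frameRate(movie)
  acc <- array(0, c(depth, dim(frames)[2L], dim(frames)[3L]))
  n <- 0L
  for (s in spikeTimes(train)) {
    f <- floor(s * fr) + 1L
    if (f > depth && f <= dim(frames)[1L]) {
      acc <- acc + frames[(f - depth):(f - 1L), , , drop = FALSE]
      n <- n + 1L
    }
  }
  acc / n
}

# CCC by full re-averaging at every n (quadratic cost)
oracleCCC <- function(vals) {
  N <- nrow(vals)
  full <- colMeans(vals)
  vapply(seq_len(N), function(n) {
    pre <- colMeans(vals[seq_len(n), , drop = FALSE])
    suppressWarnings(stats::cor(pre, full))
  }, numeric(1L))
}

# exhaustive best-matching block scan
oracleBestBlock <- function(movie, w, target) {
  frames <- stimFrames(movie)
  depth <- dim(w)[1L]
  nBlocks <- dim(frames)[1L] - depth + 1L
  best <- 1L; bestResid <- Inf
  for (t in seq_len(nBlocks)) {
    s <- sum(w * frames[t:(t + depth - 1L), , , drop = FALSE])
    if (abs(s - target) < bestResid) { bestResid <- abs(s - target); best <- t }
  }
  list(start = best, resid = bestResid)
}
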