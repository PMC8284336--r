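#' Prepare windowed stimulus-response pairs for encoding models
#'
#' Visual recordings: each training sample is 20 consecutive frames (600 ms
#' at 30 Hz) and the target is the spike count in the 33 ms frame that
#' follows. Electrical recordings: the 20 Hz stimulus is up-sampled to 250 Hz
#' by linear interpolation (factor 12.5), windows span 5 original frames
#' (250 ms, 63 up-sampled steps) and targets are spike counts in the 4 ms bin
#' following each window, so consecutive windows tile the 50 ms after each
#' stimulus; predictions are down-sampled back to the native frame rate
#' before scoring.
#'
#' @param stimulus a \linkS4class{StimulusMovie}.
#' @param trains a \linkS4class{SpikeTrain} or list of them (one output unit
#'   per train).
#' @param windowFrames stimulus frames per window at the native rate
#'   (default 20 visual, 5 electrical).
#' @param upsampleHz target rate for electrical up-sampling (default 250).
#' @return List with the effective-rate stimulus matrix \code{S}, window
#'   start indices \code{starts}, targets matrix (windows x cells),
#'   \code{windowLen}, input dimensions \code{dims = c(channels, H, W)},
#'   effective rate \code{effRate}, native rate, modality and the
#'   down-sampling factor.
#' @export
windowPairs <- function(stimulus, trains, windowFrames = NULL,
                        upsampleHz = 250) {
  if (methods::is(trains, "SpikeTrain")) trains <- list(trains)
  frames <- stimFrames(stimulus)
  d <- dim(frames)
  fr <- frameRate(stimulus)
  mod <- modality(stimulus)
  if (is.null(windowFrames)) windowFrames <- if (mod == "visual") 20L else 5L
  S <- flattenFrames(frames)
  if (mod == "electrical") {
    factor <- upsampleHz / fr
    tOrig <- (seq_len(d[1L]) - 0.5) / fr
    nUp <- floor(d[1L] * factor)
    tUp <- (seq_len(nUp) - 0.5) / upsampleHz
    S <- apply(S, 2L, function(col)
      stats::approx(tOrig, col, xout = tUp, rule = 2)$y)
    effRate <- upsampleHz
    windowLen <- as.integer(round(windowFrames * factor))
  } else {
    factor <- 1
    effRate <- fr
    windowLen <- as.integer(windowFrames)
  }
  nEff <- nrow(S)
  starts <- seq_len(nEff - windowLen)
  targets <- vapply(trains, function(tr) {
    counts <- binSpikes(tr, effRate, nBins = nEff)
    counts[starts + windowLen]
  }, numeric(length(starts)))
  targets <- matrix(targets, nrow = length(starts))
  colnames(targets) <- vapply(trains, cellId, character(1L))
  list(S = S, starts = starts, targets = targets, windowLen = windowLen,
       dims = c(windowLen, d[2L], d[3L]), effRate = effRate,
       nativeRate = fr, modality = mod, downFactor = factor)
}

#' CNN hyperparameter configuration
#'
#' Thirteen searchable hyperparameters: per-block filter count, filter size,
#' stride and PReLU initial slope; learning rate; L2 coefficient alpha
#' (weights); L1 coefficient beta (output); batch size; dropout probability.
#' Defaults follow the per-modality architectures: visual 8 filters of
#' 13 x 13 then 16 of 9 x 9; electrical 16 of 5 x 5 then 32 of 5 x 5.
#'
#' @param modality "visual" or "electrical" (sets the default architecture).
#' @param conv1Filters,conv1Size,conv1Stride,conv1Slope block-1 parameters.
#' @param conv2Filters,conv2Size,conv2Stride,conv2Slope block-2 parameters.
#' @param learningRate Adam step size.
#' @param alpha L2 weight-regularization coefficient.
#' @param beta L1 output-regularization coefficient.
#' @param batchSize minibatch size.
#' @param dropout dropout probability.
#' @param epochs training epochs.
#' @param bnMomentum batch-normalization running-average momentum.
#' @return Named list of hyperparameters.
#' @export
cnnConfig <- function(modality = c("visual", "electrical"),
                      conv1Filters = NULL, conv1Size = NULL,
                      conv1Stride = 1L, conv1Slope = 0.25,
                      conv2Filters = NULL, conv2Size = NULL,
                      conv2Stride = 1L, conv2Slope = 0.25,
                      learningRate = 1e-3, alpha = 1e-4, beta = 1e-5,
                      batchSize = 64L, dropout = 0.5, epochs = 10L,
                      bnMomentum = 0.5) {
  modality <- match.arg(modality)
  if (is.null(conv1Filters)) conv1Filters <- if (modality == "visual") 8L else 16L
  if (is.null(conv1Size))    conv1Size    <- if (modality == "visual") 13L else 5L
  if (is.null(conv2Filters)) conv2Filters <- if (modality == "visual") 16L else 32L
  if (is.null(conv2Size))    conv2Size    <- if (modality == "visual") 9L else 5L
  list(modality = modality,
       conv1Filters = as.integer(conv1Filters), conv1Size = as.integer(conv1Size),
       conv1Stride = as.integer(conv1Stride), conv1Slope = conv1Slope,
       conv2Filters = as.integer(conv2Filters), conv2Size = as.integer(conv2Size),
       conv2Stride = as.integer(conv2Stride), conv2Slope = conv2Slope,
       learningRate = learningRate, alpha = alpha, beta = beta,
       batchSize = as.integer(batchSize), dropout = dropout,
       epochs = as.integer(epochs), bnMomentum = bnMomentum)
}

# index map for im2col: (k*k*C) x (Ho*Wo) matrix of sample-vector indices.
# sample vectors are channel blocks of column-major H x W images.
im2colMap <- function(C, H, W, k, stride) {
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) stop("filter larger than its input")
  patch <- as.vector(vapply(seq_len(C), function(c)
    as.vector(outer(seq_len(k), seq_len(k),
                    function(i, j) (c - 1L) * H * W + (j - 1L) * H + i)),
    numeric(k * k)))
  offs <- as.vector(outer(seq_len(Ho), seq_len(Wo), function(io, jo)
    ((jo - 1L) * stride) * H + (io - 1L) * stride))
  idx <- outer(patch, offs, `+`)
  list(idx = idx, Ho = Ho, Wo = Wo)
}

# expand batch (n x CHW) to patches ((n*P) x k^2C); row order: sample fastest
im2col <- function(Xb, map) {
  n <- nrow(Xb)
  K <- nrow(map$idx); P <- ncol(map$idx)
  M <- Xb[, as.vector(map$idx), drop = FALSE]        # n x (K*P)
  dim(M) <- c(n, K, P)
  M <- aperm(M, c(1L, 3L, 2L))                       # n, P, K
  dim(M) <- c(n * P, K)
  M
}

# scatter patch gradients back to the input layout (transpose of im2col)
col2im <- function(dZ, map, n, inLen) {
  K <- nrow(map$idx); P <- ncol(map$idx)
  dim(dZ) <- c(n, P, K)
  dM <- aperm(dZ, c(1L, 3L, 2L))                     # n, K, P
  dim(dM) <- c(n, K * P)
  grp <- as.vector(map$idx)
  agg <- rowsum(t(dM), group = grp)                  # unique-idx x n
  dX <- matrix(0, n, inLen)
  dX[, as.integer(rownames(agg))] <- t(agg)
  dX
}

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

initCNN <- function(config, inputDim, nCells, seed) {
  set.seed(as.integer(seed))
  C <- inputDim[1L]; H <- inputDim[2L]; W <- inputDim[3L]
  m1 <- im2colMap(C, H, W, config$conv1Size, config$conv1Stride)
  m2 <- im2colMap(config$conv1Filters, m1$Ho, m1$Wo,
                  config$conv2Size, config$conv2Stride)
  he <- function(fanIn, nOut) matrix(stats::rnorm(fanIn * nOut,
                                                  sd = sqrt(2 / fanIn)),
                                     fanIn, nOut)
  K1 <- config$conv1Size^2 * C
  K2 <- config$conv2Size^2 * config$conv1Filters
  D <- config$conv2Filters * m2$Ho * m2$Wo
  params <- list(
    W1 = he(K1, config$conv1Filters), b1 = numeric(config$conv1Filters),
    a1 = rep(config$conv1Slope, config$conv1Filters),
    g1 = rep(1, config$conv1Filters), be1 = numeric(config$conv1Filters),
    W2 = he(K2, config$conv2Filters), b2 = numeric(config$conv2Filters),
    a2 = rep(config$conv2Slope, config$conv2Filters),
    g2 = rep(1, config$conv2Filters), be2 = numeric(config$conv2Filters),
    W3 = he(D, nCells) * 0.1, b3 = numeric(nCells))
  state <- list(
    maps = list(m1, m2),
    run1 = list(mean = numeric(config$conv1Filters),
                var = rep(1, config$conv1Filters)),
    run2 = list(mean = numeric(config$conv2Filters),
                var = rep(1, config$conv2Filters)))
  list(params = params, state = state)
}

# forward pass; training mode uses batch statistics and dropout
cnnForward <- function(Xb, params, state, config, training = FALSE,
                       dropMask = NULL) {
  n <- nrow(Xb)
  eps <- 1e-5
  cache <- list(n = n)
  blocks <- list(
    list(W = "W1", b = "b1", a = "a1", g = "g1", be = "be1", run = "run1",
         map = 1L),
    list(W = "W2", b = "b2", a = "a2", g = "g2", be = "be2", run = "run2",
         map = 2L))
  X <- Xb
  for (bi in 1:2) {
    bl <- blocks[[bi]]
    map <- state$maps[[bl$map]]
    Z <- im2col(X, map)
    conv <- sweep(Z %*% params[[bl$W]], 2L, params[[bl$b]], `+`)
    # PReLU
    pos <- conv > 0
    act <- conv
    act[!pos] <- sweep(conv, 2L, params[[bl$a]], `*`)[!pos]
    # batch normalization per channel
    if (training) {
      mu <- colMeans(act)
      vr <- colMeans(sweep(act, 2L, mu)^2)
    } else {
      mu <- state[[bl$run]]$mean
      vr <- state[[bl$run]]$var
    }
    xhat <- sweep(sweep(act, 2L, mu), 2L, sqrt(vr + eps), `/`)
    bn <- sweep(sweep(xhat, 2L, params[[bl$g]], `*`), 2L, params[[bl$be]], `+`)
    if (training && config$dropout > 0) {
      mask <- if (is.null(dropMask)) {
        matrix(stats::rbinom(length(bn), 1L, 1 - config$dropout),
               nrow(bn), ncol(bn)) / (1 - config$dropout)
      } else dropMask[[bi]]
      out <- bn * mask
    } else {
      mask <- NULL
      out <- bn
    }
    cache[[paste0("blk", bi)]] <- list(X = X, Z = Z, conv = conv, pos = pos,
                                       act = act, mu = mu, vr = vr,
                                       xhat = xhat, mask = mask, map = map)
    P <- map$Ho * map$Wo
    Fc <- ncol(out)
    dim(out) <- c(n, P, Fc)
    dim(out) <- c(n, P * Fc)
    X <- out
  }
  z <- sweep(X %*% params$W3, 2L, params$b3, `+`)
  cache$flat <- X
  cache$z <- z
  cache$pred <- softplus(z)
  cache
}

cnnLoss <- function(pred, targets, params, config) {
  N <- length(pred)
  eps <- 1e-8
  nll <- mean(pred - targets * log(pred + eps))
  l2 <- config$alpha / 2 * (sum(params$W1^2) + sum(params$W2^2) +
                            sum(params$W3^2))
  l1 <- config$beta * mean(abs(pred))
  nll + l2 + l1
}

cnnBackward <- function(cache, targets, params, state, config) {
  n <- cache$n
  eps <- 1e-8
  N <- length(cache$pred)
  dPred <- (1 - targets / (cache$pred + eps)) / N + config$beta / N
  dZfin <- dPred * stats::plogis(cache$z)            # softplus'
  grads <- list(
    W3 = crossprod(cache$flat, dZfin) + config$alpha * params$W3,
    b3 = colSums(dZfin))
  dX <- tcrossprod(dZfin, params$W3)                 # n x (P*F)
  for (bi in 2:1) {
    bl <- cache[[paste0("blk", bi)]]
    map <- bl$map
    P <- map$Ho * map$Wo
    Fc <- length(bl$mu)
    dim(dX) <- c(n, P, Fc)
    dim(dX) <- c(n * P, Fc)
    dOut <- dX
    if (!is.null(bl$mask)) dOut <- dOut * bl$mask
    # batchnorm backward
    m <- nrow(dOut)
    dXhat <- sweep(dOut, 2L, params[[paste0("g", bi)]], `*`)
    gG <- colSums(dOut * bl$xhat)
    gBe <- colSums(dOut)
    inv <- 1 / sqrt(bl$vr + 1e-5)
    dAct <- sweep(dXhat - matrix(colMeans(dXhat), m, Fc, byrow = TRUE) -
                    sweep(bl$xhat, 2L, colMeans(dXhat * bl$xhat), `*`),
                  2L, inv, `*`)
    # PReLU backward
    neg <- !bl$pos
    gA <- colSums((dAct * bl$conv) * neg)
    dConv <- dAct
    dConv[neg] <- sweep(dAct, 2L, params[[paste0("a", bi)]], `*`)[neg]
    # conv backward
    gW <- crossprod(bl$Z, dConv) + config$alpha * params[[paste0("W", bi)]]
    gB <- colSums(dConv)
    grads[[paste0("W", bi)]] <- gW
    grads[[paste0("b", bi)]] <- gB
    grads[[paste0("a", bi)]] <- gA
    grads[[paste0("g", bi)]] <- gG
    grads[[paste0("be", bi)]] <- gBe
    if (bi == 2L) {
      dZ <- tcrossprod(dConv, params$W2)
      dX <- col2im(dZ, map, n, ncol(bl$X))
    }
  }
  grads
}

#' Build and train the convolutional encoding model
#'
#' Two blocks of [2-D convolution -> parametric ReLU -> batch normalization
#' -> dropout], flattened into a dense layer with one output unit per cell
#' and a softplus rectification so predicted rates are positive. Trained
#' with the Adam optimizer on the Poisson negative log-likelihood
#' mean(pred - obs * log pred) plus (alpha/2) * sum of squared Frobenius
#' norms of the weight matrices and (beta/N) * sum |pred|.
#'
#' @param pairs windowed stimulus-response pairs from \code{\link{windowPairs}}.
#' @param config a \code{\link{cnnConfig}}.
#' @param seed integer seed (initialization, shuffling, dropout).
#' @param sampleIdx indices into \code{pairs$starts} to train on (default all).
#' @param verbose print per-epoch loss.
#' @return A \linkS4class{CNNModel}.
#' @export
buildAndTrainCNN <- function(pairs, config = NULL, seed = 1L,
                             sampleIdx = NULL, verbose = FALSE) {
  if (is.null(config)) config <- cnnConfig(pairs$modality)
  if (is.null(sampleIdx)) sampleIdx <- seq_along(pairs$starts)
  nCells <- ncol(pairs$targets)
  net <- initCNN(config, pairs$dims, nCells, seed)
  params <- net$params
  state <- net$state
  adam <- list(m = lapply(params, function(p) p * 0),
               v = lapply(params, function(p) p * 0), t = 0L)
  lr <- config$learningRate
  lossHist <- numeric(config$epochs)
  mom <- config$bnMomentum
  for (ep in seq_len(config$epochs)) {
    ord <- sample(sampleIdx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epLoss <- 0
    for (bt in batches) {
      if (length(bt) < 2L) next
      Xb <- buildWindows(pairs, bt)
      yb <- pairs$targets[bt, , drop = FALSE]
      cache <- cnnForward(Xb, params, state, config, training = TRUE)
      loss <- cnnLoss(cache$pred, yb, params, config)
      if (!is.finite(loss))
        stop("CNN training diverged (non-finite loss); lower the learning rate")
      epLoss <- epLoss + loss * length(bt)
      # update batchnorm running statistics
      for (bi in 1:2) {
        bl <- cache[[paste0("blk", bi)]]
        rn <- paste0("run", bi)
        state[[rn]]$mean <- mom * state[[rn]]$mean + (1 - mom) * bl$mu
        state[[rn]]$var <- mom * state[[rn]]$var + (1 - mom) * bl$vr
      }
      grads <- cnnBackward(cache, yb, params, state, config)
      adam$t <- adam$t + 1L
      for (nm in names(grads)) {
        g <- grads[[nm]]
        adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * g
        adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * g^2
        mhat <- adam$m[[nm]] / (1 - 0.9^adam$t)
        vhat <- adam$v[[nm]] / (1 - 0.999^adam$t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    lossHist[ep] <- epLoss / length(ord)
    if (verbose) message(sprintf("epoch %d: loss %.5f", ep, lossHist[ep]))
  }
  new("CNNModel", config = config, params = c(params, list(state = state)),
      lossHistory = lossHist, inputDim = as.integer(pairs$dims),
      nCells = as.integer(nCells))
}

# assemble the (n x C*H*W) input matrix for a set of window indices
buildWindows <- function(pairs, idx) {
  L <- pairs$windowLen
  out <- matrix(0, length(idx), L * ncol(pairs$S))
  for (i in seq_along(idx)) {
    t0 <- pairs$starts[idx[i]]
    out[i, ] <- as.vector(t(pairs$S[t0:(t0 + L - 1L), , drop = FALSE]))
  }
  out
}

#' Predict rates from a trained CNN
#'
#' Evaluation-mode forward pass (running batchnorm statistics, no dropout).
#'
#' @param model a \linkS4class{CNNModel}.
#' @param pairs windowed pairs from \code{\link{windowPairs}}.
#' @param sampleIdx window indices to predict (default all).
#' @param batchSize evaluation batch size.
#' @return Matrix (windows x cells) of predicted per-bin spike counts.
#' @export
predictCNN <- function(model, pairs, sampleIdx = NULL, batchSize = 512L) {
  if (is.null(sampleIdx)) sampleIdx <- seq_along(pairs$starts)
  params <- model@params
  state <- params$state
  params$state <- NULL
  out <- matrix(0, length(sampleIdx), model@nCells)
  splits <- split(seq_along(sampleIdx),
                  ceiling(seq_along(sampleIdx) / batchSize))
  for (sp in splits) {
    Xb <- buildWindows(pairs, sampleIdx[sp])
    cache <- cnnForward(Xb, params, state, model@config, training = FALSE)
    out[sp, ] <- cache$pred
  }
  out
}

#' Score a CNN on a held-out segment
#'
#' Predictions are placed on the effective-rate grid at each window's target
#' bin, down-sampled to the native frame rate for electrical recordings, and
#' correlated with the observed spike counts after Gaussian broadening.
#'
#' @param model a \linkS4class{CNNModel}.
#' @param pairs windowed pairs from \code{\link{windowPairs}}.
#' @param train the observed \linkS4class{SpikeTrain} (first cell by default).
#' @param segment native-rate frame indices to score.
#' @param cell output-unit index.
#' @param sigmaFrames Gaussian broadening SD in native frames.
#' @return Pearson r.
#' @export
evaluateCNN <- function(model, pairs, train, segment = NULL, cell = 1L,
                        sigmaFrames = 2) {
  pred <- predictCNN(model, pairs)[, cell]
  nEff <- nrow(pairs$S)
  trace <- rep(NA_real_, nEff)
  trace[pairs$starts + pairs$windowLen] <- pred
  trace[is.na(trace)] <- mean(pred)
  if (pairs$modality == "electrical") {
    # average the up-sampled bins covering each native frame
    frameOf <- floor(((seq_len(nEff) - 0.5) / pairs$effRate) *
                       pairs$nativeRate) + 1L
    nFr <- max(frameOf)
    native <- as.numeric(rowsum(trace, frameOf) / tabulate(frameOf, nFr))
    rateScale <- pairs$effRate
  } else {
    native <- trace
    rateScale <- pairs$nativeRate
  }
  evaluateModel(native * rateScale, train, pairs$nativeRate,
                segment = segment, sigmaFrames = sigmaFrames)
}

#' Random search over CNN hyperparameters
#'
#' Samples configurations uniformly within declared bounds for the 13
#' searchable hyperparameters, trains each on the training windows and ranks
#' them by Pearson r on the test windows. A small number of trials keeps the
#' search at desk scale.
#'
#' @param pairs windowed pairs from \code{\link{windowPairs}}.
#' @param train observed \linkS4class{SpikeTrain} for scoring.
#' @param trainIdx,testIdx window indices for training and scoring.
#' @param testSegment native-rate frames used for scoring.
#' @param nTrials number of sampled configurations (default 10).
#' @param seed integer seed.
#' @param bounds named list overriding default search bounds.
#' @param epochs training epochs per trial.
#' @return List with \code{best} (a \code{\link{cnnConfig}}), \code{bestR} and
#'   a \code{results} data.frame.
#' @export
randomSearchCNN <- function(pairs, train, trainIdx, testIdx,
                            testSegment = NULL, nTrials = 10L, seed = 1L,
                            bounds = list(), epochs = 3L) {
  H <- pairs$dims[2L]; W <- pairs$dims[3L]
  maxK <- max(2L, min(H, W) - 1L)
  def <- list(conv1Filters = c(4L, 16L), conv1Size = c(2L, min(maxK, 13L)),
              conv1Stride = c(1L, 2L), conv1Slope = c(0.1, 0.5),
              conv2Filters = c(4L, 32L), conv2Size = c(2L, min(maxK, 9L)),
              conv2Stride = c(1L, 1L), conv2Slope = c(0.1, 0.5),
              learningRate = c(1e-4, 1e-2), alpha = c(1e-6, 1e-3),
              beta = c(1e-7, 1e-4), batchSize = c(32L, 128L),
              dropout = c(0.1, 0.6))
  def[names(bounds)] <- bounds
  set.seed(as.integer(seed))
  results <- NULL
  best <- NULL; bestR <- -Inf
  for (tr in seq_len(nTrials)) {
    sInt <- function(b) as.integer(round(stats::runif(1, b[1L], b[2L])))
    sLog <- function(b) exp(stats::runif(1, log(b[1L]), log(b[2L])))
    cfg <- NULL
    for (attempt in 1:25) {
      cfg <- tryCatch({
      cfg <- cnnConfig(pairs$modality,
        conv1Filters = sInt(def$conv1Filters), conv1Size = sInt(def$conv1Size),
        conv1Stride = sInt(def$conv1Stride),
        conv1Slope = stats::runif(1, def$conv1Slope[1], def$conv1Slope[2]),
        conv2Filters = sInt(def$conv2Filters), conv2Size = sInt(def$conv2Size),
        conv2Stride = sInt(def$conv2Stride),
        conv2Slope = stats::runif(1, def$conv2Slope[1], def$conv2Slope[2]),
        learningRate = sLog(def$learningRate), alpha = sLog(def$alpha),
        beta = sLog(def$beta), batchSize = sInt(def$batchSize),
        dropout = stats::runif(1, def$dropout[1], def$dropout[2]),
        epochs = epochs)
      # reject configurations whose second block does not fit
      m1 <- im2colMap(pairs$dims[1L], H, W, cfg$conv1Size, cfg$conv1Stride)
      im2colMap(cfg$conv1Filters, m1$Ho, m1$Wo, cfg$conv2Size,
                cfg$conv2Stride)
      cfg
      }, error = function(e) NULL)
      if (!is.null(cfg)) break
    }
    if (is.null(cfg)) next
    fitSeed <- subSeed(seed, paste0("trial", tr))
    r <- tryCatch({
      mdl <- buildAndTrainCNN(pairs, cfg, seed = fitSeed,
                              sampleIdx = trainIdx)
      evaluateCNN(mdl, pairs, train, segment = testSegment)
    }, error = function(e) NA_real_)
    results <- rbind(results, data.frame(trial = tr, r = r,
                                         lr = cfg$learningRate,
                                         f1 = cfg$conv1Filters,
                                         k1 = cfg$conv1Size,
                                         f2 = cfg$conv2Filters,
                                         k2 = cfg$conv2Size))
    if (is.finite(r) && r > bestR) { bestR <- r; best <- cfg }
  }
  list(best = best, bestR = bestR, results = results)
}
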