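# retfidelity

Tools for quantifying the fidelity of retinal ganglion cell (RGC)
responses to patterned stimulation — natural (visual) or prosthetic
(subretinal electrical) — and for asking how much of that fidelity matters
for what a downstream observer can decode.

Subretinal photovoltaic implants let blind patients recognize letters, but
more slowly than healthy subjects viewing equally pixelated images. Three
quantitative questions frame the analysis this package implements:

1. **How predictable is each cell?** Every cell is fitted with a
   linear–nonlinear (LN) cascade, `R(s) = N(w · s)`, where the filter `w`
   is the spike-triggered average (STA) under binary white noise, and with
   a two-block convolutional network trained on a Poisson log-likelihood
   with L2 weight and L1 output penalties. Models are scored by Pearson
   correlation between Gaussian-broadened (σ = 2 frames) predicted and
   observed spike trains on a held-out 20% of the recording.
2. **How much of a cell's firing is effectively random?** The
   characteristic correlation curve `CCC(n/N) = Corr(STA(1), STA(n/N))`
   compares growing-subset STAs with the full-spike STA on a
   3 px × 3 px × 4-frame crop around the STA peak. Its area under the curve
   (AUC) is 1 for a perfectly reliable cell and `∫√x dx = 2/3` for purely
   random spiking. Replacing a known fraction (the *noise ratio*, NR) of a
   reference cell's spikes with Poisson-timed spikes builds a family of
   curves; matching a cell's AUC into that family estimates its NR.
3. **What can the population decode?** Per-orientation response templates
   for a pixelated Landolt-C (ring with a gap of 1/5 its diameter) are
   assembled from each cell's 500 white-noise blocks best matching the
   letter's filter drive `w · ŝ`; Poisson trials are decoded by arg-max
   template correlation, yielding accuracy as a function of cell count,
   letter size, and number of stimulus presentations.

Since the underlying recordings are not publicly deposited, the package
includes a ground-truth synthetic retina (LN–Poisson cells on jittered
mosaics, with controllable noise ratios and presets matching the healthy
and degenerate study populations) so that every estimator is validated by
parameter recovery. A preprocessing module (artifact blanking, polynomial
detrending, 3×RMS spike detection, refractory-violation contamination
estimates) covers the raw-trace stage on synthetic 20 kHz traces.

## Worked example

```r
library(retfidelity)

# 30 minutes of binary white noise on a compact canvas
movie <- generateWhiteNoise(c(54000, 8, 8), frameRate = 30, seed = 2)

# a ground-truth ON cell, then its recording
cell  <- groundTruthCell(center = c(4.5, 4.5), gain = 40,
                         baselineRate = 0.5, frameRate = 30)
train <- simulateCell(cell, movie, seed = 3)
train
#> SpikeTrain 'cell': 9302 spikes over 1800.0 s (5.17 Hz)

# receptive field recovery
sta <- computeSTA(train, movie)
cor(as.vector(staKernel(sta)) - 0.5,
    as.vector(cellKernel(cell, c(8, 8))))
#> [1] 0.9310
extractTimeCourse(sta)@snr
#> [1] 20.35

# noise-ratio estimation: inject 50% random spikes, then recover it
fam <- buildNoiseFamily(train, movie, nrGrid = seq(0, 1, 0.1), nSeeds = 3)
noisy <- injectNoise(train, nr = 0.5, seed = 7)
cc <- computeCCC(noisy, movie, cropBox = cropBox(sta))
matchNoiseRatio(cc, fam)
#> [1] 0.5361
```

The recovered filter correlates 0.93 with the generating kernel, the
time-course SNR (20.4) sails past the ≥3 inclusion criterion, and a cell
whose spikes were half replaced by random timing is assigned a noise ratio
of 0.54 — parameter recovery within the ±0.1 band the estimator is
validated to.

An end-to-end run (stimulus → population → STAs → model fits → noise
estimates → decoding) with CSV artifacts and a JSON manifest:

```r
manifest <- runPipeline(defaultConfig(), outDir = "out/demo", seed = 1)
reportPipeline(manifest)
```

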