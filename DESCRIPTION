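Package: retfidelity
Title: Fidelity of Retinal Ganglion Cell Responses to Visual and Subretinal Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how faithfully retinal ganglion cells (RGCs)
    encode patterned stimulation, built around white-noise receptive-field
    analysis. Provides a ground-truth synthetic retina (linear-nonlinear
    Poisson cells with controllable spontaneous-spike contamination), raw-trace
    preprocessing for stimulation artifacts (blanking, polynomial detrending,
    threshold spike detection, refractory-violation contamination estimates),
    spike-triggered average (STA) receptive-field estimation with SNR and
    ON/OFF polarity classification, linear-nonlinear and convolutional
    neural-network encoding models with Poisson-likelihood training, a
    noise-ratio estimator based on characteristic correlation curves of
    growing-subset STAs, and a population template decoder for Landolt-C
    orientation discrimination under varying cell counts, letter sizes and
    presentation counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'encoding_cnn.R'
    'encoding_ln.R'
    'ensemble_decoding.R'
    'io.R'
    'noise_estimation.R'
    'pipeline.R'
    'preprocess.R'
    'receptive_fields.R'
    'stimuli.R'
    'synthetic_retina.R'
    'utils.R'
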