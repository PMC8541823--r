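Package: synaptoquant
Title: Quantification Toolkit for Synaptic Physiology and Neurogenetics at the
    Drosophila Neuromuscular Junction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative procedures for studies of synaptic vesicle
    acidification and transmission at the Drosophila larval neuromuscular
    junction. Implements quantal analysis of miniature excitatory postsynaptic
    potential (mEPSP) amplitude histograms via a binomial x Gaussian
    convolution model with maximum-likelihood fitting; peristaltic-wave
    counting and stride metrics from larval tracker output using
    Savitzky-Golay smoothing and prominence-based peak detection;
    fixed-threshold area-fraction and masked-intensity ratio quantification
    for pHluorin quench/collapse and FM-dye load/unload imaging; label-free
    co-immunoprecipitation enrichment calling (TOP3 abundance, replicate
    presence filtering, minimum-abundance imputation, per-experiment log2
    ratios); and Mendelian progeny-class expectations for crosses with
    balancer lethality and conditional transgene rescue. Synthetic-data
    generators with recorded ground truth make every stage testable without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
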