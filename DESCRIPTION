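Package: ntmetrics
Title: Quantitative Analysis of Engineered Neuromuscular Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable quantification pipeline for engineered skeletal muscle
    and neuromuscular junction (NMJ) experiments. Computes muscle-structure
    metrics from calibrated fluorescence fields of view (nuclei density,
    myogenic index, myotube width, sarcomere index from a radially collapsed
    2D FFT power spectrum, sarcomere length), converts muscular thin film
    (MTF) top-view videos to contractile stress via film curvature and a
    Stoney-type plate equation, scores pre/postsynaptic co-localization of
    synapsin and alpha-bungarotoxin at NMJs, detects and characterizes
    miniature excitatory postsynaptic potentials (mEPSPs) in intracellular
    voltage traces, and runs a bulk-transcriptomics stage (FPKM-UQ
    normalization, gene-specific differential expression, PCA with per-gene
    component loadings, hierarchical heatmap ordering). Every input modality
    has a matching synthetic-data generator that emits machine-readable
    ground truth, so each stage is verifiable by parameter recovery without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    signal,
    pracma,
    jsonlite,
    tiff,
    car,
    withr,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
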