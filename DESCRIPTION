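Package: icdim
Title: Automatic Selection of the Number of Independent Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for choosing the number of components to extract in an
    independent component analysis (ICA) of multichannel signals such as
    scalp EEG.  The core estimator splits the channels into two blocks,
    decomposes each block separately over a range of candidate dimensions,
    and scores every candidate by the smallest column-wise maximum absolute
    Spearman correlation between the two blocks' components; the dimension
    preceding the largest drop in that score, voted over repeated random
    splits, is reported as the optimal number of components.  Comparator
    selectors (Durbin-Watson residual criterion, known-source correlation,
    ICA-by-Blocks), an EEG-like source simulator with a Gaussian mixing
    model, and a benchmarking harness for accuracy and robustness
    experiments are included.  FastICA, Infomax and JADE decompositions are
    provided through the 'ica' package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ica,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
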