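Package: contactens
Title: Ensembling and Evaluation of Protein Residue-Residue Contact
    Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for converting predicted inter-residue distance
    distributions (distograms) into contact probabilities at the 8 Angstrom
    threshold, averaging contact probabilities across heterogeneous
    prediction methods, selecting the top-L most probable contacts per
    sequence-separation class, deriving ground-truth contact labels from
    experimental structures (including NMR model ensembles), and scoring
    predictions with ceiling-normalized top-L precision and Jaccard
    distances between contact sets. Includes CASP RR format readers and
    writers and a synthetic benchmark generator producing folded toy chains
    and families of noisy distance predictors with tunable accuracy and
    inter-predictor error correlation.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
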