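Package: nucstruct
Title: Nucleosome Positioning and Occupancy from DNA Structural Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts genomic DNA into smoothed physicochemical structural
    profiles using twelve published dinucleotide and trinucleotide property
    scales (propeller twist, DNA denaturation, bending stiffness, stacking
    energy, Z-DNA transition energy and others), and predicts nucleosome
    organization from them. Discrete nucleosome positions are located by an
    adaptive peak/valley detector with steric exclusion, by a Random-Forest
    meta-predictor that integrates per-feature call sets, and by a 16-state
    hidden Markov model decoded with the Viterbi algorithm. Continuous
    nucleosome occupancy is predicted with a least angle regression linear
    model over the twelve profiles. Includes interval-matching evaluation
    (sensitivity, specificity, F-measure) against reference nucleosome maps,
    a matched random baseline, and a synthetic-genome simulator with planted
    nucleosomes for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
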