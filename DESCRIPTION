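Package: fragmentoscope
Title: Cell-Free DNA Fragmentomics and Library-Preparation Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of cell-free DNA (cfDNA) fragmentation patterns from
    aligned fragment intervals: fragment-length spectra with sub-nucleosomal
    sawtooth periodicity estimation, terminal base-composition profiles,
    weak/strong dinucleotide oscillation profiles around fragment midpoints
    and termini, window protection scores (WPS) with median normalization and
    Savitzky-Golay smoothing, region-averaged nucleosome footprints, and
    synthetic-oligonucleotide purity and overhang-coverage quality control.
    Includes a synthetic-data generator that emulates nucleosome-protected
    duplex cfDNA templates, transcription-factor footprint loci, and oligo
    pools with synthesis truncations, together with in-silico native-end and
    end-polished library preparation, so that every analysis stage can be
    verified against constructions with known ground truth.
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
    methods,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
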