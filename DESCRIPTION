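Package: bali
Title: Design, Simulation and Decoding of Light-Directed Combinatorial
    Spatial Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for light-driven combinatorial spatial barcoding of
    biomolecules in tissue sections. Builds base-i / N-digit barcode
    dictionaries with alternating 6/7-nt ligation overhangs, compiles
    per-digit illumination schedules and photomasks from segmented region
    maps, simulates the uncaging/ligation chemistry down to synthetic
    paired-end sequencing reads, decodes reads back to spatial regions with
    overhang-parity-aware handling of partial barcodes, and recovers
    per-cycle ligation efficiencies from observed barcode spectra by
    maximum likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    Matrix,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
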