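Package: symbiotrans
Title: Transport Function Analysis for Reduced-Genome Endosymbionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the transport function of obligate intracellular
    bacteria such as Buchnera aphidicola. Provides a qualitative
    metabolic-network data model with side-compound filtering and compound-graph
    topology, identification of network input and output (boundary) compounds,
    enumeration of all minimal precursor sets of a target metabolite by forward
    closure, a machine-readable four-strain transporter repertoire with
    gene/system counting, confidence tiers, conserved-core extraction and
    lifestyle-group comparative statistics (two-sample Kolmogorov-Smirnov,
    linear fits), assignment of candidate transporters to boundary compounds
    with membrane-coverage orphan reporting, line-profile membrane counting for
    transmission electron micrographs (FFT bandpass, ROI column averaging,
    trough detection), ratiometric fluorescence uniformity checks, and seeded
    synthetic-data generators with ground-truth manifests for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
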