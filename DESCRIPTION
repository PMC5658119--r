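Package: parnuc
Title: Parallel Chemical and MNase Mapping of Nucleosomes on Circular
    Minichromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for gel-based parallel nucleosome mapping, in
    which histone H4 S47C site-directed hydroxyl-radical cleavage (marking
    nucleosome centers) is read out alongside micrococcal nuclease (MNase)
    digestion (marking linker DNA) on a circular yeast minichromosome.
    Provides circular coordinate arithmetic for minichromosome maps,
    densitometry calibration of gel lanes to base coordinates (size-marker
    standard curves, anchor-band interpolation, the primer-extension
    one-base Taq correction), strand-resolved 5'-end and cleavage-site
    pileup tracks with replicate combination and moving-average smoothing,
    nucleosome inference (MNase-protected regions, chemical dyad centers,
    center offsets, nucleosome-free-region sizes, overlapping position
    frames), and seeded synthetic-data generators for chemical-cleavage
    reads, MNase cut sets and gel lane traces with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
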