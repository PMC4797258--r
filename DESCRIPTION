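Package: transdecon
Title: Planning and Simulation of Transductional Deconvolution Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping-by-replacement genetics in bacteria with
    circular chromosomes. Models co-transduction linkage between a
    selectable marker and a nearby locus with the Wu frequency curve,
    searches ordered marker-insertion libraries for the nearest marker to
    any genomic position, designs new marker libraries at a target spacing
    inside intergenic regions, builds per-variant transduction experiment
    plans from whole-genome sequencing variant calls, scores plate-reader
    re-screen data into causative-mutation calls, and runs Monte-Carlo
    simulations of the complete forward-genetic screen plus transductional
    deconvolution workflow, including a Poisson mutagenesis dose model and
    a stochastic replaced-fragment model of generalized transduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
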