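Package: wavescape
Title: RNA Polymerase II Pause-Release Waves, UV Damage Sensing and
    Mutation Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Analytics for genotoxic-stress transcription genomics: promoter
    escape indexes (EI) and their UV-induced shifts, elongation wave front and
    backend estimation from composite read-density profiles with elongation-rate
    kinetics, genome-wide calling of dipyrimidine (XTTX) loci on gene template
    strands, summit-minus-flank ('S - F') stalling and excision-repair scores
    with control-derived thresholds and the associated non-parametric test
    battery, and strand- and expression-resolved somatic mutation prevalence
    profiles with exome density correction.  A deterministic synthetic-data
    generator (genome, annotation, coverage time courses, stalling and repair
    signals, expression tables, mutation catalogs) makes every stage testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
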