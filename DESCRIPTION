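Package: rdnatiming
Title: Replication Timing, Licensing and Firing Analysis at Repetitive rDNA Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies DNA replication at a tandemly repeated rDNA locus from
    fragment-interval sequencing libraries. Computes relative replication
    timing (Trel) from sorted G1/S libraries, estimates rDNA copy number from
    the G1 read fraction, builds fragment-size-resolved MCM-ChEC and MNase
    profiles that resolve closely spaced helicase complexes, infers origin
    firing from the differential disappearance of MCM footprints across a
    hydroxyurea time course, quantifies EdU origin activity, and implements
    Southern-band and qPCR arithmetic for licensing and array-size estimation.
    Includes a synthetic fragment-library generator that emulates the locus
    model so every analysis stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
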