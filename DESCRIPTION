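Package: invindel
Title: Inversion-Indel Distance for Circular Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome rearrangement distances between unichromosomal circular
    genomes with unequal marker content and no duplicated markers. Builds the
    relational diagram of two genomes, decomposes it into cycles, counts runs
    of unique-marker labels and their indel-potential, and computes the DCJ
    (double cut and join) distance, the DCJ-indel distance, the inversion
    distance (via the component tree), and the inversion-indel distance --
    exactly through safe singleton integrations when the diagram has no bad
    component, and as component-tree cover bounds otherwise. Includes a
    sorting-scenario generator, a seeded synthetic genome-pair simulator, and
    exhaustive breadth-first-search reference implementations for validation
    on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
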