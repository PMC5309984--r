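Package: hlaflow
Title: Simulation and Quality-Control Machinery for Registry-Scale Amplicon HLA Genotyping
Version: 0.1.0
Authors@R:
    person("DKMS-style", "Workflow Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate and audit high-throughput amplicon-based HLA
    genotyping workflows of the kind used by large stem-cell donor registries.
    Includes a synthetic registry generator (donor DNA concentrations, allele
    panels with hidden novel alleles, paired-end amplicon reads with primer
    dimers, PCR chimeras, point errors and allelic dropout), read-artefact
    classification, a simplified consensus genotype caller, an auditable
    repeat-typing policy engine, Michaelis-Menten read-yield modelling for
    quantification-free post-PCR pool normalisation, and resampling-based
    forecasting of novel-allele discovery with a three-parameter exponential
    decay model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
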