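Package: gdresist
Title: Gene Drive Dynamics and Target-Site Resistance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic population-genetic modelling of a CRISPR-Cas9 homing
    gene drive with target-site resistance, and analysis of pooled amplicon
    sequencing of the drive target locus. Implements a four-allele (wild type,
    drive, functional and non-functional resistant) discrete-generation
    recursion with meiotic homing, meiotic and embryonic end-joining from
    maternally deposited nuclease, and sex-specific fertility effects;
    estimators linking single-cross transmission counts and cage trajectories
    to model rates; an amplicon pipeline for indel calling, frame
    classification, allele-frequency tables, SNV calling, haplotype assignment
    and microhomology-mediated end-joining (MMEJ) deletion prediction; and a
    fully seeded synthetic-data generator producing paired-end amplicon reads
    with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
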