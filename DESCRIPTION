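Package: defloc
Title: Locating Antiviral Defence Systems in Prokaryotic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects antiviral defence systems (restriction-modification,
    CRISPR-Cas, DISARM, Wadjet, retrons and others) in annotated bacterial
    and archaeal genomes. Candidate defence genes are identified from
    profile-HMM homology search results filtered on E-value and alignment
    coverage, then compared against declarative system-definition models
    that specify core, accessory and prohibited gene families together with
    quorum and colocalization rules. CRISPR arrays and retron ncRNAs are
    integrated as non-coding system components, and annotation-flagged
    pseudogenes can be rescued by substituting their inferred full-length
    protein products. Results are written as a per-gene CSV and a systems
    GFF3, with per-genome diversity and abundance summaries. A deterministic
    fixture generator builds a toy model database and synthetic genomes with
    planted systems for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
SystemRequirements: HMMER3 (hmmsearch, hmmbuild) for in-process profile
    searches and demo database construction; Prodigal (optional) for gene
    calling on unannotated nucleotide input.
RoxygenNote: 7.3.3
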