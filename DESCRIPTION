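Package: fairVCF
Title: FAIR Metadata Validation and Annotation for Plant Genotyping VCF Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses, validates and repairs the meta-information section of
    Variant Call Format (VCF, version 4.x) files against a FAIR metadata
    profile for plant genotyping studies. Implements a registry of
    field-grammar and cardinality rules (file date, bioinformatics source,
    reference assembly accession and URL, contig and SAMPLE records with
    BioSample, DOI and external-identifier grammars), cross-checks contig
    declarations against a reference FASTA (names, lengths, MD5 digests)
    and data-line positions against declared contig bounds, and injects
    compliant metadata into existing headers. Ships a deterministic fixture
    generator, a machine-readable validation report, and a command-line
    interface with validate, annotate and fixtures subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    jsonlite,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
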