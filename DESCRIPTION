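Package: refsmith
Title: Search, Install and Preprocess Reference Genomes and Gene Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing reference genome assemblies and gene
    annotations: search cached assembly metadata by free text, taxonomy
    identifier or assembly accession; install (fetch and preprocess) genomes
    with controllable repeat masking, alternate-locus removal and regex
    contig filtering; generate supporting files (byte-offset FASTA index,
    contig sizes, assembly-gap intervals); read and interconvert GFF3, GTF
    and BED12 gene annotations through a common transcript model; harmonize
    contig naming between annotation and genome; and log full provenance of
    every installation.  All functionality works offline against
    filesystem-backed providers and includes a synthetic fixture generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
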