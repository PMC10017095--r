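# refsmith

Reference genomes and gene annotations, managed.

Every functional-genomics analysis — ATAC-, ChIP- or RNA-seq, motif
scanning, variant annotation — starts from a reference assembly and a gene
annotation. These come from several providers (Ensembl, UCSC, NCBI,
GENCODE, plus model-organism databases) in different formats, naming
schemes and masking conventions, and assembling them by hand is tedious and
hard to reproduce. refsmith is an R package plus command-line tool for
people who need that plumbing done deterministically: it searches cached
assembly metadata, installs (fetches and preprocesses) a genome with
controllable masking and contig filtering, generates the supporting files
aligners and browsers expect, converts annotations among GFF3/GTF/BED12,
reconciles contig naming between annotation and genome, and logs the
provenance of every step.

Everything works offline against filesystem-backed providers, and a
synthetic fixture generator with known ground truth makes the whole feature
set testable without a single download.

## What it computes

**Metadata search.** Queries are classified automatically: strings matching
the INSDC accession grammar `GC[AF]_` + 9 digits (+ optional `.version`)
are accessions, all-digit strings are taxonomy IDs, everything else is free
text. Text matches case-insensitive substrings of name, species and
description fields; a version-less accession matches every version of that
accession, a versioned one only its own.

**Genome index.** A faidx-style per-contig table
(name, length, offset, linebases, linebytes) over the uncompressed FASTA
stream. For a 0-based offset *i* in a contig with *b* bases and *B* bytes
per line, the byte position is

    offset + floor(i / b) * B + (i mod b)

which gives O(1) extraction of any region, with IUPAC-aware reverse
complement on the minus strand. Random regions are drawn uniformly from the
pool of valid start positions across contigs, so contigs are sampled in
proportion to their valid-start counts; gap exclusion shrinks the pool
exactly.

**Masking.** `soft` keeps the file as shipped (lowercase = repeats),
`hard` replaces every lowercase base with `N`, `none` uppercases. Headers,
line wrapping and sequence lengths are never altered; uppercase bases are
never touched.

**Gaps and sizes.** Assembly gaps are the maximal runs of `N`/`n`
(0-based half-open, emitted as 3-column BED); contig sizes come from the
index.

**Annotation model.** GFF3, GTF and BED12 all parse into one
transcript-centric model — ascending disjoint exon intervals plus an
optional CDS span, 0-based half-open — which is the pivot for every
conversion (GTF/GFF3 are 1-based closed on disk; BED12 encodes exons as
`blockSizes`/`blockStarts` and the CDS as `thickStart`/`thickEnd`, with
`thickStart == thickEnd` meaning non-coding).

**Contig harmonization.** Annotation contigs are renamed to genome contigs
by a fixed rule cascade — exact match, alias-group lookup
(assembly-report-style tables), `chr` prefix added/removed,
case-insensitive — with ambiguities raised as errors, never guessed.

**Install pipeline.** fetch → decompress → alt-contig exclusion → regex
filter → masking → rewrap/write → index → sizes → gaps → annotation
(most descriptive format available: GFF3 > GTF > BED12) → GTF + BED12
emission → harmonization → contig filtering → plugins → provenance README.
Defaults follow common practice: soft masking, alternate loci excluded.

## Worked example

Build a synthetic provider, search it, and install an assembly:

```r
library(refsmith)

root <- "prov_demo"
generate_provider(root, "ensembl_fs",
  list(zfish_toy = fixture_spec(seed = 7, orphan_transcripts = 2,
                                alt_contig_count = 2)),
  annotation_formats = c("gtf", "gff3", "bed12"),
  taxonomy_ids = c(zfish_toy = 7955L),
  species = c(zfish_toy = "Danio rerio"))

cache <- load_metadata_cache(root)
writeLines(format_search_table(search_records(cache, "danio")))
#> name       provider    accession        taxonomy_id  annotations  species
#> zfish_toy  ensembl_fs  GCA_100000701.1  7955         YYY          Danio rerio

res <- install_assembly("zfish_toy", cache, output_root = "installed")
res$files
#> README.txt  zfish_toy.annotation.bed  zfish_toy.annotation.gtf
#> zfish_toy.fa  zfish_toy.fa.fai  zfish_toy.fa.sizes  zfish_toy.gaps.bed
```

The taxonomy ID 7955 was matched automatically (`YYY` marks the three
annotation sources available). The install excluded the two alt-locus
contigs (`chr1_GL100001_alt`, `chr2_ctg_hap2` — listed under
"filtered contigs" in `README.txt`), picked the GFF3 annotation as the most
descriptive source, and emitted it as GTF and BED12 with contig names
matching the genome. The supporting files:

```r
readLines(file.path(res$dir, "zfish_toy.fa.sizes"))
#> chr1  5369
#> chr2  3490
#> chr3  5486
head(readLines(file.path(res$dir, "zfish_toy.gaps.bed")), 3)
#> chr1  433   502
#> chr1  2715  2764
#> chr2  2155  2197
```

Random access through the index (1-based closed region string, internally
converted):

```r
idx <- read_genome_index(file.path(res$dir, "zfish_toy.fa.fai"),
                         file.path(res$dir, "zfish_toy.fa"))
extract_sequence(idx, file.path(res$dir, "zfish_toy.fa"), "chr1:101-140")
#> "CTCTTAGATGTGCAAATGTTCACAtagactcgttatctta"
```

The same operations from a shell:

```sh
refsmith search 7955 --providers-root prov_demo
refsmith install zfish_toy --providers-root prov_demo --output installed
refsmith genome extract installed/zfish_toy/zfish_toy.fa chr1:101-140
refsmith convert installed/zfish_toy/zfish_toy.annotation.gtf out.bed --to bed12
```

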