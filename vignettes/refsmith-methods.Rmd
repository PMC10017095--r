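---
title: "refsmith: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{refsmith: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refsmith)
```

refsmith manages reference genomic data: it searches assembly metadata,
installs and preprocesses genomes and gene annotations, generates the
supporting files downstream tools expect, and records provenance. This
vignette explains the conventions the package commits to, why each default
is what it is, and what the test fixtures do and do not demonstrate about
real provider data.

## Coordinate conventions

All internal coordinates are 0-based half-open, i.e. BED semantics: an
interval `[start, end)` of length `end - start`. The two annotation
formats that are 1-based fully closed on disk (GTF, GFF3) are converted at
the parse and emit boundary only, by `start - 1` on the way in and
`start + 1` on the way out; these conversions are exact inverses and the
test suite asserts the composition is the identity. User-facing region
strings (`chr1:101-140`) follow the samtools convention — 1-based, both
ends included — because that is what people type into `samtools faidx`.
Keeping one internal convention removes the most common class of
off-by-one defects in this problem space.

## The genome index

The index is the faidx layout: per contig, its length, the byte offset of
its first sequence byte, and the line geometry (bases per line, bytes per
line). It is computed on the *uncompressed* stream, so gzip-compressed
inputs index identically to plain ones; extraction from a compressed file
skips bytes sequentially rather than seeking, trading speed for
correctness on a format that does not support random access. A FASTA is
accepted only if every sequence line of a record except the last has equal
length — ragged interiors make the offset arithmetic meaningless and are
rejected with the contig and line number rather than silently misindexed.

Empty records (a header with no sequence) are legal and indexed with
length zero; their line geometry is recorded as zero and no extraction
other than the empty interval is valid.

## Random region sampling

`random_regions()` draws start positions uniformly from the concatenated
pool of valid starts over all contigs: a contig of length `L` contributes
`L - len + 1` starts for region length `len`, so contigs are selected with
probability exactly proportional to their valid-start counts — a property
the tests verify with a binomial 3-sigma bound at n = 10,000. Gap
exclusion removes the forbidden start interval
`[gap_start - len + 1, gap_end)` from the pool before drawing, so the "no
region overlaps a gap" guarantee is structural, not rejection-sampled, and
the function stays a pure function of `(index, n, len, seed,
exclude_gaps, gaps)`. Sampling runs in a private RNG scope so callers'
random streams are unaffected.

## Masking

FASTA carries exactly one masking signal: case. Consequently `hard`
masking replaces precisely the lowercase alphabet with `N` and `none`
uppercases it; uppercase repeats are unknowable from the file and are
never touched. `soft` is a byte-for-byte copy. Masking never rewraps or
re-headers — the transform is line-local — so a masked file differs from
its input only at lowercase positions. Both `hard` and `none` are
idempotent, which the acceptance checks exercise directly.

The install default is `soft` masking with alternate loci excluded:
soft-masked references preserve repeat information without affecting
aligner seeds, while alt contigs duplicate primary sequence and cause
multi-mapping, so most pipelines want them gone unless asked otherwise.

## Alt-locus recognition

Providers do not flag alternate loci inside FASTA, so recognition is
name-based: a header token containing `_alt`, ending in `alt`, or
containing `hap` followed by a digit (case-insensitive) is treated as an
alt contig. This covers the GRC-style (`chr5_GL339449v2_alt`) and older
haplotype (`chr6_apd_hap1`) conventions. It is a stand-in for provider
metadata, documented as such, and the pattern list is an argument
(`patterns =`) so callers can override it per assembly.

## Gap definition

A gap is a maximal run of `N`/`n`, minimum length one. Other IUPAC
ambiguity codes are *not* gaps: they encode partial base knowledge, not
absence, and assembly-gap practice (UCSC `gap` tracks, NCBI AGP) counts
only N runs. Output is 3-column BED, so gap intervals compose directly
with interval tools.

## The transcript model and format conversion

Transcripts, not genes, are the conversion pivot: BED12 is inherently
transcript-level, and gene records are re-derivable from `gene_id`. A
transcript is its contig, strand, ascending pairwise-disjoint exon
intervals, and an optional CDS span. Parsing enforces the invariants
(overlapping exons, duplicate transcript ids, a transcript spanning two
contigs are all hard errors) because silently "repairing" pathological
annotations produces files that fail later in someone else's aligner.

Conversion choices worth stating explicitly:

* BED12 blocks are always emitted in ascending order regardless of strand;
  `thickStart == thickEnd == chromStart` encodes "no CDS" (UCSC
  convention).
* `exon_number` in emitted GTF counts in transcription order, i.e. from
  the rightmost exon for minus-strand transcripts. Strand `.` is preserved
  on input and treated as `+` only where an orientation is forced.
* The CDS span is taken verbatim from the input features (min/max over CDS
  lines in GTF/GFF3) and emitted as a single CDS feature with that span.
  No stop-codon ±3 adjustment is applied between dialects — the formats
  disagree about whether the stop codon is inside the CDS, the input does
  not say which convention it used, and guessing would corrupt round
  trips. This is the documented caveat for consumers that care about the
  terminal codon.
* GTF attribute parsing handles the `key "value";` dialect; escaped quotes
  inside values are out of scope and rejected loudly. GFF3 percent
  decoding covers the reserved characters (`;`, `=`, `&`, `,`, tab, `%`)
  only.
* Emitted GFF3 reconstructs a `gene` feature per `gene_id` so the output
  is hierarchy-complete and re-parseable; a table whose `gene_id` equals a
  `transcript_id` would produce colliding IDs and is the one known
  degenerate input for that writer.

When an install must choose among available annotation sources, the
preference is GFF3 > GTF > BED12 — richest hierarchy and attribute model
first, since the poorer formats are derivable from the richer but not vice
versa. Provider-specific labels (the UCSC-style four-way annotation
flags) fall back to the provider's own listed order, first available wins.

## Contig-name harmonization

Matching annotation contigs to genome contigs uses a fixed rule cascade:
(1) exact name, (2) alias-group lookup in an assembly-report-style table,
(3) `chr` prefix added or removed, (4) case-insensitive match. The first
applicable rule wins; the resulting map must be injective, and two
annotation contigs resolving to one genome contig is an error listing the
offenders rather than a guess. Unmatched contigs are left untouched and
reported, and `filter_by_contigs()` then removes their transcripts with
exact counts. Because mapped names are genome names, a second application
of the cascade hits rule 1 everywhere — harmonization is idempotent by
construction, and the tests assert it.

## The install pipeline and provenance

The pipeline order is fixed: fetch, decompress, alt exclusion, regex
filter, masking, rewrap and write, index, sizes, gaps, annotation fetch /
parse / emit / harmonize / filter, plugins, README. Each step appends
exactly one provenance entry; filtered contigs are listed exhaustively.
The installed genome is rewrapped at 80 bases/line regardless of input
wrapping so that byte-level comparisons between installs are
well-defined — "same config, same provider, same bytes (modulo
timestamps)" is an acceptance property. Work happens in a temporary
directory that is promoted atomically; a failed install leaves a
quarantined `.tmp_<name>` directory and never a half-written layout, and
re-installing requires `force = TRUE`.

The README format is the package's own, deliberately line-oriented so that
`read_readme()` parses it back and write–parse–write is byte-identical; no
compatibility with any other tool's log format is claimed.

Plugins run after core processing in registration order. The blacklist
plugin copies a configured blacklist BED into the layout, harmonizing its
contig names with the same rule cascade as annotations. Aligner-index
plugins (bwa, bowtie2, minimap2, STAR, HISAT2) are registered as hook
points that record "external tool not invoked" in provenance: invoking the
tools themselves is out of scope, but the extension seam is real and
tested. All plugins default to disabled; states persist in a small
per-user config file.

## The fixture generator

`fixture_spec()` + `generate_genome()` + `generate_annotation()` produce
genomes and annotations whose ground truth is known by construction:
uniform A/C/G/T sequence, soft-mask runs recorded as intervals, N-gap runs
planted with at least one non-N base between and around them (so
maximality is guaranteed), alt contigs named per the documented patterns,
transcripts placed in gap-free windows, orphan transcripts planted on a
contig absent from the genome, and alias tables across `ucsc` /
`ensembl` / `ncbi` style naming schemes. One seeded generator drives each
artifact, so every file is byte-identical given a spec.

Defaults are sized for a toy vertebrate-like fixture: 3 contigs of
2–6 kb, 20% soft-masked, two 20–100 b gaps per contig, one alt contig,
10 genes with 1–2 transcripts of 1–5 exons, wrapped at 60 bases. These
exercise every code path (multi-contig wrapping, masking, gaps, alt
exclusion, multi-exon CDS transcripts, scheme divergence) while keeping
the full test suite in seconds.

What the fixtures do *not* emulate — and therefore what passing tests do
not show about real data: realistic nucleotide composition or repeat
structure, provider-specific format quirks (out-of-spec GTF attributes,
GFF3 FASTA sections), very large genomes, or real provider server
behavior. The oracle properties (index arithmetic, round trips,
harmonization) are format-level and transfer to real files; data-quality
robustness beyond the documented error cases does not.

## Problem sizes in the checks

The acceptance checks use five genomes of four contigs at 5–20 kb each
with 1,000 random extractions per genome, 100 randomized transcript tables
for the round trips, 50 generated search queries plus a 30-case
classification table, and two full installs compared byte-for-byte. These
sizes give the binomial sampling bound adequate power and exercise every
branch while the whole suite stays fast enough to run on every change.

## Known limitations

* BED12 cannot carry `gene_id`/`gene_name`; converting through BED12 loses
  them (ids and structure survive). Round trips through GTF/GFF3 are
  lossless for structure, CDS, strand, ids and gene names.
* Accession queries assume the INSDC `GC[AF]_` grammar; providers using
  other identifier schemes are matched as text.
* The all-digits-means-taxonomy rule is deterministic but means a numeric
  assembly name needs `--as-text` (CLI) or `as_text = TRUE`.
* Transport is local paths and `file://` (plus plain `download.file` for
  http), sufficient for filesystem providers and mirrors; there are no
  live provider clients.
* The fixtures CLI takes plain flags rather than a spec file; the full
  spec surface is available programmatically through `fixture_spec()`.
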