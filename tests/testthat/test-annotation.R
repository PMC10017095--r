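# Annotation parsing, conversion round trips, harmonization, dictionaries.

gtf_line <- function(contig, type, start, end, strand, attrs) {
  sprintf("%s\tsrc\t%s\t%d\t%d\t.\t%s\t.\t%s", contig, type, start, end,
          strand, attrs)
}

write_tmp <- function(lines, ext = ".gtf") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("GTF exons group by transcript and convert to 0-based half-open", {
  path <- write_tmp(c(
    "# a comment",
    gtf_line("chr1", "exon", 11, 20, "+", 'gene_id "g1"; transcript_id "t1";'),
    gtf_line("chr1", "exon", 31, 40, "+", 'gene_id "g1"; transcript_id "t1";')))
  tab <- read_gtf(path)
  expect_length(tab$transcripts, 1L)
  expect_equal(tab$transcripts$t1$exons, rbind(c(10, 20), c(30, 40)))
  expect_equal(tab$transcripts$t1$gene_id, "g1")
  expect_null(tab$transcripts$t1$cds)
})

test_that("GTF edge cases: gene-only files, missing ids, overlapping exons", {
  gene_only <- write_tmp(gtf_line("chr1", "gene", 1, 100, "+", 'gene_id "g";'))
  expect_warning(tab <- read_gtf(gene_only), "no exon")
  expect_length(tab$transcripts, 0L)
  no_id <- write_tmp(gtf_line("chr1", "exon", 1, 10, "+", 'gene_id "g";'))
  expect_error(read_gtf(no_id), "line 1", class = "refsmith_format")
  overlap <- write_tmp(c(
    gtf_line("chr1", "exon", 1, 10, "+", 'transcript_id "t";'),
    gtf_line("chr1", "exon", 5, 20, "+", 'transcript_id "t";')))
  expect_error(read_gtf(overlap), class = "refsmith_integrity")
  esc <- write_tmp(gtf_line("chr1", "exon", 1, 10, "+",
                            'transcript_id "a\\"b";'))
  expect_error(read_gtf(esc), class = "refsmith_format")
})

test_that("GFF3 assembles transcripts through the Parent graph", {
  path <- write_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1;Name=GeneA",
    "chr1\tsrc\tmRNA\t11\t40\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t11\t20\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t31\t40\t.\t+\t.\tParent=t1"), ".gff3")
  tab <- read_gff3(path)
  expect_equal(tab$transcripts$t1$exons, rbind(c(10, 20), c(30, 40)))
  expect_equal(tab$transcripts$t1$gene_id, "g1")
  expect_equal(tab$transcripts$t1$gene_name, "GeneA")
})

test_that("GFF3 multi-parent exons, forward references, bad links", {
  multi <- write_tmp(c(
    "chr1\tsrc\texon\t11\t20\t.\t+\t.\tParent=t1,t2",  # forward reference
    "chr1\tsrc\tmRNA\t11\t20\t.\t+\t.\tID=t1",
    "chr1\tsrc\tmRNA\t11\t20\t.\t+\t.\tID=t2"), ".gff3")
  tab <- read_gff3(multi)
  expect_setequal(names(tab$transcripts), c("t1", "t2"))
  expect_equal(tab$transcripts$t1$exons, tab$transcripts$t2$exons)
  orphan <- write_tmp("chr1\tsrc\texon\t1\t10\t.\t+\t.\tParent=ghost", ".gff3")
  expect_error(read_gff3(orphan), "ghost", class = "refsmith_format")
  cyclic <- write_tmp(c(
    "chr1\tsrc\tmRNA\t1\t10\t.\t+\t.\tID=a;Parent=b",
    "chr1\tsrc\tmRNA\t1\t10\t.\t+\t.\tID=b;Parent=a",
    "chr1\tsrc\texon\t1\t10\t.\t+\t.\tParent=a"), ".gff3")
  expect_error(read_gff3(cyclic), class = "refsmith_integrity")
})

test_that("GFF3 percent-encoding of reserved characters round-trips", {
  path <- write_tmp(c(
    "chr1\tsrc\tmRNA\t1\t10\t.\t+\t.\tID=t1;gene_name=a%3Bb%3Dc%2Cd%25",
    "chr1\tsrc\texon\t1\t10\t.\t+\t.\tParent=t1"), ".gff3")
  tab <- read_gff3(path)
  expect_equal(tab$transcripts$t1$gene_name, "a;b=c,d%")
  out <- table_to_gff3(tab)
  expect_true(any(grepl("a%3Bb%3Dc%2Cd%25", out, fixed = TRUE)))
})

test_that("BED12 columns decode to exons and CDS", {
  row <- "chr1\t10\t40\tt1\t0\t+\t14\t35\t0\t2\t10,10\t0,20"
  tab <- read_bed12(write_tmp(row, ".bed"))
  t1 <- tab$transcripts$t1
  expect_equal(t1$exons, rbind(c(10, 20), c(30, 40)))
  expect_equal(t1$cds, c(14, 35))
  # thickStart == thickEnd encodes no CDS
  no_cds <- "chr1\t10\t40\tt2\t0\t+\t10\t10\t0\t2\t10,10\t0,20"
  expect_null(read_bed12(write_tmp(no_cds, ".bed"))$transcripts$t2$cds)
  bad_count <- "chr1\t10\t40\tt\t0\t+\t10\t10\t0\t3\t10,10\t0,20"
  expect_error(read_bed12(write_tmp(bad_count, ".bed")),
               class = "refsmith_format")
  past_end <- "chr1\t10\t40\tt\t0\t+\t10\t10\t0\t2\t10,15\t0,20"
  expect_error(read_bed12(write_tmp(past_end, ".bed")),
               class = "refsmith_bounds")
})

test_that("BED12 emission inverts BED12 parsing", {
  row <- "chr1\t10\t40\tt1\t0\t+\t14\t35\t0\t2\t10,10\t0,20"
  tab <- read_bed12(write_tmp(row, ".bed"))
  expect_equal(table_to_bed12(tab), row)
  # single-exon transcript without CDS
  one <- new_annotation_table(list(list(
    transcript_id = "s", gene_id = "s", gene_name = NA_character_,
    contig = "c", strand = "+", exons = matrix(c(0, 5), ncol = 2),
    cds = NULL, attributes = character(0), lines = 1L)), "bed12", "c")
  expect_equal(table_to_bed12(one), "c\t0\t5\ts\t0\t+\t0\t0\t0\t1\t5\t0")
})

test_that("GTF emission numbers exons in transcription order", {
  tab <- read_bed12(write_tmp(
    "chr1\t10\t40\tneg\t0\t-\t14\t35\t0\t2\t10,10\t0,20", ".bed"))
  lines <- table_to_gtf(tab)
  exon_lines <- grep("\texon\t", lines, value = TRUE)
  # exon_number 1 must be the rightmost exon for strand -
  first <- exon_lines[grepl('exon_number "1"', exon_lines)]
  expect_match(first, "\t31\t40\t")
  expect_match(exon_lines[grepl('exon_number "2"', exon_lines)], "\t11\t20\t")
  # 1-based closed coordinates on output
  expect_match(grep("\ttranscript\t", lines, value = TRUE), "\t11\t40\t")
})

test_that("round trips preserve structure across formats for random tables", {
  for (seed in c(3L, 17L, 29L)) {
    spec <- fixture_spec(seed = seed, n_genes = 8L)
    truth <- generate_genome(spec, tempfile(fileext = ".fa"))
    tab <- generate_annotation(truth)$table
    gtf <- write_tmp(table_to_gtf(tab))
    expect_true(tables_equal(tab, read_gtf(gtf), check_name = TRUE))
    bed <- write_tmp(table_to_bed12(tab), ".bed")
    expect_true(tables_equal(tab, read_bed12(bed), check_gene = FALSE))
    gff <- write_tmp(table_to_gff3(tab), ".gff3")
    expect_true(tables_equal(tab, read_gff3(gff), check_name = TRUE))
    # cross-format: both renderings parse to the same table
    expect_true(tables_equal(read_gtf(gtf), read_gff3(gff), check_name = TRUE))
    # second round trip is the identity of the first
    expect_identical(table_to_gtf(read_gtf(gtf)), readLines(gtf))
  }
})

test_that("contig harmonization applies the rule cascade deterministically", {
  mk_tab <- function(contig) new_annotation_table(list(list(
    transcript_id = "t", gene_id = "g", gene_name = NA_character_,
    contig = contig, strand = "+", exons = matrix(c(0, 10), ncol = 2),
    cds = NULL, attributes = character(0), lines = 1L)), "gtf", contig)
  # rule 1: exact
  h <- harmonize_contig_names(mk_tab("chr1"), c("chr1", "chr2"))
  expect_equal(unname(h$report$map[["chr1"]]), "chr1")
  expect_length(h$report$unmatched, 0L)
  # rule 3: chr prefix removal and addition
  h <- harmonize_contig_names(mk_tab("chr1"), c("1", "2"))
  expect_equal(h$table$transcripts$t$contig, "1")
  h <- harmonize_contig_names(mk_tab("1"), c("chr1", "chr2"))
  expect_equal(h$table$transcripts$t$contig, "chr1")
  # rule 2: alias groups beat the chr-prefix rule
  aliases <- structure(list(groups = list(
    c(ncbi = "KN149696.1", ucsc = "chrUn_KN149696v1")),
    schemes = c("ncbi", "ucsc")), class = "contig_alias_map")
  h <- harmonize_contig_names(mk_tab("KN149696.1"), "chrUn_KN149696v1", aliases)
  expect_equal(h$table$transcripts$t$contig, "chrUn_KN149696v1")
  # rule 4: case-insensitive
  h <- harmonize_contig_names(mk_tab("CHRM"), c("chrM", "chr1"))
  expect_equal(h$table$transcripts$t$contig, "chrM")
  # unmatched contigs are reported, not guessed
  h <- harmonize_contig_names(mk_tab("weird_scaffold"), c("chr1"))
  expect_equal(h$report$unmatched, "weird_scaffold")
  expect_equal(h$report$n_unmatched_transcripts, 1L)
})

test_that("harmonization is idempotent and rejects ambiguous mappings", {
  spec <- fixture_spec(seed = 13L, orphan_transcripts = 2L)
  truth <- generate_genome(spec, tempfile(fileext = ".fa"))
  ann <- generate_annotation(truth)
  ens <- rename_annotation_scheme(ann$table, truth, "ensembl")
  genome <- truth$primary_contigs
  al_path <- tempfile(fileext = ".tsv")
  generate_alias_table(truth, al_path)
  aliases <- read_alias_table(al_path)
  h1 <- harmonize_contig_names(ens, genome, aliases)
  h2 <- harmonize_contig_names(h1$table, genome, aliases)
  expect_identical(h1$table, h2$table)
  expect_setequal(unname(h1$report$map), genome)
  # two annotation contigs collapsing onto one genome contig is an error
  amb <- new_annotation_table(list(
    list(transcript_id = "t1", gene_id = "g", gene_name = NA_character_,
         contig = "chr1", strand = "+", exons = matrix(c(0, 10), ncol = 2),
         cds = NULL, attributes = character(0), lines = 1L),
    list(transcript_id = "t2", gene_id = "g", gene_name = NA_character_,
         contig = "CHR1", strand = "+", exons = matrix(c(0, 10), ncol = 2),
         cds = NULL, attributes = character(0), lines = 2L)),
    "gtf", c("chr1", "CHR1"))
  expect_error(harmonize_contig_names(amb, "chr1"),
               class = "refsmith_integrity")
})

test_that("transcripts on missing contigs are filtered with exact counts", {
  spec <- fixture_spec(seed = 19L, orphan_transcripts = 3L)
  truth <- generate_genome(spec, tempfile(fileext = ".fa"))
  ann <- generate_annotation(truth)
  filtered <- filter_by_contigs(ann$table, truth$primary_contigs)
  expect_setequal(attr(filtered, "removed_transcripts"), ann$orphan_ids)
  expect_length(filtered$transcripts,
                length(ann$table$transcripts) - length(ann$orphan_ids))
  # no mismatches: identity
  same <- filter_by_contigs(filtered, truth$primary_contigs)
  expect_equal(names(same$transcripts), names(filtered$transcripts))
  expect_length(attr(same, "removed_transcripts"), 0L)
})

test_that("attribute dictionaries map any two fields with conflict reporting", {
  tab <- new_annotation_table(list(
    list(transcript_id = "t1", gene_id = "g1", gene_name = "GeneA",
         contig = "c", strand = "+", exons = matrix(c(0, 10), ncol = 2),
         cds = NULL, attributes = c(biotype = "coding"), lines = 1L),
    list(transcript_id = "t2", gene_id = "g1", gene_name = "GeneA2",
         contig = "c", strand = "+", exons = matrix(c(20, 30), ncol = 2),
         cds = NULL, attributes = c(biotype = "coding"), lines = 2L),
    list(transcript_id = "t3", gene_id = "g2", gene_name = NA_character_,
         contig = "c", strand = "-", exons = matrix(c(40, 50), ncol = 2),
         cds = NULL, attributes = character(0), lines = 3L)),
    "gtf", "c")
  d <- attribute_dictionary(tab, "gene_id", "gene_name")
  expect_equal(unname(d[["g1"]]), "GeneA")       # first occurrence wins
  expect_equal(attr(d, "conflicts"), 1L)
  expect_false("g2" %in% names(d))               # missing value -> omitted
  ident <- attribute_dictionary(tab, "gene_id", "gene_id")
  expect_equal(sort(names(ident)), c("g1", "g2"))
  expect_identical(unname(ident[names(ident)]), names(ident))
  bt <- attribute_dictionary(tab, "transcript_id", "biotype")
  expect_equal(sort(names(bt)), c("t1", "t2"))
  expect_error(attribute_dictionary(tab, "gene_id", "nonsense"),
               class = "refsmith_invalid_query")
})

test_that("contig scheme mapping inverts the alias groups", {
  al <- tempfile(fileext = ".tsv")
  writeLines(c("ensembl\tucsc", "1\tchr1", "2\tchr2", "MT\tchrM"), al)
  aliases <- read_alias_table(al)
  m <- map_contig_scheme(c("1", "chr2", "MT", "unknown"), aliases, "ucsc")
  expect_equal(unname(m[1:3]), c("chr1", "chr2", "chrM"))
  expect_true(is.na(m[["unknown"]]))
  expect_equal(attr(m, "unmapped"), "unknown")
  expect_error(map_contig_scheme("1", aliases, "refseq"),
               class = "refsmith_invalid_query")
  # full inversion oracle: mapping every ensembl name equals the ucsc column
  ens <- vapply(aliases$groups, `[[`, character(1), "ensembl")
  ucsc <- vapply(aliases$groups, `[[`, character(1), "ucsc")
  expect_equal(unname(map_contig_scheme(ens, aliases, "ucsc")), ucsc,
               ignore_attr = TRUE)
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "x\ty", "x\tz"), dup)
  expect_error(read_alias_table(dup), class = "refsmith_integrity")
})

test_that("annotation preview detects formats and returns data lines", {
  gtf <- write_tmp(c("# header",
    gtf_line("chr1", "exon", 1, 10, "+", 'transcript_id "t";')))
  h <- annotation_head(gtf, 2L)
  expect_equal(h$format, "gtf")
  expect_length(h$lines, 1L)
  bed <- write_tmp("chr1\t10\t40\tt1\t0\t+\t14\t35\t0\t2\t10,10\t0,20", ".bed")
  expect_equal(annotation_head(bed)$format, "bed12")
  gff <- write_tmp(c("##gff-version 3", "# only comments"), ".gff3")
  h3 <- annotation_head(gff, 5L)
  expect_equal(h3$format, "gff3")
  expect_length(h3$lines, 0L)
  expect_error(annotation_head(write_tmp("just some text", ".txt")),
               class = "refsmith_format")
})
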