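# Shared helpers: tiny on-the-fly fixtures and brute-force oracles that are
# independent of the implementation paths they check.

tmp_fasta <- function(seqs, width = 4L, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fa.gz" else ".fa")
  write_fasta(seqs, path, width = width)
  path
}

# independent reverse complement: plain lookup over ACGTN, case preserved
oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           a = "t", c = "g", g = "c", t = "a", n = "n")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

oracle_extract <- function(seqs, contig, start, end, strand = "+") {
  s <- substr(seqs[[contig]], start + 1, end)
  if (strand == "-") oracle_revcomp(s) else s
}

# regex-free gap scan: walk the characters
oracle_gaps <- function(seqs) {
  rows <- list()
  for (ctg in names(seqs)) {
    ch <- strsplit(seqs[[ctg]], "")[[1]]
    in_gap <- FALSE
    for (i in seq_along(ch)) {
      if (ch[i] %in% c("N", "n")) {
        if (!in_gap) { gs <- i - 1; in_gap <- TRUE }
      } else if (in_gap) {
        rows[[length(rows) + 1L]] <- data.frame(contig = ctg, start = gs,
                                                end = i - 1)
        in_gap <- FALSE
      }
    }
    if (in_gap)
      rows[[length(rows) + 1L]] <- data.frame(contig = ctg, start = gs,
                                              end = length(ch))
  }
  if (!length(rows))
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0)))
  out <- do.call(rbind, rows)
  out$start <- as.numeric(out$start); out$end <- as.numeric(out$end)
  out
}

# brute-force linear-scan search oracle over assembly records
oracle_search <- function(records, raw, type) {
  hits <- Filter(function(r) {
    switch(type,
      text = {
        hay <- tolower(c(r$assembly_name, r$species, r$description_fields))
        any(vapply(hay, function(h)
          grepl(tolower(raw), h, fixed = TRUE), logical(1)))
      },
      taxonomy = !is.na(r$taxonomy_id) && r$taxonomy_id == as.integer(raw),
      accession = {
        if (is.na(r$accession)) FALSE
        else if (grepl(".", raw, fixed = TRUE)) toupper(r$accession) == toupper(raw)
        else startsWith(sub("\\..*$", "", toupper(r$accession)), toupper(raw))
      })
  }, records)
  hits[order(vapply(hits, `[[`, character(1), "provider_name"),
             vapply(hits, `[[`, character(1), "assembly_name"),
             method = "radix")]
}

# structural equality of two transcripts (exons, CDS, strand, ids)
same_structure <- function(a, b, check_gene = TRUE, check_name = FALSE) {
  ok <- isTRUE(all.equal(a$exons, b$exons)) &&
    isTRUE(all.equal(a$cds, b$cds)) &&
    identical(a$strand, b$strand) &&
    identical(a$contig, b$contig)
  if (check_gene) ok <- ok && identical(a$gene_id, b$gene_id)
  if (check_name) ok <- ok && identical(a$gene_name, b$gene_name)
  ok
}

tables_equal <- function(a, b, ...) {
  identical(sort(names(a$transcripts)), sort(names(b$transcripts))) &&
    all(vapply(names(a$transcripts), function(id)
      same_structure(a$transcripts[[id]], b$transcripts[[id]], ...),
      logical(1)))
}

# small provider tree used by installer/CLI tests
make_test_provider <- function(root = tempfile("prov"), seed = 7L,
                               blacklist = TRUE) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    zfish_toy = fixture_spec(seed = seed, orphan_transcripts = 2L,
                             alt_contig_count = 2L),
    human_toy = fixture_spec(seed = seed + 1L, n_contigs = 2L))
  truths <- generate_provider(
    root, "ensembl_fs", specs,
    annotation_formats = c("gtf", "gff3", "bed12"),
    taxonomy_ids = c(zfish_toy = 7955L, human_toy = 9606L),
    species = c(zfish_toy = "Danio rerio", human_toy = "Homo sapiens"),
    blacklist = blacklist)
  list(root = root, truths = truths, cache = load_metadata_cache(root))
}
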