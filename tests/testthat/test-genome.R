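# FASTA indexing, random access, masking, filtering, sizes and gaps.

test_that("index records the faidx layout arithmetic", {
  fa <- tmp_fasta(c(chr1 = "ACGTACGT"), width = 4L)
  idx <- build_index(fa)
  expect_equal(idx$contig, "chr1")
  expect_equal(idx$length, 8L)
  expect_equal(idx$offset, 6)          # ">chr1\n"
  expect_equal(idx$bases_per_line, 4L)
  expect_equal(idx$bytes_per_line, 5L)

  # empty sequence record
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">c", ">d", "ACGT"), fa2)
  idx2 <- build_index(fa2)
  expect_equal(idx2$length, c(0L, 4L))
})

test_that("malformed FASTA is rejected with context", {
  bad <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", "ACGTA", "AC"), bad)   # interior line longer
  expect_error(build_index(bad), class = "refsmith_format")
  writeLines(c(">c1", "ACGT", "AC", "ACGT"), bad)    # interior line shorter
  expect_error(build_index(bad), "c1", class = "refsmith_format")
  writeLines(c(">c1", "ACGT", ">c1", "AC"), bad)
  expect_error(build_index(bad), class = "refsmith_integrity")
})

test_that("extraction matches the in-memory substring oracle", {
  set.seed(42)
  seqs <- c(
    chrA = paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t", "N"),
                        997, replace = TRUE), collapse = ""),
    chrB = paste(sample(c("A", "C", "G", "T"), 1203, replace = TRUE),
                 collapse = ""))
  for (gz in c(FALSE, TRUE)) {
    fa <- tmp_fasta(seqs, width = 61L, gz = gz)
    idx <- build_index(fa)
    expect_equal(idx$length, unname(nchar(seqs)))
    for (i in 1:150) {
      ctg <- sample(names(seqs), 1)
      len <- nchar(seqs[[ctg]])
      st <- sample(0:(len - 1), 1)
      en <- min(len, st + sample(1:100, 1))
      strand <- sample(c("+", "-"), 1)
      got <- extract_sequence(idx, fa, region(ctg, st, en, strand))
      expect_identical(got, oracle_extract(seqs, ctg, st, en, strand),
                       info = sprintf("%s:%d-%d(%s) gz=%s", ctg, st, en, strand, gz))
    }
  }
})

test_that("strand - returns the reverse complement, IUPAC and case aware", {
  fa <- tmp_fasta(c(c1 = "ACGTacgtRYKMn"), width = 80L)
  idx <- build_index(fa)
  expect_equal(extract_sequence(idx, fa, region("c1", 0, 4, "+")), "ACGT")
  expect_equal(extract_sequence(idx, fa, region("c1", 0, 4, "-")), "ACGT")
  expect_equal(extract_sequence(idx, fa, region("c1", 8, 13, "-")), "nKMRY")
})

test_that("extraction errors on unknown contigs and out-of-bounds regions", {
  fa <- tmp_fasta(c(c1 = "ACGTACGT"), width = 4L)
  idx <- build_index(fa)
  expect_error(extract_sequence(idx, fa, region("nope", 0, 2)),
               class = "refsmith_not_found")
  expect_error(extract_sequence(idx, fa, region("c1", 4, 9)),
               class = "refsmith_bounds")
  expect_equal(extract_sequence(idx, fa, region("c1", 3, 3)), "")
})

test_that("index write/reload round-trips losslessly", {
  set.seed(7)
  seqs <- c(a = paste(sample(c("A", "C"), 333, TRUE), collapse = ""),
            b = "", cc = "ACGTN")
  fa <- tmp_fasta(seqs, width = 50L)
  idx <- build_index(fa)
  fai <- tempfile(fileext = ".fai")
  write_genome_index(idx, fai)
  idx2 <- read_genome_index(fai, fasta = fa)
  expect_equal(as.data.frame(idx), as.data.frame(idx2))
  expect_identical(extract_sequence(idx2, fa, region("a", 10, 60)),
                   oracle_extract(seqs, "a", 10, 60))
})

test_that("1-based region strings convert to internal coordinates and back", {
  fa <- tmp_fasta(c(chr1 = "ACGTACGTAA"), width = 10L)
  idx <- build_index(fa)
  r <- parse_region("chr1:1-4", idx)
  expect_equal(c(r$start, r$end), c(0, 4))
  expect_equal(extract_sequence(idx, fa, "chr1:1-4"), "ACGT")
  expect_equal(format(r), "chr1:1-4(+)")
  expect_equal(parse_region("chr1", idx)$end, 10)
  expect_error(parse_region("bogus:!!"), class = "refsmith_invalid_query")
})

test_that("masking transforms exactly the lowercase alphabet", {
  fa <- tmp_fasta(c(c1 = "ACgtN"), width = 80L)
  out <- tempfile(fileext = ".fa")
  expect_equal(as.integer(apply_masking(fa, "hard", out)), 2L)
  expect_equal(unname(read_fasta(out)), "ACNNN")
  expect_equal(as.integer(apply_masking(fa, "none", out)), 2L)
  expect_equal(unname(read_fasta(out)), "ACGTN")
  expect_equal(as.integer(apply_masking(fa, "soft", out)), 0L)
  expect_equal(unname(read_fasta(out)), "ACgtN")
})

test_that("masking preserves layout and is idempotent for hard and none", {
  set.seed(11)
  seqs <- c(x = paste(sample(c("A", "c", "g", "T", "N", "n"), 500, TRUE),
                      collapse = ""),
            y = paste(sample(c("a", "C", "t", "G"), 123, TRUE), collapse = ""))
  fa <- tmp_fasta(seqs, width = 37L)
  for (level in c("hard", "none")) {
    once <- tempfile(fileext = ".fa")
    twice <- tempfile(fileext = ".fa")
    apply_masking(fa, level, once)
    changed_again <- apply_masking(once, level, twice)
    expect_equal(as.integer(changed_again), 0L)
    expect_identical(readLines(once), readLines(twice))
    m <- read_fasta(once)
    expect_equal(nchar(m), nchar(seqs))          # lengths preserved
    expect_equal(names(m), names(seqs))          # headers preserved
    # uppercase ACGT positions never altered
    up <- gregexpr("[ACGT]", seqs[["x"]])[[1]]
    orig <- strsplit(seqs[["x"]], "")[[1]]
    new <- strsplit(m[["x"]], "")[[1]]
    expect_identical(new[up], orig[up])
  }
})

test_that("regex contig filtering partitions the contig set", {
  seqs <- c(chr1 = "AAAA", chr2 = "CCCC", chrM = "GGGG", scaffold_1 = "TTTT")
  fa <- tmp_fasta(seqs, width = 4L)
  out <- tempfile(fileext = ".fa")
  res <- filter_contigs(fa, "^chr", keep_matches = TRUE, fasta_out = out)
  expect_setequal(res$kept, c("chr1", "chr2", "chrM"))
  expect_equal(res$removed, "scaffold_1")
  inv <- filter_contigs(fa, "^chr", keep_matches = FALSE,
                        fasta_out = tempfile(fileext = ".fa"))
  expect_equal(inv$kept, "scaffold_1")
  expect_setequal(c(res$kept, inv$kept), names(seqs))
  expect_length(intersect(res$kept, inv$kept), 0L)
  all_out <- tempfile(fileext = ".fa")
  keep_all <- filter_contigs(fa, ".*", TRUE, all_out)
  expect_equal(keep_all$kept, names(seqs))
  expect_identical(readLines(all_out), readLines(fa))
  expect_error(filter_contigs(fa, "([", TRUE, out),
               class = "refsmith_invalid_query")
  expect_warning(filter_contigs(fa, "^nomatch$", TRUE, out), "no contigs")
})

test_that("alt-locus contigs are recognized by their name patterns", {
  seqs <- c(chr1 = "AAAA", chr5_GL339449v2_alt = "CCCC",
            chr6_apd_hap1 = "GGGG", chrUn_KN149696v1 = "TTTT")
  fa <- tmp_fasta(seqs, width = 4L)
  out <- tempfile(fileext = ".fa")
  removed <- exclude_alt_contigs(fa, out)
  expect_setequal(removed, c("chr5_GL339449v2_alt", "chr6_apd_hap1"))
  expect_equal(names(read_fasta(out)), c("chr1", "chrUn_KN149696v1"))
  # genome without alts: byte-identical records
  fa2 <- tmp_fasta(c(chr1 = "AAAA", chr2 = "CC"), width = 4L)
  out2 <- tempfile(fileext = ".fa")
  expect_length(exclude_alt_contigs(fa2, out2), 0L)
  expect_identical(readLines(out2), readLines(fa2))
})

test_that("contig sizes agree with brute-force character counts", {
  seqs <- c(chr1 = "ACGTACGT", empty = "",
            chr2 = paste(rep("ACGTN", 30), collapse = ""))
  fa <- tmp_fasta(seqs, width = 13L)
  sizes <- compute_contig_sizes(build_index(fa))
  expect_equal(sizes$contig, names(seqs))
  expect_equal(sizes$length, unname(nchar(seqs)))
  expect_equal(sum(sizes$length), sum(nchar(seqs)))
})

test_that("gap detection finds exactly the maximal N runs", {
  fa <- tmp_fasta(c(c = "ACGTNNNACGT"), width = 5L)
  g <- compute_gaps(fa)
  expect_equal(g, data.frame(contig = "c", start = 4, end = 7))
  fa2 <- tmp_fasta(c(c = "NNN"), width = 80L)
  expect_equal(compute_gaps(fa2), data.frame(contig = "c", start = 0, end = 3))
  # randomized: equality with the character-walk oracle
  set.seed(5)
  seqs <- c(u = paste(sample(c("A", "N", "n", "C"), 400, TRUE), collapse = ""),
            v = paste(sample(c("G", "T"), 100, TRUE), collapse = ""))
  fa3 <- tmp_fasta(seqs, width = 21L)
  got <- compute_gaps(fa3)
  want <- oracle_gaps(seqs)
  expect_equal(got, want, ignore_attr = TRUE)
  # disjoint + maximal: total length equals brute-force N count
  expect_equal(sum(got$end - got$start),
               sum(nchar(gsub("[^Nn]", "", seqs))))
  if (nrow(got) > 1) {
    by_ctg <- split(got, got$contig)
    for (b in by_ctg)
      if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
})

test_that("random regions are deterministic, in-bounds and length-proportional", {
  expect_length(random_regions(build_index(tmp_fasta(c(a = "ACGTACGTAA"))),
                               0, 5), 0L)
  # single valid start: the unique full-contig region for any seed
  fa1 <- tmp_fasta(c(one = "ACGTACGTAA"), width = 10L)
  idx1 <- build_index(fa1)
  for (seed in c(1, 99)) {
    r <- random_regions(idx1, 3, 10, seed = seed)
    expect_true(all(vapply(r, function(x)
      x$contig == "one" && x$start == 0 && x$end == 10, logical(1))))
  }
  # determinism: pure function of the seed
  set.seed(1001)
  seqs <- c(s1 = paste(sample(c("A", "C"), 1000, TRUE), collapse = ""),
            s2 = paste(sample(c("G", "T"), 3000, TRUE), collapse = ""))
  fa <- tmp_fasta(seqs, width = 70L)
  idx <- build_index(fa)
  expect_identical(random_regions(idx, 50, 100, seed = 3),
                   random_regions(idx, 50, 100, seed = 3))
  # contig picked proportionally to its valid start count (3 sigma)
  n <- 10000L
  regs <- random_regions(idx, n, 100, seed = 5)
  expect_true(all(vapply(regs, function(r)
    r$end - r$start == 100 && r$start >= 0 &&
      r$end <= nchar(seqs[[r$contig]]), logical(1))))
  p2 <- 2901 / (901 + 2901)
  frac2 <- mean(vapply(regs, function(r) r$contig == "s2", logical(1)))
  expect_lt(abs(frac2 - p2), 3 * sqrt(p2 * (1 - p2) / n))
  # infeasible length
  expect_error(random_regions(idx, 1, 5000), class = "refsmith_infeasible")
})

test_that("gap exclusion removes exactly the overlapping start positions", {
  seqs <- c(g = paste0(strrep("A", 100), strrep("N", 50), strrep("C", 100)))
  fa <- tmp_fasta(seqs, width = 80L)
  idx <- build_index(fa)
  gaps <- compute_gaps(fa)
  expect_equal(gaps$start, 100)
  regs <- random_regions(idx, 2000, 20, seed = 2, exclude_gaps = TRUE,
                         gaps = gaps)
  overlaps <- vapply(regs, function(r)
    r$start < 150 && r$end > 100, logical(1))
  expect_false(any(overlaps))
  # valid starts: [0,80] and [150,230] -> starts never in 81..149
  expect_true(all(vapply(regs, function(r)
    r$start <= 80 || r$start >= 150, logical(1))))
})
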