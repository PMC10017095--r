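# Genome FASTA computations: byte-offset indexing, random access, masking
# transforms, contig filtering, contig sizes and assembly-gap detection.
#
# Coordinates are 0-based half-open internally; user-facing region strings
# ("chr1:1-100") are 1-based fully closed and converted at the boundary.

read_file_bytes <- function(path, n = Inf) {
  con <- if (is_gzip(path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  chunks <- list()
  left <- n
  repeat {
    take <- as.integer(min(left, 1e7))
    if (take <= 0L) break
    b <- readBin(con, "raw", n = take)
    if (!length(b)) break
    chunks[[length(chunks) + 1L]] <- b
    left <- left - length(b)
  }
  if (!length(chunks)) raw(0) else do.call(c, chunks)
}

#' Build a byte-offset index of a genome FASTA
#'
#' Records, per contig, the sequence length, the byte offset of the first
#' sequence byte and the line geometry (bases and bytes per line) of the
#' uncompressed stream, enabling O(1) random access.  The on-disk form
#' ([write_genome_index()]) follows the faidx 5-column layout.
#'
#' @param fasta Path to a FASTA file, optionally gzip-compressed (offsets
#'   then refer to the uncompressed stream).
#' @return A `genome_index`: data frame with columns `contig`, `length`,
#'   `offset`, `bases_per_line`, `bytes_per_line`.
#' @export
build_index <- function(fasta) {
  txt <- rawToChar(read_file_bytes(fasta))
  eol_len <- if (grepl("\r\n", txt, fixed = TRUE)) 2L else 1L
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (eol_len == 2L) lines <- sub("\r$", "", lines)
  if (!length(lines)) {
    return(structure(data.frame(contig = character(0), length = integer(0),
                                offset = numeric(0), bases_per_line = integer(0),
                                bytes_per_line = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("genome_index", "data.frame"), fasta = fasta))
  }
  if (!startsWith(lines[1], ">"))
    rs_stop("refsmith_format", fasta, ": FASTA does not start with '>'")
  nb <- nchar(lines, type = "bytes")
  line_offset <- cumsum(c(0, nb + eol_len))[seq_along(lines)]
  hdr <- startsWith(lines, ">")
  hdr_idx <- which(hdr)
  contigs <- header_token(sub("^>", "", lines[hdr_idx]))
  if (anyDuplicated(contigs))
    rs_stop("refsmith_integrity", fasta, ": duplicate contig name(s): ",
            paste(unique(contigs[duplicated(contigs)]), collapse = ", "))
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  entries <- lapply(seq_along(hdr_idx), function(i) {
    first <- hdr_idx[i] + 1L
    last <- ends[i]
    if (first > last) {
      return(list(contig = contigs[i], length = 0L,
                  offset = line_offset[hdr_idx[i]] + nb[hdr_idx[i]] + eol_len,
                  bases_per_line = 0L, bytes_per_line = 0L))
    }
    widths <- nb[first:last]
    if (last > first && any(widths[-length(widths)] != widths[1])) {
      bad <- (first:last)[which(widths[-length(widths)] != widths[1])[1]]
      rs_stop("refsmith_format", fasta, ": ragged sequence lines in contig '",
              contigs[i], "' at line ", bad)
    }
    if (widths[length(widths)] > widths[1])
      rs_stop("refsmith_format", fasta, ": last line longer than wrap width in contig '",
              contigs[i], "' at line ", last)
    list(contig = contigs[i], length = sum(widths),
         offset = line_offset[first],
         bases_per_line = widths[1], bytes_per_line = widths[1] + eol_len)
  })
  idx <- do.call(rbind.data.frame, c(entries, stringsAsFactors = FALSE))
  structure(idx, class = c("genome_index", "data.frame"), fasta = fasta)
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> ", nrow(x), " contig(s), ",
      format(sum(x$length), big.mark = ","), " bases\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write / read a genome index (faidx-compatible 5-column TSV)
#'
#' @param index A `genome_index`.
#' @param path Output path (conventionally `<genome>.fa.fai`).
#' @return `path` (write) or the reloaded `genome_index` (read).
#' @export
write_genome_index <- function(index, path) {
  lines <- sprintf("%s\t%d\t%.0f\t%d\t%d", index$contig, index$length,
                   index$offset, index$bases_per_line, index$bytes_per_line)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genome_index
#' @param fasta FASTA path to associate with the reloaded index.
#' @export
read_genome_index <- function(path, fasta = NULL) {
  lines <- read_text_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 5L))
    rs_stop("refsmith_format", path, ": index lines must have 5 fields")
  idx <- data.frame(
    contig = vapply(parts, `[`, character(1), 1L),
    length = as.integer(vapply(parts, `[`, character(1), 2L)),
    offset = as.numeric(vapply(parts, `[`, character(1), 3L)),
    bases_per_line = as.integer(vapply(parts, `[`, character(1), 4L)),
    bytes_per_line = as.integer(vapply(parts, `[`, character(1), 5L)),
    stringsAsFactors = FALSE)
  structure(idx, class = c("genome_index", "data.frame"), fasta = fasta)
}

#' Construct a genomic region
#'
#' @param contig Contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand `"+"` or `"-"`.
#' @return A `region` list.
#' @export
region <- function(contig, start, end, strand = "+") {
  stopifnot(strand %in% c("+", "-"), start >= 0, end >= start)
  structure(list(contig = contig, start = as.numeric(start),
                 end = as.numeric(end), strand = strand), class = "region")
}

#' Parse a 1-based closed region string ("chr1:1-100") into a region
#'
#' @param text Region string in the samtools convention (1-based, both ends
#'   included); a bare contig name means the whole contig.
#' @param index Optional `genome_index` used to resolve bare contig names.
#' @param strand Strand of the resulting region.
#' @return A `region` (internal 0-based half-open coordinates).
#' @export
parse_region <- function(text, index = NULL, strand = "+") {
  m <- regmatches(text, regexec("^(.+):([0-9]+)-([0-9]+)$", text))[[1]]
  if (length(m) == 4L)
    return(region(m[2], as.numeric(m[3]) - 1, as.numeric(m[4]), strand))
  if (!is.null(index) && text %in% index$contig)
    return(region(text, 0, index$length[match(text, index$contig)], strand))
  rs_stop("refsmith_invalid_query", "cannot parse region '", text, "'")
}

#' Format a region back into the 1-based closed string convention
#' @param x A `region`.
#' @export
format.region <- function(x, ...) {
  sprintf("%s:%.0f-%.0f(%s)", x$contig, x$start + 1, x$end, x$strand)
}

#' @export
print.region <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

base_byte <- function(entry, i) {
  entry$offset + (i %/% entry$bases_per_line) * entry$bytes_per_line +
    i %% entry$bases_per_line
}

#' Extract a sequence from an indexed FASTA
#'
#' Seeks directly to the byte range covering the region and strips line
#' terminators; minus-strand regions are reverse-complemented (IUPAC-aware,
#' case preserved).  Out-of-bounds requests are errors, never clamped.
#'
#' @param index A `genome_index` for `fasta`.
#' @param fasta The FASTA path the index was built from.
#' @param region A `region` (0-based half-open), or a 1-based region string.
#' @return The sequence as a single string.
#' @export
extract_sequence <- function(index, fasta, region) {
  if (is.character(region)) region <- parse_region(region, index)
  i <- match(region$contig, index$contig)
  if (is.na(i))
    rs_stop("refsmith_not_found", "unknown contig '", region$contig, "'")
  entry <- index[i, ]
  if (region$start < 0 || region$end > entry$length)
    rs_stop("refsmith_bounds", "region ", format(region),
            " outside contig bounds [0,", entry$length, ")")
  if (region$end == region$start) return("")
  first <- base_byte(entry, region$start)
  last <- base_byte(entry, region$end - 1)
  n <- last - first + 1
  if (is_gzip(fasta)) {
    con <- gzfile(fasta, "rb")
    on.exit(close(con))
    skip <- first
    while (skip > 0) {
      got <- readBin(con, "raw", n = as.integer(min(skip, 1e7)))
      skip <- skip - length(got)
    }
    chunk <- rawToChar(readBin(con, "raw", n = as.integer(n)))
  } else {
    con <- file(fasta, "rb")
    on.exit(close(con))
    seek(con, where = first, origin = "start")
    chunk <- rawToChar(readBin(con, "raw", n = as.integer(n)))
  }
  s <- gsub("[\r\n]", "", chunk)
  if (region$strand == "-") reverse_complement(s) else s
}

# Allowed start intervals (0-based, half-open on starts) per contig for
# regions of a given length, optionally excluding gap overlap.
valid_start_intervals <- function(index, length, exclude_gaps, gaps) {
  out <- list()
  for (i in seq_len(nrow(index))) {
    len <- index$length[i]
    if (len < length) next
    lo <- 0
    hi <- len - length + 1  # starts in [0, hi)
    allowed <- matrix(c(lo, hi), ncol = 2)
    if (exclude_gaps && !is.null(gaps) && nrow(gaps)) {
      g <- gaps[gaps$contig == index$contig[i], , drop = FALSE]
      for (j in seq_len(nrow(g))) {
        fs <- max(lo, g$start[j] - length + 1)
        fe <- min(hi, g$end[j])  # forbidden starts [fs, fe)
        if (fe <= fs) next
        pieces <- list()
        for (k in seq_len(nrow(allowed))) {
          a <- allowed[k, 1]; b <- allowed[k, 2]
          if (fe <= a || fs >= b) { pieces[[length(pieces) + 1L]] <- c(a, b); next }
          if (a < fs) pieces[[length(pieces) + 1L]] <- c(a, fs)
          if (fe < b) pieces[[length(pieces) + 1L]] <- c(fe, b)
        }
        allowed <- if (length(pieces)) do.call(rbind, pieces) else
          matrix(numeric(0), ncol = 2)
      }
    }
    if (nrow(allowed))
      out[[length(out) + 1L]] <- data.frame(contig = index$contig[i],
                                            from = allowed[, 1], to = allowed[, 2],
                                            stringsAsFactors = FALSE)
  }
  if (!length(out)) data.frame(contig = character(0), from = numeric(0),
                               to = numeric(0), stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

#' Sample random regions from a genome
#'
#' Draws start positions uniformly from the pool of all valid starts across
#' contigs, so each contig is chosen with probability proportional to its
#' number of valid start positions.  Deterministic for a given seed.
#'
#' @param index A `genome_index`.
#' @param n Number of regions (0 allowed).
#' @param length Region length in bases.
#' @param seed Integer seed; same seed, same output.
#' @param exclude_gaps If `TRUE`, no returned region overlaps a gap.
#' @param gaps Gap records from [compute_gaps()] (required when
#'   `exclude_gaps` is `TRUE`).
#' @return List of `region` objects (plus strand).
#' @export
random_regions <- function(index, n, length, seed = 1L,
                           exclude_gaps = FALSE, gaps = NULL) {
  stopifnot(n >= 0, length >= 1)
  if (exclude_gaps && is.null(gaps))
    rs_stop("refsmith_invalid_query", "exclude_gaps=TRUE requires gap records")
  pool <- valid_start_intervals(index, length, exclude_gaps, gaps)
  sizes <- pool$to - pool$from
  total <- sum(sizes)
  if (n > 0 && total == 0)
    rs_stop("refsmith_infeasible", "no valid start position for length ", length)
  if (n == 0) return(list())
  cum <- cumsum(sizes)
  draws <- with_seed(seed, sample.int(total, n, replace = TRUE))
  lapply(draws, function(d) {
    k <- findInterval(d - 1, cum) + 1L  # d in (cum[k-1], cum[k]]
    start <- pool$from[k] + (d - 1 - c(0, cum)[k])
    region(pool$contig[k], start, start + length, "+")
  })
}

#' Apply a masking level to a genome FASTA
#'
#' `soft` copies the file unchanged (soft masking is the lowercase already
#' present); `hard` replaces every lowercase base with uppercase `N`;
#' `none` uppercases every lowercase base.  Headers, line wrapping and
#' sequence lengths are never altered.
#'
#' @param fasta_in Input FASTA (optionally gzipped).
#' @param level One of `"soft"`, `"hard"`, `"none"`.
#' @param fasta_out Output path (`.gz` suffix compresses).
#' @return Invisibly, the number of bases changed.
#' @export
apply_masking <- function(fasta_in, level = c("soft", "hard", "none"),
                          fasta_out) {
  level <- match.arg(level)
  lines <- read_text_lines(fasta_in)
  is_seq <- !startsWith(lines, ">")
  changed <- 0L
  if (level != "soft") {
    lower <- sum(nchar(gsub("[^a-z]", "", lines[is_seq])))
    lines[is_seq] <- if (level == "hard")
      gsub("[a-z]", "N", lines[is_seq]) else toupper(lines[is_seq])
    changed <- lower
  }
  con <- if (grepl("\\.gz$", fasta_out)) gzfile(fasta_out, "wt")
  else file(fasta_out, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(changed)
}

compile_regex <- function(pattern) {
  ok <- tryCatch({ grepl(pattern, ""); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) rs_stop("refsmith_invalid_query", "invalid regex: ", pattern)
  pattern
}

split_fasta_records <- function(lines) {
  if (length(lines) && !startsWith(lines[1], ">"))
    rs_stop("refsmith_format", "FASTA does not start with '>'")
  hdr_idx <- which(startsWith(lines, ">"))
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  lapply(seq_along(hdr_idx), function(i) {
    list(token = header_token(sub("^>", "", lines[hdr_idx[i]])),
         lines = lines[hdr_idx[i]:ends[i]])
  })
}

write_records <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (r in records) writeLines(r$lines, con)
  invisible(path)
}

#' Filter contigs by a regex on the header token
#'
#' The pattern is searched (unanchored) against the first whitespace-delimited
#' word of each header.  Kept records are written verbatim, in input order.
#'
#' @param fasta_in,fasta_out Input/output FASTA paths.
#' @param pattern Regular expression.
#' @param keep_matches `TRUE` keeps matching contigs, `FALSE` keeps the rest.
#' @return List with `kept` and `removed` contig-name vectors.
#' @export
filter_contigs <- function(fasta_in, pattern, keep_matches = TRUE, fasta_out) {
  compile_regex(pattern)
  records <- split_fasta_records(read_text_lines(fasta_in))
  tokens <- vapply(records, `[[`, character(1), "token")
  matched <- grepl(pattern, tokens)
  keep <- if (keep_matches) matched else !matched
  if (!any(keep)) rs_warn("no contigs kept by pattern '", pattern, "'")
  write_records(records[keep], fasta_out)
  list(kept = tokens[keep], removed = tokens[!keep])
}

# Name patterns identifying alternate-locus contigs.  Purely name-based
# (providers do not ship a machine-readable alt flag in FASTA); overridable.
ALT_CONTIG_PATTERNS <- c("_alt", "alt$", "hap[0-9]")

is_alt_contig <- function(tokens, patterns = ALT_CONTIG_PATTERNS) {
  Reduce(`|`, lapply(patterns, function(p)
    grepl(p, tokens, ignore.case = TRUE)), rep(FALSE, length(tokens)))
}

#' Remove alternate-locus contigs from a genome FASTA
#'
#' Alt contigs (divergent haplotypes duplicated in the primary assembly,
#' which cause multi-mapping during alignment) are recognized by header-name
#' patterns: a `_alt` substring, an `alt` suffix, or `hap` followed by a
#' digit, all case-insensitive.
#'
#' @param fasta_in,fasta_out Input/output FASTA paths.
#' @param patterns Override the default name patterns.
#' @return Character vector of removed contig names.
#' @export
exclude_alt_contigs <- function(fasta_in, fasta_out,
                                patterns = ALT_CONTIG_PATTERNS) {
  records <- split_fasta_records(read_text_lines(fasta_in))
  tokens <- vapply(records, `[[`, character(1), "token")
  alt <- is_alt_contig(tokens, patterns)
  write_records(records[!alt], fasta_out)
  tokens[alt]
}

#' Contig sizes from a genome index
#'
#' @param index A `genome_index`.
#' @return Data frame (`contig`, `length`) in genome file order.
#' @export
compute_contig_sizes <- function(index) {
  data.frame(contig = index$contig, length = index$length,
             stringsAsFactors = FALSE)
}

#' @rdname compute_contig_sizes
#' @param sizes Result of `compute_contig_sizes`.
#' @param path Output path for the 2-column TSV.
#' @export
write_contig_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", sizes$contig, sizes$length), path)
  invisible(path)
}

#' Detect assembly gaps (maximal runs of N) in a genome FASTA
#'
#' A gap is a maximal run of `N`/`n` of length >= 1; other IUPAC ambiguity
#' codes are not gaps.  Intervals are 0-based half-open, sorted by contig
#' file order then start.
#'
#' @param fasta FASTA path.
#' @return Data frame (`contig`, `start`, `end`).
#' @export
compute_gaps <- function(fasta) {
  seqs <- read_fasta(fasta)
  names(seqs) <- header_token(names(seqs))
  out <- lapply(names(seqs), function(ctg) {
    m <- gregexpr("[Nn]+", seqs[[ctg]])[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(contig = ctg, start = as.numeric(m) - 1,
               end = as.numeric(m) - 1 + attr(m, "match.length"),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @rdname compute_gaps
#' @param gaps Result of `compute_gaps`.
#' @param path Output path for the 3-column BED (0-based half-open).
#' @export
write_gaps <- function(gaps, path) {
  writeLines(sprintf("%s\t%.0f\t%.0f", gaps$contig, gaps$start, gaps$end), path)
  invisible(path)
}
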