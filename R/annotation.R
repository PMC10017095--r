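# Gene-annotation processing.  GFF3, GTF and BED12 are all read into a
# common transcript-centric model (exon intervals ascending, CDS span,
# 0-based half-open coordinates) which is the pivot for every conversion.
# GTF/GFF3 use 1-based closed coordinates on disk; BED12 is 0-based
# half-open; conversion happens at the parse/emit boundary only.

new_transcript <- function(transcript_id, gene_id, gene_name, contig, strand,
                           exons, cds = NULL, attributes = character(0),
                           lines = integer(0)) {
  exons <- matrix(as.numeric(exons), ncol = 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (!nrow(exons))
    rs_stop("refsmith_integrity", "transcript '", transcript_id, "' has no exons")
  if (any(exons[, 2] <= exons[, 1]))
    rs_stop("refsmith_integrity", "transcript '", transcript_id,
            "': empty or inverted exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    rs_stop("refsmith_integrity", "transcript '", transcript_id,
            "': overlapping exons")
  if (!is.null(cds)) {
    cds <- unname(as.numeric(cds))
    if (cds[1] < exons[1, 1] || cds[2] > exons[nrow(exons), 2])
      rs_stop("refsmith_integrity", "transcript '", transcript_id,
              "': CDS outside transcript span")
  }
  list(transcript_id = transcript_id, gene_id = gene_id,
       gene_name = gene_name, contig = contig, strand = strand,
       exons = unname(exons), cds = cds, attributes = attributes,
       lines = lines)
}

new_annotation_table <- function(transcripts, source_format, contig_order) {
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids))
    rs_stop("refsmith_integrity", "duplicate transcript id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  structure(list(transcripts = transcripts, source_format = source_format,
                 contig_order = contig_order),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  n_exons <- vapply(x$transcripts, function(t) nrow(t$exons), integer(1))
  cat("<annotation_table> ", length(x$transcripts), " transcript(s) on ",
      length(x$contig_order), " contig(s) [source: ", x$source_format, "]\n",
      "  exons per transcript: ",
      if (length(n_exons)) paste0(min(n_exons), "-", max(n_exons)) else "-",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.annotation_table <- function(object, ...) {
  data.frame(
    transcript_id = names(object$transcripts),
    gene_id = vapply(object$transcripts, `[[`, character(1), "gene_id"),
    contig = vapply(object$transcripts, `[[`, character(1), "contig"),
    strand = vapply(object$transcripts, `[[`, character(1), "strand"),
    n_exons = vapply(object$transcripts, function(t) nrow(t$exons), integer(1)),
    has_cds = vapply(object$transcripts, function(t) !is.null(t$cds), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

attr_get <- function(attrs, key) {
  if (key %in% names(attrs)) attrs[[key]] else NULL
}

## ---- GTF ------------------------------------------------------------------

parse_gtf_attributes <- function(text, where) {
  if (grepl('\\\\"', text))
    rs_stop("refsmith_format", where,
            ": escaped quotes in GTF attributes are not supported")
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_.]*)\\s+"([^"]*)"\\s*;?', text)[[1]]
  if (m[1] == -1) return(character(0))
  pieces <- regmatches(text, list(m))[[1]]
  keys <- sub('^([A-Za-z_][A-Za-z0-9_.]*)\\s+.*$', "\\1", pieces)
  vals <- sub('^[^"]*"([^"]*)".*$', "\\1", pieces)
  stats::setNames(vals, keys)
}

split_columns <- function(line, path, ln, n = 9L) {
  cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(cols) < n)
    rs_stop("refsmith_format", path, " line ", ln, ": expected ", n,
            " tab-separated fields, got ", length(cols))
  cols
}

assemble_transcripts <- function(feats, path) {
  # feats: list of (id, gene_id, gene_name, contig, strand, type, start0,
  # end0, attrs, line) for exon/CDS features already resolved to an id
  by_id <- split(seq_along(feats), vapply(feats, `[[`, character(1), "id"))
  transcripts <- vector("list", length(by_id))
  first_line <- integer(length(by_id))
  for (i in seq_along(by_id)) {
    fs <- feats[by_id[[i]]]
    contigs <- unique(vapply(fs, `[[`, character(1), "contig"))
    id <- fs[[1]]$id
    if (length(contigs) > 1)
      rs_stop("refsmith_integrity", path, ": transcript '", id,
              "' spans multiple contigs: ", paste(contigs, collapse = ", "))
    is_exon <- vapply(fs, function(f) f$type == "exon", logical(1))
    if (!any(is_exon))
      rs_stop("refsmith_format", path, ": transcript '", id, "' has no exons")
    exons <- do.call(rbind, lapply(fs[is_exon], function(f) c(f$start0, f$end0)))
    cds_f <- fs[!is_exon]
    cds <- if (length(cds_f)) {
      c(min(vapply(cds_f, `[[`, numeric(1), "start0")),
        max(vapply(cds_f, `[[`, numeric(1), "end0")))
    } else NULL
    gname <- Filter(Negate(is.na), vapply(fs, `[[`, character(1), "gene_name"))
    attrs <- fs[[which(is_exon)[1]]]$attrs
    attrs <- attrs[setdiff(names(attrs), c("exon_number", "exon_id"))]
    transcripts[[i]] <- new_transcript(
      transcript_id = id,
      gene_id = fs[[1]]$gene_id,
      gene_name = if (length(gname)) gname[[1]] else NA_character_,
      contig = contigs, strand = fs[[1]]$strand,
      exons = exons, cds = cds, attributes = attrs,
      lines = vapply(fs, `[[`, integer(1), "line"))
    first_line[i] <- min(transcripts[[i]]$lines)
  }
  transcripts[order(first_line)]
}

#' Read a GTF gene annotation
#'
#' Transcripts are assembled by grouping `exon` features on their
#' `transcript_id` attribute; the CDS span is the min/max over `CDS`
#' features.  1-based closed coordinates are converted to the internal
#' 0-based half-open convention.  Comment lines (`#`) are skipped.
#'
#' @param path GTF path (optionally gzipped).
#' @return An `annotation_table`.
#' @export
read_gtf <- function(path) {
  lines <- read_text_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  feats <- list()
  contig_order <- character(0)
  saw_feature <- FALSE
  for (ln in which(keep)) {
    cols <- split_columns(lines[ln], path, ln)
    saw_feature <- TRUE
    type <- cols[3]
    if (!(type %in% c("exon", "CDS"))) next
    attrs <- parse_gtf_attributes(cols[9], paste0(path, " line ", ln))
    tid <- attr_get(attrs, "transcript_id")
    if (is.null(tid) || is.na(tid) || !nzchar(tid))
      rs_stop("refsmith_format", path, " line ", ln,
              ": ", type, " feature lacks transcript_id")
    if (!(cols[1] %in% contig_order))
      contig_order <- c(contig_order, cols[1])
    feats[[length(feats) + 1L]] <- list(
      id = tid,
      gene_id = if (!is.null(attr_get(attrs, "gene_id")))
        attrs[["gene_id"]] else tid,
      gene_name = if (!is.null(attr_get(attrs, "gene_name")))
        attrs[["gene_name"]] else NA_character_,
      contig = cols[1], strand = cols[7], type = type,
      start0 = as.numeric(cols[4]) - 1, end0 = as.numeric(cols[5]),
      attrs = attrs, line = ln)
  }
  if (!length(feats) && saw_feature)
    rs_warn(path, ": no exon features found; 0 transcripts")
  new_annotation_table(assemble_transcripts(feats, path), "gtf", contig_order)
}

## ---- GFF3 -----------------------------------------------------------------

GFF3_DECODE <- c("%3B" = ";", "%3D" = "=", "%26" = "&", "%2C" = ",",
                 "%09" = "\t", "%25" = "%")
GFF3_ENCODE <- c(";" = "%3B", "=" = "%3D", "&" = "%26", "," = "%2C",
                 "\t" = "%09")

gff3_decode <- function(x) {
  # %25 last so decoded percents are not re-interpreted
  for (code in c(setdiff(names(GFF3_DECODE), "%25"), "%25"))
    x <- gsub(code, GFF3_DECODE[[code]], x, fixed = TRUE)
  x
}

gff3_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  for (ch in names(GFF3_ENCODE))
    x <- gsub(ch, GFF3_ENCODE[[ch]], x, fixed = TRUE)
  x
}

parse_gff3_attributes <- function(text) {
  if (!nzchar(text) || text == ".") return(character(0))
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  keys <- sub("=.*$", "", parts)
  vals <- gff3_decode(sub("^[^=]*=", "", parts))
  stats::setNames(vals, trimws2(keys))
}

TRANSCRIPT_TYPES <- c("mRNA", "transcript", "ncRNA", "tRNA", "rRNA",
                      "snoRNA", "snRNA", "miRNA", "lnc_RNA", "pseudogenic_transcript")

#' Read a GFF3 gene annotation
#'
#' Transcripts are assembled through the `ID`/`Parent` feature graph
#' (forward references allowed; an exon listing several parents is attached
#' to each).  Reserved-character percent-encoding in attribute values is
#' decoded.  Coordinates are converted as for GTF.
#'
#' @param path GFF3 path (optionally gzipped).
#' @return An `annotation_table`.
#' @export
read_gff3 <- function(path) {
  lines <- read_text_lines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  features <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    ln <- keep[j]
    cols <- split_columns(lines[ln], path, ln)
    features[[j]] <- list(contig = cols[1], type = cols[3],
                          start0 = as.numeric(cols[4]) - 1,
                          end0 = as.numeric(cols[5]), strand = cols[7],
                          attrs = parse_gff3_attributes(cols[9]), line = ln)
  }
  ids <- vapply(features, function(f) {
    v <- attr_get(f$attrs, "ID"); if (is.null(v)) NA_character_ else v
  }, character(1))
  by_id <- stats::setNames(features, ids)[!is.na(ids)]
  # detect Parent cycles
  for (id in names(by_id)) {
    seen <- character(0)
    cur <- id
    while (!is.na(cur) && cur %in% names(by_id)) {
      if (cur %in% seen)
        rs_stop("refsmith_integrity", path, ": cyclic Parent links at '", cur, "'")
      seen <- c(seen, cur)
      p <- attr_get(by_id[[cur]]$attrs, "Parent")
      cur <- if (is.null(p)) NA_character_ else strsplit(p, ",", fixed = TRUE)[[1]][1]
    }
  }
  resolve_gene <- function(tr) {
    p <- attr_get(tr$attrs, "Parent")
    gid <- attr_get(tr$attrs, "gene_id")
    gene <- if (!is.null(p) && p %in% names(by_id)) by_id[[p]] else NULL
    list(gene_id = if (!is.null(gid)) gid
                   else if (!is.null(gene)) attr_get(gene$attrs, "ID")
                   else attr_get(tr$attrs, "ID"),
         gene_name = {
           gn <- attr_get(tr$attrs, "gene_name")
           if (is.null(gn) && !is.null(gene)) gn <- attr_get(gene$attrs, "Name")
           if (is.null(gn)) NA_character_ else gn
         })
  }
  feats <- list()
  contig_order <- character(0)
  for (f in features) {
    if (!(f$type %in% c("exon", "CDS"))) next
    p <- attr_get(f$attrs, "Parent")
    if (is.null(p) || !nzchar(p))
      rs_stop("refsmith_format", path, " line ", f$line,
              ": ", f$type, " feature lacks a Parent")
    for (pid in strsplit(p, ",", fixed = TRUE)[[1]]) {
      tr <- by_id[[pid]]
      if (is.null(tr))
        rs_stop("refsmith_format", path, " line ", f$line,
                ": unresolvable Parent '", pid, "'")
      g <- resolve_gene(tr)
      if (!(f$contig %in% contig_order))
        contig_order <- c(contig_order, f$contig)
      feats[[length(feats) + 1L]] <- list(
        id = pid, gene_id = g$gene_id, gene_name = g$gene_name,
        contig = f$contig, strand = tr$strand, type = f$type,
        start0 = f$start0, end0 = f$end0,
        attrs = tr$attrs[setdiff(names(tr$attrs), c("ID", "Parent"))],
        line = f$line)
    }
  }
  if (!length(feats) && length(features))
    rs_warn(path, ": no exon features found; 0 transcripts")
  new_annotation_table(assemble_transcripts(feats, path), "gff3", contig_order)
}

## ---- BED12 ----------------------------------------------------------------

parse_int_list <- function(x) as.numeric(strsplit(sub(",$", "", x), ",")[[1]])

#' Read a BED12 gene annotation
#'
#' Exons are reconstructed from `chromStart` plus the block lists; the CDS
#' span comes from `thickStart`/`thickEnd` (equal values encode "no CDS").
#' The `name` column becomes both transcript and gene id.
#'
#' @param path BED12 path (optionally gzipped).
#' @return An `annotation_table`.
#' @export
read_bed12 <- function(path) {
  lines <- read_text_lines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  transcripts <- list()
  contig_order <- character(0)
  for (ln in keep) {
    cols <- split_columns(lines[ln], path, ln, n = 12L)
    chrom_start <- as.numeric(cols[2]); chrom_end <- as.numeric(cols[3])
    sizes <- parse_int_list(cols[11]); starts <- parse_int_list(cols[12])
    n_blocks <- as.integer(cols[10])
    if (length(sizes) != n_blocks || length(starts) != n_blocks)
      rs_stop("refsmith_format", path, " line ", ln,
              ": blockCount=", n_blocks, " but ", length(sizes), " sizes / ",
              length(starts), " starts")
    exons <- cbind(chrom_start + starts, chrom_start + starts + sizes)
    if (any(exons[, 2] > chrom_end) || any(exons[, 1] < chrom_start))
      rs_stop("refsmith_bounds", path, " line ", ln,
              ": blocks extend outside [chromStart, chromEnd)")
    thick <- c(as.numeric(cols[7]), as.numeric(cols[8]))
    cds <- if (thick[1] == thick[2]) NULL else thick
    if (!(cols[1] %in% contig_order)) contig_order <- c(contig_order, cols[1])
    transcripts[[length(transcripts) + 1L]] <- new_transcript(
      transcript_id = cols[4], gene_id = cols[4], gene_name = NA_character_,
      contig = cols[1], strand = cols[6], exons = exons, cds = cds,
      lines = ln)
  }
  new_annotation_table(transcripts, "bed12", contig_order)
}

## ---- Emitters -------------------------------------------------------------

sorted_transcripts <- function(table) {
  trs <- table$transcripts
  contig_rank <- match(vapply(trs, `[[`, character(1), "contig"),
                       table$contig_order)
  contig_rank[is.na(contig_rank)] <- length(table$contig_order) + 1L
  starts <- vapply(trs, function(t) t$exons[1, 1], numeric(1))
  trs[order(contig_rank, starts, names(trs), method = "radix")]
}

#' Render an annotation table as BED12 lines
#'
#' One line per transcript; blocks are the exons in ascending order
#' regardless of strand; `thickStart`/`thickEnd` carry the CDS span, or
#' `chromStart` twice when the transcript is non-coding (UCSC convention).
#' Lines are sorted by (contig order, chromStart, transcript id).
#'
#' @param table An `annotation_table`.
#' @return Character vector of BED12 lines.
#' @export
table_to_bed12 <- function(table) {
  vapply(sorted_transcripts(table), function(t) {
    ex <- t$exons
    cs <- ex[1, 1]; ce <- ex[nrow(ex), 2]
    thick <- if (is.null(t$cds)) c(cs, cs) else t$cds
    sprintf("%s\t%.0f\t%.0f\t%s\t0\t%s\t%.0f\t%.0f\t0\t%d\t%s\t%s",
            t$contig, cs, ce, t$transcript_id, t$strand, thick[1], thick[2],
            nrow(ex),
            paste(sprintf("%.0f", ex[, 2] - ex[, 1]), collapse = ","),
            paste(sprintf("%.0f", ex[, 1] - cs), collapse = ","))
  }, character(1), USE.NAMES = FALSE)
}

gtf_attr_string <- function(t, extra = character(0)) {
  a <- c(gene_id = t$gene_id, transcript_id = t$transcript_id)
  if (!is.na(t$gene_name)) a <- c(a, gene_name = t$gene_name)
  a <- c(a, extra)
  paste(sprintf('%s "%s";', names(a), a), collapse = " ")
}

#' Render an annotation table as GTF lines
#'
#' Emits `transcript`, `exon` and (for coding transcripts) `CDS` features
#' with `gene_id`/`transcript_id`/`gene_name` attributes.  The
#' `exon_number` attribute counts 1..n in transcription order, i.e. from the
#' rightmost exon for minus-strand transcripts.  Coordinates are emitted
#' 1-based closed.
#'
#' @param table An `annotation_table`.
#' @param source Value for the GTF source column.
#' @return Character vector of GTF lines.
#' @export
table_to_gtf <- function(table, source = "refsmith") {
  out <- character(0)
  for (t in sorted_transcripts(table)) {
    ex <- t$exons
    span <- c(ex[1, 1], ex[nrow(ex), 2])
    line <- function(type, s0, e0, attrs) {
      sprintf("%s\t%s\t%s\t%.0f\t%.0f\t.\t%s\t.\t%s",
              t$contig, source, type, s0 + 1, e0, t$strand, attrs)
    }
    out <- c(out, line("transcript", span[1], span[2], gtf_attr_string(t)))
    ord <- if (t$strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    for (k in seq_along(ord)) {
      i <- ord[k]
      out <- c(out, line("exon", ex[i, 1], ex[i, 2],
                         gtf_attr_string(t, c(exon_number = as.character(k)))))
    }
    if (!is.null(t$cds))
      out <- c(out, line("CDS", t$cds[1], t$cds[2], gtf_attr_string(t)))
  }
  out
}

#' Render an annotation table as GFF3 lines
#'
#' Emits a `gene` feature per gene id, an `mRNA` per transcript and `exon`/
#' `CDS` children linked through `ID`/`Parent`; reserved characters in
#' attribute values are percent-encoded.
#'
#' @param table An `annotation_table`.
#' @param source Value for the source column.
#' @return Character vector of GFF3 lines (with the version pragma).
#' @export
table_to_gff3 <- function(table, source = "refsmith") {
  out <- "##gff-version 3"
  trs <- sorted_transcripts(table)
  gene_ids <- vapply(trs, `[[`, character(1), "gene_id")
  emitted_genes <- character(0)
  line <- function(contig, type, s0, e0, strand, attrs) {
    sprintf("%s\t%s\t%s\t%.0f\t%.0f\t.\t%s\t.\t%s",
            contig, source, type, s0 + 1, e0, strand, attrs)
  }
  for (j in seq_along(trs)) {
    t <- trs[[j]]
    ex <- t$exons
    span <- c(ex[1, 1], ex[nrow(ex), 2])
    if (!(t$gene_id %in% emitted_genes)) {
      same <- trs[gene_ids == t$gene_id]
      gs <- min(vapply(same, function(x) x$exons[1, 1], numeric(1)))
      ge <- max(vapply(same, function(x) x$exons[nrow(x$exons), 2], numeric(1)))
      ga <- paste0("ID=", gff3_encode(t$gene_id))
      if (!is.na(t$gene_name))
        ga <- paste0(ga, ";Name=", gff3_encode(t$gene_name))
      out <- c(out, line(t$contig, "gene", gs, ge, t$strand, ga))
      emitted_genes <- c(emitted_genes, t$gene_id)
    }
    ta <- paste0("ID=", gff3_encode(t$transcript_id),
                 ";Parent=", gff3_encode(t$gene_id))
    if (!is.na(t$gene_name))
      ta <- paste0(ta, ";gene_name=", gff3_encode(t$gene_name))
    out <- c(out, line(t$contig, "mRNA", span[1], span[2], t$strand, ta))
    for (i in seq_len(nrow(ex)))
      out <- c(out, line(t$contig, "exon", ex[i, 1], ex[i, 2], t$strand,
                         paste0("ID=", gff3_encode(t$transcript_id), ".exon", i,
                                ";Parent=", gff3_encode(t$transcript_id))))
    if (!is.null(t$cds))
      out <- c(out, line(t$contig, "CDS", t$cds[1], t$cds[2], t$strand,
                         paste0("ID=", gff3_encode(t$transcript_id), ".cds",
                                ";Parent=", gff3_encode(t$transcript_id))))
  }
  out
}

#' Write an annotation table to disk in a chosen format
#'
#' @param table An `annotation_table`.
#' @param path Output path.
#' @param format `"gtf"`, `"bed12"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(table, path, format = c("gtf", "bed12", "gff3")) {
  format <- match.arg(format)
  lines <- switch(format, gtf = table_to_gtf(table),
                  bed12 = table_to_bed12(table), gff3 = table_to_gff3(table))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

## ---- Contig-name harmonization -------------------------------------------

#' Read a contig-alias table
#'
#' A TSV whose header names the naming schemes (e.g. `ucsc`, `ensembl`,
#' `ncbi`) and whose rows list, per physical contig, its name under each
#' scheme (empty cells allowed).
#'
#' @param path Alias-table path.
#' @return A `contig_alias_map`: list of per-contig groups, each a named
#'   character vector scheme -> name.
#' @export
read_alias_table <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) rs_stop("refsmith_format", path, ": empty alias table")
  schemes <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  groups <- lapply(lines[-1], function(l) {
    cells <- strsplit(l, "\t", fixed = TRUE)[[1]]
    length(cells) <- length(schemes)
    cells[is.na(cells)] <- ""
    g <- stats::setNames(cells, schemes)
    g[nzchar(g)]
  })
  all_names <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_names))
    rs_stop("refsmith_integrity", path, ": contig name(s) in multiple groups: ",
            paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  structure(list(groups = groups, schemes = schemes),
            class = "contig_alias_map")
}

#' @export
print.contig_alias_map <- function(x, ...) {
  cat("<contig_alias_map> ", length(x$groups), " group(s), schemes: ",
      paste(x$schemes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

match_contig_name <- function(name, genome_contigs, aliases) {
  if (name %in% genome_contigs) return(name)                       # rule 1
  if (!is.null(aliases)) {                                          # rule 2
    for (g in aliases$groups) {
      if (name %in% g) {
        hit <- intersect(g, genome_contigs)
        if (length(hit)) return(hit[1])
      }
    }
  }
  with_chr <- paste0("chr", name)                                   # rule 3
  if (with_chr %in% genome_contigs) return(with_chr)
  if (startsWith(name, "chr")) {
    bare <- sub("^chr", "", name)
    if (bare %in% genome_contigs) return(bare)
  }
  ci <- match(tolower(name), tolower(genome_contigs))               # rule 4
  if (!is.na(ci)) return(genome_contigs[ci])
  NA_character_
}

#' Harmonize annotation contig names against a genome
#'
#' Each annotation contig is renamed to a genome contig by the first
#' applicable rule: (1) exact match, (2) alias-group lookup, (3) `chr`
#' prefix added or removed, (4) case-insensitive match.  The mapping must be
#' injective; two annotation contigs resolving to the same genome contig is
#' an error.  Contigs that match no rule are left untouched and their
#' transcripts are reported as unmatched.
#'
#' @param table An `annotation_table`.
#' @param genome_contigs Character vector of genome contig names.
#' @param aliases Optional `contig_alias_map`.
#' @return List with `table` (renamed) and `report` (elements `map`,
#'   `unmatched`, `n_unmatched_transcripts`).
#' @export
harmonize_contig_names <- function(table, genome_contigs, aliases = NULL) {
  stopifnot(length(genome_contigs) > 0)
  ann_contigs <- unique(c(table$contig_order,
                          vapply(table$transcripts, `[[`, character(1), "contig")))
  mapped <- vapply(ann_contigs, match_contig_name, character(1),
                   genome_contigs = genome_contigs, aliases = aliases)
  ok <- !is.na(mapped)
  dup <- mapped[ok][duplicated(mapped[ok])]
  if (length(dup)) {
    offenders <- ann_contigs[ok][mapped[ok] %in% dup]
    rs_stop("refsmith_integrity", "ambiguous contig mapping: {",
            paste(offenders, collapse = ", "), "} all map onto {",
            paste(unique(dup), collapse = ", "), "}")
  }
  final <- ifelse(ok, mapped, ann_contigs)
  names(final) <- ann_contigs
  table$contig_order <- unname(final[table$contig_order])
  n_unmatched_tr <- 0L
  table$transcripts <- lapply(table$transcripts, function(t) {
    t$contig <- unname(final[[t$contig]])
    t
  })
  unmatched <- ann_contigs[!ok]
  n_unmatched_tr <- sum(vapply(table$transcripts, function(t)
    t$contig %in% unmatched, logical(1)))
  list(table = table,
       report = list(map = final[ok], unmatched = unmatched,
                     n_unmatched_transcripts = n_unmatched_tr))
}

#' Drop transcripts on contigs absent from the genome
#'
#' Applied after [harmonize_contig_names()]: any transcript still sitting on
#' a contig the genome does not contain is removed.
#'
#' @param table An `annotation_table`.
#' @param genome_contigs Character vector of genome contig names.
#' @return The filtered `annotation_table`; removed transcript ids are in
#'   `attr(, "removed_transcripts")`.
#' @export
filter_by_contigs <- function(table, genome_contigs) {
  on_genome <- vapply(table$transcripts, function(t)
    t$contig %in% genome_contigs, logical(1))
  removed <- names(table$transcripts)[!on_genome]
  table$transcripts <- table$transcripts[on_genome]
  table$contig_order <- intersect(table$contig_order, genome_contigs)
  attr(table, "removed_transcripts") <- removed
  table
}

## ---- Dictionaries and scheme maps ----------------------------------------

FIXED_FIELDS <- c("transcript_id", "gene_id", "gene_name", "contig", "strand")

field_value <- function(t, field) {
  if (field %in% FIXED_FIELDS) {
    v <- t[[field]]
    if (is.null(v) || is.na(v)) NA_character_ else v
  } else {
    v <- attr_get(t$attributes, field)
    if (is.null(v)) NA_character_ else v
  }
}

#' Build a dictionary between two annotation fields
#'
#' Either field may be a fixed column (`transcript_id`, `gene_id`,
#' `gene_name`, `contig`, `strand`) or any attribute key.  When one key maps
#' to conflicting values, the first occurrence wins and the conflict is
#' counted in `attr(, "conflicts")`.  Keys with a missing value are omitted.
#'
#' @param table An `annotation_table`.
#' @param key_field,value_field Field names.
#' @return Named character vector (key -> value).
#' @export
attribute_dictionary <- function(table, key_field, value_field) {
  avail <- unique(c(FIXED_FIELDS,
                    unlist(lapply(table$transcripts, function(t)
                      names(t$attributes)))))
  for (f in c(key_field, value_field)) {
    if (!(f %in% avail))
      rs_stop("refsmith_invalid_query", "unknown field '", f,
              "'; available fields: ", paste(avail, collapse = ", "))
  }
  dict <- character(0)
  conflicts <- 0L
  for (t in table$transcripts) {
    k <- field_value(t, key_field)
    v <- field_value(t, value_field)
    if (is.na(k) || is.na(v)) next
    if (k %in% names(dict)) {
      if (!identical(dict[[k]], v)) conflicts <- conflicts + 1L
    } else dict[[k]] <- v
  }
  attr(dict, "conflicts") <- conflicts
  dict
}

#' Map contig names into another provider's naming scheme
#'
#' @param names Character vector of contig names (any scheme).
#' @param aliases A `contig_alias_map`.
#' @param target_scheme A scheme label present in the alias map.
#' @return Named character vector; names with no alias group (or whose group
#'   lacks the target scheme) are `NA` and listed in `attr(, "unmapped")`.
#' @export
map_contig_scheme <- function(names, aliases, target_scheme) {
  if (!(target_scheme %in% aliases$schemes))
    rs_stop("refsmith_invalid_query", "unknown scheme '", target_scheme,
            "'; known schemes: ", paste(aliases$schemes, collapse = ", "))
  out <- vapply(names, function(nm) {
    for (g in aliases$groups) {
      if (nm %in% g) {
        v <- attr_get(g, target_scheme)
        return(if (is.null(v)) NA_character_ else v)
      }
    }
    NA_character_
  }, character(1))
  names(out) <- names
  attr(out, "unmapped") <- names[is.na(out)]
  out
}

## ---- Inspection -----------------------------------------------------------

#' Detect the format of an annotation file
#'
#' @param path Annotation path.
#' @return `"gtf"`, `"gff3"` or `"bed12"`.
#' @export
detect_annotation_format <- function(path) {
  lines <- read_text_lines(path)
  pragma <- lines[startsWith(lines, "##gff-version")]
  if (length(pragma)) return("gff3")
  data <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(data))
    rs_stop("refsmith_format", path, ": cannot detect format (no data lines)")
  cols <- strsplit(data[1], "\t", fixed = TRUE)[[1]]
  if (length(cols) == 12L &&
      !anyNA(suppressWarnings(as.numeric(cols[c(2, 3, 5, 7, 8, 10)]))))
    return("bed12")
  if (length(cols) >= 9L) {
    if (grepl('\\w+\\s+"', cols[9])) return("gtf")
    if (grepl("=", cols[9], fixed = TRUE)) return("gff3")
  }
  rs_stop("refsmith_format", path, ": unrecognized annotation format")
}

#' Preview the first lines of an annotation file
#'
#' @param path Annotation path (GFF3, GTF or BED12).
#' @param n_lines Number of non-comment lines to return.
#' @return List with `format` and `lines`.
#' @export
annotation_head <- function(path, n_lines = 5L) {
  fmt <- detect_annotation_format(path)
  lines <- read_text_lines(path)
  data <- lines[nzchar(lines) & !startsWith(lines, "#")]
  list(format = fmt, lines = utils::head(data, n_lines))
}

#' Read an annotation file of any recognized format
#'
#' Dispatches on [detect_annotation_format()].
#'
#' @param path Annotation path.
#' @return An `annotation_table`.
#' @export
read_annotation <- function(path) {
  switch(detect_annotation_format(path),
         gtf = read_gtf(path), gff3 = read_gff3(path), bed12 = read_bed12(path))
}
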