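# Assembly-metadata cache: loading, query classification, search, rendering.
#
# Each provider is a directory under the provider root holding a
# `metadata.tsv` table with the fixed header
#   name  accession  taxonomy_id  species  description  annotations
# where `description` is a |-separated list of free-text fields and
# `annotations` a comma-separated list of `label:0/1` flags (at least one
# label per provider; UCSC-style providers carry four).

METADATA_COLUMNS <- c("name", "accession", "taxonomy_id", "species",
                      "description", "annotations")
ACCESSION_REGEX <- "^GC[AF]_[0-9]{9}(\\.[0-9]+)?$"

#' Classify a search query
#'
#' The query type is recognized automatically: strings beginning with
#' `GCA_`/`GCF_` plus at least one digit (case-insensitive) are assembly
#' accessions, all-digit strings are taxonomy identifiers, anything else is
#' free text.  Numeric assembly names must be forced to text by the caller
#' (CLI flag `--as-text`).
#'
#' @param raw Query string; surrounding whitespace is ignored.
#' @param as_text Force classification as free text.
#' @return A list with elements `raw` (trimmed) and `query_type`
#'   (`"accession"`, `"taxonomy"` or `"text"`).
#' @examples
#' classify_query("GCA_000001405.15")$query_type  # accession
#' classify_query("7227")$query_type              # taxonomy
#' classify_query("zebrafish")$query_type         # text
#' @export
classify_query <- function(raw, as_text = FALSE) {
  raw <- trimws2(as.character(raw))
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw))
    rs_stop("refsmith_invalid_query", "empty search query")
  type <- if (as_text) "text"
  else if (grepl("^GC[AF]_[0-9]", raw, ignore.case = TRUE)) "accession"
  else if (grepl("^[0-9]+$", raw)) "taxonomy"
  else "text"
  structure(list(raw = raw, query_type = type), class = "search_query")
}

parse_annotation_flags <- function(x, where) {
  if (!nzchar(x))
    rs_stop("refsmith_integrity", where, ": empty annotation flag list")
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([^:]+):([01])$", parts))
  if (any(lengths(m) != 3L))
    rs_stop("refsmith_format", where, ": malformed annotation flags '", x, "'")
  labels <- vapply(m, `[`, character(1), 2L)
  avail <- vapply(m, `[`, character(1), 3L) == "1"
  names(avail) <- labels
  avail
}

load_provider_table <- function(path, provider) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    rs_stop("refsmith_format", path, ": empty metadata table (no header)")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (!identical(fields[[1]], METADATA_COLUMNS))
    rs_stop("refsmith_format", path, ": unexpected header; expected ",
            paste(METADATA_COLUMNS, collapse = "\t"))
  records <- vector("list", length(lines) - 1L)
  for (i in seq_along(records)) {
    row <- fields[[i + 1L]]
    where <- paste0(path, " line ", i + 1L)
    if (length(row) != length(METADATA_COLUMNS))
      rs_stop("refsmith_format", where, ": expected ",
              length(METADATA_COLUMNS), " fields, got ", length(row))
    names(row) <- METADATA_COLUMNS
    acc <- if (nzchar(row[["accession"]])) row[["accession"]] else NA_character_
    if (!is.na(acc) && !grepl(ACCESSION_REGEX, acc))
      rs_stop("refsmith_format", where, ": bad accession '", acc, "'")
    tax <- if (nzchar(row[["taxonomy_id"]])) {
      t <- suppressWarnings(as.integer(row[["taxonomy_id"]]))
      if (is.na(t) || t <= 0L)
        rs_stop("refsmith_format", where, ": bad taxonomy_id '",
                row[["taxonomy_id"]], "'")
      t
    } else NA_integer_
    records[[i]] <- list(
      provider_name = provider,
      assembly_name = row[["name"]],
      accession = acc,
      taxonomy_id = tax,
      species = row[["species"]],
      description_fields = if (nzchar(row[["description"]]))
        strsplit(row[["description"]], "|", fixed = TRUE)[[1]] else character(0),
      annotation_flags = parse_annotation_flags(row[["annotations"]], where)
    )
  }
  records
}

#' Load the assembly-metadata cache for all providers
#'
#' @param provider_root Directory containing one subdirectory per provider,
#'   each with a `metadata.tsv` table.
#' @param providers Optional character vector restricting which providers to
#'   load (default: every subdirectory containing a metadata table).
#' @return A `metadata_cache` object (records, fetch timestamp, source).
#' @export
load_metadata_cache <- function(provider_root, providers = NULL) {
  if (!dir.exists(provider_root))
    rs_stop("refsmith_not_found", "provider root not found: ", provider_root)
  if (is.null(providers)) {
    dirs <- list.dirs(provider_root, recursive = FALSE, full.names = FALSE)
    providers <- dirs[file.exists(file.path(provider_root, dirs, "metadata.tsv"))]
  }
  records <- list()
  for (p in sort(providers)) {
    tab <- file.path(provider_root, p, "metadata.tsv")
    if (!file.exists(tab))
      rs_stop("refsmith_not_found", "provider unavailable: no metadata table for '",
              p, "' under ", provider_root)
    records <- c(records, load_provider_table(tab, p))
  }
  keys <- vapply(records, function(r)
    paste(r$provider_name, r$assembly_name, sep = "/"), character(1))
  if (anyDuplicated(keys))
    rs_stop("refsmith_integrity", "duplicate assembly record(s): ",
            paste(unique(keys[duplicated(keys)]), collapse = ", "))
  structure(list(
    records = records,
    fetched_at = iso_time(),
    source_descriptor = normalizePath(provider_root)
  ), class = "metadata_cache")
}

#' @export
print.metadata_cache <- function(x, ...) {
  cat("<metadata_cache> ", length(x$records), " assemblies from ",
      length(unique(vapply(x$records, `[[`, character(1), "provider_name"))),
      " provider(s)\n  source: ", x$source_descriptor, "\n", sep = "")
  invisible(x)
}

record_matches <- function(record, query) {
  switch(query$query_type,
    text = {
      hay <- c(record$assembly_name, record$species, record$description_fields)
      any(grepl(tolower(query$raw), tolower(hay), fixed = TRUE))
    },
    taxonomy = !is.na(record$taxonomy_id) &&
      record$taxonomy_id == as.integer(query$raw),
    accession = {
      if (is.na(record$accession)) return(FALSE)
      q <- toupper(query$raw)
      acc <- toupper(record$accession)
      if (grepl("\\.", q)) identical(acc, q) else {
        root <- sub("\\..*$", "", acc)
        startsWith(root, q)
      }
    },
    FALSE)
}

#' Search assembly records
#'
#' Text queries match case-insensitively as substrings of the assembly name,
#' species and every description field; taxonomy queries match the taxonomy
#' identifier exactly; accession queries with an explicit version match only
#' that version, version-less ones match every version of the accession
#' (GCA and GCF accessions remain distinct).
#'
#' @param cache A `metadata_cache`.
#' @param query A `search_query` from [classify_query()], or a raw string.
#' @param provider Optional provider-name filter.
#' @return List of matching assembly records, ordered by
#'   (provider, assembly name).
#' @export
search_records <- function(cache, query, provider = NULL) {
  stopifnot(inherits(cache, "metadata_cache"))
  if (!inherits(query, "search_query")) query <- classify_query(query)
  hits <- Filter(function(r) record_matches(r, query), cache$records)
  if (!is.null(provider))
    hits <- Filter(function(r) r$provider_name %in% provider, hits)
  ord <- order(vapply(hits, `[[`, character(1), "provider_name"),
               vapply(hits, `[[`, character(1), "assembly_name"),
               method = "radix")
  hits[ord]
}

#' Render assembly records as a text table
#'
#' One row per record with columns name, provider, accession, taxonomy id,
#' annotation availability (one mark per annotation source, `Y` available /
#' `-` not) and species, sorted by (provider, name).
#'
#' @param records List of assembly records.
#' @param sep Column separator: `"table"` pads for alignment, `"tsv"` emits
#'   machine-readable tab-separated rows.
#' @return Character vector of lines, header first.
#' @export
format_search_table <- function(records, sep = c("table", "tsv")) {
  sep <- match.arg(sep)
  ord <- order(vapply(records, `[[`, character(1), "provider_name"),
               vapply(records, `[[`, character(1), "assembly_name"),
               method = "radix")
  records <- records[ord]
  rows <- lapply(records, function(r) c(
    name = r$assembly_name,
    provider = r$provider_name,
    accession = if (is.na(r$accession)) "na" else r$accession,
    taxonomy_id = if (is.na(r$taxonomy_id)) "na" else as.character(r$taxonomy_id),
    annotations = paste(ifelse(r$annotation_flags, "Y", "-"), collapse = ""),
    species = r$species))
  mat <- rbind(c("name", "provider", "accession", "taxonomy_id",
                 "annotations", "species"),
               do.call(rbind, rows))
  if (sep == "tsv") return(apply(mat, 1L, paste, collapse = "\t"))
  widths <- apply(nchar(mat), 2L, max)
  apply(mat, 1L, function(r)
    trimws(paste(mapply(function(v, w) formatC(v, width = -w), r, widths),
                 collapse = "  "), "right"))
}
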