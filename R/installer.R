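# Installation orchestration: resolve a source (provider entry or explicit
# URI/paths), fetch, run the genome through alt-contig exclusion, regex
# filtering and masking, generate the index / sizes / gaps, process the
# annotation into GTF + BED12 harmonized with the genome, run enabled
# plugins, and write a provenance README.

REFSMITH_VERSION <- "0.1.0"

## ---- Transport ------------------------------------------------------------

# Single fetch interface; local paths and file:// URIs satisfy it offline,
# http(s) URIs go through download.file.
fetch_uri <- function(uri, dest) {
  src <- if (startsWith(uri, "file://")) sub("^file://", "", uri) else uri
  if (grepl("^https?://", uri)) {
    status <- utils::download.file(uri, dest, quiet = TRUE, mode = "wb")
    if (status != 0L) rs_stop("refsmith_not_found", "download failed: ", uri)
  } else {
    if (!file.exists(src))
      rs_stop("refsmith_not_found", "source not found: ", uri)
    file.copy(src, dest, overwrite = TRUE)
  }
  invisible(dest)
}

## ---- Provenance -----------------------------------------------------------

new_provenance <- function(assembly) {
  env <- new.env(parent = emptyenv())
  env$record <- list(assembly = assembly, tool_version = REFSMITH_VERSION,
                     sources = character(0), filtered_contigs = character(0),
                     steps = data.frame(timestamp = character(0),
                                        step = character(0),
                                        detail = character(0),
                                        stringsAsFactors = FALSE))
  env
}

prov_step <- function(prov, step, detail = "") {
  detail <- gsub("[\r\n]+", " ", detail)
  prov$record$steps <- rbind(prov$record$steps,
    data.frame(timestamp = iso_time(), step = step, detail = detail,
               stringsAsFactors = FALSE))
  invisible(prov)
}

prov_source <- function(prov, role, uri) {
  s <- prov$record$sources
  s[[role]] <- uri
  prov$record$sources <- s
  invisible(prov)
}

#' Write an installation README (provenance log)
#'
#' Deterministic layout recording the assembly, tool version, source URIs,
#' exhaustively listed filtered contigs and one timestamped line per
#' processing step.  [read_readme()] parses it back; write-parse-write is
#' byte-identical.
#'
#' @param record A provenance record (as returned in `install_assembly()`'s
#'   result) or the internal environment wrapper.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_readme <- function(record, path) {
  if (is.environment(record)) record <- record$record
  lines <- c(
    "# refsmith installation README",
    paste0("assembly: ", record$assembly),
    paste0("version: ", record$tool_version),
    "",
    "## sources")
  for (role in names(record$sources))
    lines <- c(lines, paste0(role, ": ", record$sources[[role]]))
  lines <- c(lines, "", "## filtered contigs")
  for (ctg in record$filtered_contigs) lines <- c(lines, paste0("- ", ctg))
  lines <- c(lines, "", "## steps")
  if (nrow(record$steps))
    lines <- c(lines, sprintf("[%s] %s: %s", record$steps$timestamp,
                              record$steps$step, record$steps$detail))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_readme
#' @export
read_readme <- function(path) {
  lines <- read_text_lines(path)
  if (!length(lines) || lines[1] != "# refsmith installation README")
    rs_stop("refsmith_format", path, ": not a refsmith README")
  record <- list(assembly = sub("^assembly: ", "", lines[2]),
                 tool_version = sub("^version: ", "", lines[3]),
                 sources = character(0), filtered_contigs = character(0),
                 steps = data.frame(timestamp = character(0),
                                    step = character(0), detail = character(0),
                                    stringsAsFactors = FALSE))
  section <- ""
  for (line in lines[-(1:3)]) {
    if (!nzchar(line)) next
    if (startsWith(line, "## ")) { section <- sub("^## ", "", line); next }
    if (section == "sources") {
      role <- sub(":.*$", "", line)
      record$sources[[role]] <- sub("^[^:]+: ", "", line)
    } else if (section == "filtered contigs") {
      record$filtered_contigs <- c(record$filtered_contigs, sub("^- ", "", line))
    } else if (section == "steps") {
      m <- regmatches(line, regexec("^\\[(.*)\\] (\\S+): (.*)$", line))[[1]]
      record$steps <- rbind(record$steps,
        data.frame(timestamp = m[2], step = m[3], detail = m[4],
                   stringsAsFactors = FALSE))
    }
  }
  record
}

## ---- Plugin framework -----------------------------------------------------

.plugins <- new.env(parent = emptyenv())

#' Register a post-installation plugin
#'
#' Plugins run after core processing, in registration order; each receives
#' the installed-genome context (assembly name, directory, FASTA path,
#' index, alias map, source locations) and may add files and provenance
#' entries.
#'
#' @param name Plugin identifier.
#' @param fun `function(context, prov)`; may return a detail string.
#' @param enabled Default enabled state.
#' @export
register_plugin <- function(name, fun, enabled = FALSE) {
  if (!exists("order", envir = .plugins, inherits = FALSE))
    assign("order", character(0), envir = .plugins)
  ord <- get("order", envir = .plugins)
  if (!(name %in% ord)) assign("order", c(ord, name), envir = .plugins)
  assign(paste0("plugin_", name), list(fun = fun, default = enabled),
         envir = .plugins)
  invisible(name)
}

plugin_names <- function() {
  if (!exists("order", envir = .plugins, inherits = FALSE)) character(0)
  else get("order", envir = .plugins)
}

default_config_path <- function() {
  getOption("refsmith.config",
            file.path(tools::R_user_dir("refsmith", "config"), "plugins.tsv"))
}

read_plugin_states <- function(config_path = default_config_path()) {
  states <- vapply(plugin_names(), function(n)
    get(paste0("plugin_", n), envir = .plugins)$default, logical(1))
  if (file.exists(config_path)) {
    lines <- read_text_lines(config_path)
    for (l in lines[nzchar(lines)]) {
      p <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(p) == 2L && p[1] %in% names(states))
        states[[p[1]]] <- p[2] == "1"
    }
  }
  states
}

#' List plugins and their enabled states
#'
#' @param config_path Plugin-state file (default: the user config).
#' @return Data frame (`plugin`, `enabled`).
#' @export
plugin_list <- function(config_path = default_config_path()) {
  states <- read_plugin_states(config_path)
  data.frame(plugin = names(states), enabled = unname(states),
             stringsAsFactors = FALSE)
}

#' Enable or disable a plugin (persisted)
#'
#' @param name Registered plugin name.
#' @param enabled New state.
#' @param config_path Plugin-state file to update.
#' @return The updated state table, invisibly.
#' @export
plugin_toggle <- function(name, enabled, config_path = default_config_path()) {
  if (!(name %in% plugin_names()))
    rs_stop("refsmith_not_found", "unknown plugin '", name, "'; valid: ",
            paste(plugin_names(), collapse = ", "))
  states <- read_plugin_states(config_path)
  states[[name]] <- isTRUE(enabled)
  dir.create(dirname(config_path), recursive = TRUE, showWarnings = FALSE)
  writeLines(sprintf("%s\t%d", names(states), as.integer(states)), config_path)
  invisible(plugin_list(config_path))
}

blacklist_plugin_fun <- function(context, prov) {
  uri <- context$source_uris[["blacklist"]]
  if (is.null(uri) || is.na(uri)) {
    prov_step(prov, "plugin:blacklist", "no blacklist available; skipped")
    return(invisible(NULL))
  }
  tmp <- tempfile(fileext = ".bed")
  fetch_uri(uri, tmp)
  prov_source(prov, "blacklist", uri)
  lines <- read_text_lines(tmp)
  lines <- lines[nzchar(lines)]
  cols <- strsplit(lines, "\t", fixed = TRUE)
  mapped <- vapply(cols, function(cc) {
    m <- match_contig_name(cc[1], context$genome_contigs, context$aliases)
    if (!is.na(m)) cc[1] <- m
    paste(cc, collapse = "\t")
  }, character(1))
  out <- file.path(context$dir, paste0(context$assembly, ".blacklist.bed"))
  writeLines(mapped, out)
  prov_step(prov, "plugin:blacklist",
            paste0(length(mapped), " interval(s), contig names harmonized"))
  invisible(out)
}

aligner_hook <- function(tool) {
  force(tool)
  function(context, prov) {
    # framework hook point only; index building needs the external tool
    prov_step(prov, paste0("plugin:", tool, "_index"),
              "external tool not invoked")
    invisible(NULL)
  }
}

register_builtin_plugins <- function() {
  register_plugin("blacklist", blacklist_plugin_fun, enabled = FALSE)
  for (tool in c("bwa", "bowtie2", "minimap2", "star", "hisat2"))
    register_plugin(paste0(tool, "_index"), aligner_hook(tool), enabled = FALSE)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_plugins()
}

## ---- Annotation-source preference ----------------------------------------

ANNOTATION_FORMAT_PREFERENCE <- c("gff3", "gtf", "bed12")

#' Pick the most descriptive available annotation source
#'
#' Format labels are preferred in the order GFF3 > GTF > BED12 (richest
#' hierarchy/attribute model first); provider-specific labels fall back to
#' the provider's own listed order, first available wins.
#'
#' @param record An assembly record (its `annotation_flags`).
#' @return The chosen label, or `NA` when none is available.
#' @export
resolve_annotation_source <- function(record) {
  flags <- record$annotation_flags
  for (fmt in ANNOTATION_FORMAT_PREFERENCE)
    if (fmt %in% names(flags) && isTRUE(flags[[fmt]])) return(fmt)
  avail <- names(flags)[flags]
  if (length(avail)) avail[1] else NA_character_
}

## ---- Install --------------------------------------------------------------

find_record <- function(cache, name, provider = NULL) {
  recs <- cache$records
  if (!is.null(provider))
    recs <- Filter(function(r) r$provider_name %in% provider, recs)
  hit <- Filter(function(r) r$assembly_name == name, recs)
  if (length(hit)) return(hit[[1]])
  all_names <- vapply(recs, `[[`, character(1), "assembly_name")
  near <- unique(all_names[agrepl(name, all_names, max.distance = 0.3,
                                  ignore.case = TRUE)])
  rs_stop("refsmith_not_found", "assembly '", name, "' not found",
          if (length(near)) paste0("; close matches: ",
                                   paste(near, collapse = ", ")) else "")
}

provider_asset_uris <- function(cache, record) {
  adir <- file.path(cache$source_descriptor, record$provider_name,
                    record$assembly_name)
  uris <- c(genome = file.path(adir, "genome.fa"))
  if (!file.exists(uris[["genome"]]) && file.exists(paste0(uris[["genome"]], ".gz")))
    uris[["genome"]] <- paste0(uris[["genome"]], ".gz")
  label <- resolve_annotation_source(record)
  if (!is.na(label)) {
    cand <- file.path(adir, paste0("annotation.", label))
    if (file.exists(cand)) uris[["annotation"]] <- cand
  }
  for (role in c("aliases", "blacklist")) {
    cand <- file.path(adir, paste0(role, ".",
                                   if (role == "aliases") "tsv" else "bed"))
    if (file.exists(cand)) uris[[role]] <- cand
  }
  uris
}

#' Install a reference assembly
#'
#' Fetches the genome (and, when requested and available, the annotation)
#' from a filesystem/URL provider or explicit URIs, then runs the fixed
#' processing pipeline: decompress, alt-contig exclusion (unless
#' `keep_alts`), regex contig filter, masking transform, rewrap and write,
#' index, contig sizes, gap detection, annotation parsing and emission as
#' GTF + BED12, contig-name harmonization, filtering to genome contigs,
#' enabled plugins, and finally a provenance README.  Each step appends one
#' provenance entry.
#'
#' @param name Assembly name (provider mode) or a label for URI installs.
#' @param cache A `metadata_cache` (required unless `uris` given).
#' @param uris Named character vector/list of explicit sources (`genome`,
#'   optionally `annotation`, `aliases`, `blacklist`); bypasses the cache.
#' @param provider Restrict provider lookup.
#' @param masking `"soft"` (default), `"hard"` or `"none"`.
#' @param keep_alts Keep alternate-locus contigs (default `FALSE`).
#' @param contig_regex Optional regex filter on contig names.
#' @param regex_keep `TRUE` keeps matches (default), `FALSE` drops them.
#' @param annotation Install the gene annotation when available (default
#'   `TRUE`).
#' @param output_root Directory receiving `<output_root>/<name>/`.
#' @param compress Write the genome gzip-compressed.
#' @param force Overwrite an existing installation.
#' @param config_path Plugin-state file consulted for enabled plugins.
#' @return Invisibly, a list with `dir`, `files` and the provenance
#'   `record`.
#' @export
install_assembly <- function(name, cache = NULL, uris = NULL, provider = NULL,
                             masking = c("soft", "hard", "none"),
                             keep_alts = FALSE, contig_regex = NULL,
                             regex_keep = TRUE, annotation = TRUE,
                             output_root = ".", compress = FALSE,
                             force = FALSE,
                             config_path = default_config_path()) {
  masking <- match.arg(masking)
  final_dir <- file.path(output_root, name)
  if (dir.exists(final_dir) && !force)
    rs_stop("refsmith_invalid_query", "assembly '", name,
            "' is already installed at ", final_dir,
            "; use force = TRUE to re-install")
  if (is.null(uris)) {
    if (is.null(cache))
      rs_stop("refsmith_invalid_query",
              "either a metadata cache or explicit uris are required")
    record <- find_record(cache, name, provider)
    uris <- provider_asset_uris(cache, record)
    source_kind <- record$provider_name
  } else {
    uris <- unlist(uris)
    if (!("genome" %in% names(uris)))
      rs_stop("refsmith_invalid_query", "uris must include a 'genome' entry")
    source_kind <- if (any(grepl("^https?://", uris))) "url" else "path"
  }
  uris <- as.list(uris)

  prov <- new_provenance(name)
  tmp <- file.path(output_root, paste0(".tmp_", name))
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) rs_warn("install failed; partial output quarantined in ", tmp))

  # fetch + decompress
  raw_fa <- file.path(tmp, "genome.fetched")
  fetch_uri(uris[["genome"]], raw_fa)
  prov_source(prov, "genome", uris[["genome"]])
  prov_step(prov, "fetch_genome", paste0("source=", source_kind, " uri=",
                                         uris[["genome"]]))
  if (is_gzip(raw_fa)) {
    plain <- file.path(tmp, "genome.plain.fa")
    writeLines(read_text_lines(raw_fa), plain)
    prov_step(prov, "decompress", "gzip input decompressed")
    raw_fa <- plain
  } else {
    prov_step(prov, "decompress", "input not compressed; no-op")
  }

  filtered <- character(0)
  # alt-contig exclusion
  cur <- raw_fa
  if (!keep_alts) {
    nxt <- file.path(tmp, "genome.noalt.fa")
    removed <- exclude_alt_contigs(cur, nxt)
    filtered <- c(filtered, removed)
    prov_step(prov, "exclude_alt_contigs",
              paste0(length(removed), " contig(s) removed",
                     if (length(removed)) paste0(": ",
                       paste(removed, collapse = ",")) else ""))
    cur <- nxt
  } else {
    prov_step(prov, "exclude_alt_contigs", "skipped (keep_alts)")
  }
  # regex filter
  if (!is.null(contig_regex)) {
    nxt <- file.path(tmp, "genome.filtered.fa")
    res <- filter_contigs(cur, contig_regex, regex_keep, nxt)
    filtered <- c(filtered, res$removed)
    prov_step(prov, "filter_contigs",
              paste0("pattern=", contig_regex, " keep_matches=", regex_keep,
                     "; ", length(res$removed), " contig(s) removed"))
    cur <- nxt
  } else {
    prov_step(prov, "filter_contigs", "no pattern; no-op")
  }
  # masking
  masked <- file.path(tmp, "genome.masked.fa")
  changed <- apply_masking(cur, masking, masked)
  prov_step(prov, "apply_masking",
            paste0("level=", masking, "; ", changed, " base(s) changed"))

  # rewrap + final write
  fa_name <- paste0(name, ".fa", if (compress) ".gz" else "")
  final_fa <- file.path(tmp, fa_name)
  write_fasta(read_fasta(masked), final_fa, width = 80L)
  prov_step(prov, "write_genome", paste0(fa_name, " (80 bases/line)"))

  # supporting files
  index <- build_index(final_fa)
  write_genome_index(index, file.path(tmp, paste0(fa_name, ".fai")))
  prov_step(prov, "build_index", paste0(fa_name, ".fai: ", nrow(index), " contig(s)"))
  sizes <- compute_contig_sizes(index)
  write_contig_sizes(sizes, file.path(tmp, paste0(name, ".fa.sizes")))
  prov_step(prov, "contig_sizes", paste0(name, ".fa.sizes: ", sum(sizes$length), " bases total"))
  gaps <- compute_gaps(final_fa)
  write_gaps(gaps, file.path(tmp, paste0(name, ".gaps.bed")))
  prov_step(prov, "contig_gaps", paste0(name, ".gaps.bed: ", nrow(gaps), " gap interval(s)"))

  aliases <- NULL
  if (!is.null(uris[["aliases"]]) && !is.na(uris[["aliases"]])) {
    al_tmp <- file.path(tmp, "aliases.tsv")
    fetch_uri(uris[["aliases"]], al_tmp)
    aliases <- read_alias_table(al_tmp)
    prov_source(prov, "aliases", uris[["aliases"]])
  }

  # annotation
  if (annotation) {
    if (is.null(uris[["annotation"]]) || is.na(uris[["annotation"]])) {
      rs_warn("no annotation available for '", name, "'; genome installed without one")
      prov_step(prov, "annotation", "none available; skipped")
    } else {
      ann_raw <- file.path(tmp, "annotation.fetched")
      fetch_uri(uris[["annotation"]], ann_raw)
      prov_source(prov, "annotation", uris[["annotation"]])
      table <- read_annotation(ann_raw)
      prov_step(prov, "parse_annotation",
                paste0("format=", table$source_format, "; ",
                       length(table$transcripts), " transcript(s)"))
      h <- harmonize_contig_names(table, index$contig, aliases)
      prov_step(prov, "harmonize_contig_names",
                paste0(length(h$report$map), " contig(s) mapped; ",
                       length(h$report$unmatched), " unmatched"))
      table <- filter_by_contigs(h$table, index$contig)
      prov_step(prov, "filter_annotation",
                paste0(length(attr(table, "removed_transcripts")),
                       " transcript(s) on missing contigs removed"))
      write_annotation(table, file.path(tmp, paste0(name, ".annotation.gtf")),
                       "gtf")
      write_annotation(table, file.path(tmp, paste0(name, ".annotation.bed")),
                       "bed12")
      prov_step(prov, "write_annotation", paste0(name, ".annotation.gtf + ", name, ".annotation.bed"))
    }
  } else {
    prov_step(prov, "annotation", "not requested")
  }

  # plugins
  states <- read_plugin_states(config_path)
  context <- list(assembly = name, dir = tmp, fasta = final_fa, index = index,
                  genome_contigs = index$contig, aliases = aliases,
                  source_uris = as.list(uris))
  for (p in plugin_names()) {
    if (isTRUE(states[[p]]))
      get(paste0("plugin_", p), envir = .plugins)$fun(context, prov)
  }

  prov$record$filtered_contigs <- filtered
  prov_step(prov, "write_readme", "README.txt")
  write_readme(prov, file.path(tmp, "README.txt"))

  if (dir.exists(final_dir)) unlink(final_dir, recursive = TRUE)
  # drop intermediates before promoting
  keep <- c(fa_name, paste0(fa_name, ".fai"), paste0(name, ".fa.sizes"),
            paste0(name, ".gaps.bed"), paste0(name, ".annotation.gtf"),
            paste0(name, ".annotation.bed"),
            paste0(name, ".blacklist.bed"), "README.txt")
  for (f in setdiff(list.files(tmp), keep)) unlink(file.path(tmp, f))
  file.rename(tmp, final_dir)
  ok <- TRUE
  invisible(list(dir = final_dir, files = sort(list.files(final_dir)),
                 record = prov$record))
}
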