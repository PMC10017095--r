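# Synthetic fixture generation with known ground truth: genomes with
# controlled line wrapping, soft-masked runs, N-gap runs and alt-locus
# contigs; internally consistent GFF3/GTF/BED12 annotations; alias tables
# across naming schemes; provider metadata caches; blacklists.  Everything
# is deterministic per seed, so every other module can be tested offline
# against an exactly known answer.

#' Describe a synthetic genome + annotation fixture
#'
#' @param seed Integer seed driving all randomness for this fixture.
#' @param n_contigs Number of primary contigs.
#' @param contig_length_range Two-element vector, bases per contig.
#' @param softmask_fraction Approximate fraction of bases soft-masked
#'   (lowercase), in `[0, 1]`.
#' @param gap_runs_per_contig Number of planted N-runs per contig.
#' @param gap_length_range Two-element vector, bases per N-run.
#' @param alt_contig_count Number of alt-locus contigs (named per the
#'   documented alt patterns).
#' @param n_genes Genes in the annotation.
#' @param transcripts_per_gene,exons_per_transcript Ranges (2-vectors).
#' @param orphan_transcripts Transcripts planted on a contig absent from the
#'   genome (to exercise harmonization cleanup).
#' @param naming_schemes Scheme labels for the alias table; the first is the
#'   scheme used by the genome FASTA itself.
#' @param wrap_width FASTA line width.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_contigs = 3L,
                         contig_length_range = c(2000L, 6000L),
                         softmask_fraction = 0.2,
                         gap_runs_per_contig = 2L,
                         gap_length_range = c(20L, 100L),
                         alt_contig_count = 1L,
                         n_genes = 10L,
                         transcripts_per_gene = c(1L, 2L),
                         exons_per_transcript = c(1L, 5L),
                         orphan_transcripts = 0L,
                         naming_schemes = c("ucsc", "ensembl", "ncbi"),
                         wrap_width = 60L) {
  stopifnot(n_contigs >= 1, softmask_fraction >= 0, softmask_fraction <= 1,
            gap_runs_per_contig >= 0, alt_contig_count >= 0, n_genes >= 0,
            wrap_width >= 1, length(naming_schemes) >= 1)
  if (gap_runs_per_contig > 0 &&
      gap_length_range[2] * (gap_runs_per_contig + 1) > contig_length_range[1])
    rs_stop("refsmith_infeasible",
            "gap runs cannot fit in the shortest allowed contig")
  structure(as.list(environment()), class = "fixture_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# scheme-specific names for primary contig i
scheme_contig_name <- function(i, scheme) {
  switch(scheme,
    ucsc = paste0("chr", i),
    ensembl = as.character(i),
    ncbi = sprintf("NC_%06d.1", i),
    paste0(scheme, "_", i))
}

#' Generate a synthetic genome FASTA with ground truth
#'
#' Sequences are uniform A/C/G/T; soft masking is applied as lowercase on
#' recorded intervals; N-gap runs are planted at recorded (non-adjacent)
#' positions; alt-locus contigs follow the documented alt name patterns.
#' Byte-identical output for a given spec.
#'
#' @param spec A [fixture_spec()].
#' @param path Output FASTA path (optionally `.gz`).
#' @return Ground truth: list with `sequences` (named, as written),
#'   `contigs`, `gaps` (data frame contig/start/end, 0-based half-open),
#'   `mask_intervals`, `alt_contigs`, `scheme_names` (matrix contig x
#'   scheme) and the spec itself.
#' @export
generate_genome <- function(spec, path) {
  with_seed(spec$seed, {
    n <- spec$n_contigs
    names_main <- vapply(seq_len(n), scheme_contig_name, character(1),
                         scheme = spec$naming_schemes[1])
    lens <- sample(spec$contig_length_range[1]:spec$contig_length_range[2],
                   n, replace = TRUE)
    seqs <- character(n)
    gaps <- list()
    masks <- list()
    for (i in seq_len(n)) {
      s <- random_dna(lens[i])
      # plant gaps first (uppercase N), leaving >=1 non-N base between runs
      if (spec$gap_runs_per_contig > 0) {
        glens <- sample(spec$gap_length_range[1]:spec$gap_length_range[2],
                        spec$gap_runs_per_contig, replace = TRUE)
        # choose ordered anchor points, then place runs with spacing
        free <- lens[i] - sum(glens) - (spec$gap_runs_per_contig + 1)
        offs <- sort(sample.int(max(free, 1), spec$gap_runs_per_contig))
        pos <- 0
        starts <- numeric(spec$gap_runs_per_contig)
        for (j in seq_len(spec$gap_runs_per_contig)) {
          starts[j] <- offs[j] + pos + 1  # 0-based start, >=1 base before
          pos <- pos + glens[j] + 1
        }
        for (j in seq_along(starts)) {
          substr(s, starts[j] + 1, starts[j] + glens[j]) <-
            strrep("N", glens[j])
        }
        gaps[[i]] <- data.frame(contig = names_main[i], start = starts,
                                end = starts + glens, stringsAsFactors = FALSE)
      }
      # soft-mask random runs over non-N bases
      if (spec$softmask_fraction > 0) {
        target <- round(spec$softmask_fraction * lens[i])
        placed <- 0
        mk <- list()
        tries <- 0
        while (placed < target && tries < 200) {
          tries <- tries + 1
          run <- sample(10:50, 1)
          st <- sample.int(max(lens[i] - run, 1), 1) - 1
          seg <- substr(s, st + 1, st + run)
          if (grepl("[Nn]", seg) || seg != toupper(seg)) next
          substr(s, st + 1, st + run) <- tolower(seg)
          mk[[length(mk) + 1L]] <- c(st, st + run)
          placed <- placed + run
        }
        masks[[i]] <- if (length(mk)) do.call(rbind, mk) else
          matrix(numeric(0), ncol = 2)
      }
      seqs[i] <- s
    }
    names(seqs) <- names_main
    alt_names <- character(0)
    if (spec$alt_contig_count > 0) {
      alt_names <- vapply(seq_len(spec$alt_contig_count), function(k) {
        base <- names_main[(k - 1) %% n + 1]
        if (k %% 2 == 1) sprintf("%s_GL%06d_alt", base, 100000 + k)
        else sprintf("%s_ctg_hap%d", base, k)
      }, character(1))
      alt_seqs <- vapply(seq_along(alt_names), function(k)
        random_dna(sample(200:500, 1)), character(1))
      names(alt_seqs) <- alt_names
      seqs <- c(seqs, alt_seqs)
    }
    scheme_names <- vapply(spec$naming_schemes, function(sc)
      vapply(seq_len(n), scheme_contig_name, character(1), scheme = sc),
      character(n))
    scheme_names <- matrix(scheme_names, nrow = n,
                           dimnames = list(names_main, spec$naming_schemes))
    write_fasta(seqs, path, width = spec$wrap_width)
    gap_df <- if (length(gaps)) do.call(rbind, gaps) else
      data.frame(contig = character(0), start = numeric(0), end = numeric(0),
                 stringsAsFactors = FALSE)
    list(spec = spec, path = path, sequences = seqs,
         contigs = names(seqs), primary_contigs = names_main,
         lengths = stats::setNames(nchar(seqs), names(seqs)),
         gaps = gap_df, mask_intervals = masks, alt_contigs = alt_names,
         scheme_names = scheme_names)
  })
}

# sample exon structures on a contig avoiding gaps; returns transcripts
place_gene <- function(truth, contig, gene_id, gene_name, n_transcripts,
                       exon_range) {
  len <- truth$lengths[[contig]]
  gaps <- truth$gaps[truth$gaps$contig == contig, , drop = FALSE]
  window <- 100 + exon_range[2] * 80  # worst-case transcript footprint
  st <- NA
  for (try in 1:100) {
    cand <- sample.int(max(len - window, 1), 1) - 1
    if (!nrow(gaps) || all(gaps$end <= cand | gaps$start >= cand + window)) {
      st <- cand
      break
    }
  }
  if (is.na(st)) return(NULL)
  strand <- sample(c("+", "-"), 1)
  lapply(seq_len(n_transcripts), function(k) {
    n_ex <- sample(exon_range[1]:exon_range[2], 1)
    elens <- sample(10:40, n_ex, replace = TRUE)
    ilens <- if (n_ex > 1) sample(5:40, n_ex - 1, replace = TRUE) else integer(0)
    starts <- st + cumsum(c(sample(0:50, 1),
                            if (n_ex > 1) elens[-n_ex] + ilens else numeric(0)))
    exons <- cbind(starts, starts + elens)
    cds <- NULL
    if (stats::runif(1) < 0.8) {
      cs <- exons[1, 1] + sample.int(elens[1], 1) - 1
      ce <- exons[n_ex, 2] - sample.int(elens[n_ex], 1) + 1
      if (ce > cs) cds <- c(cs, ce)
    }
    new_transcript(
      transcript_id = sprintf("%s.t%d", gene_id, k),
      gene_id = gene_id, gene_name = gene_name, contig = contig,
      strand = strand, exons = exons, cds = cds)
  })
}

#' Generate a synthetic annotation with ground truth
#'
#' Transcripts are placed in gap-free windows of the fixture genome;
#' optional orphan transcripts sit on a contig the genome does not contain.
#'
#' @param truth Output of [generate_genome()].
#' @return List with `table` (an `annotation_table`, using the genome's own
#'   naming scheme) and `orphan_ids`.
#' @export
generate_annotation <- function(truth) {
  spec <- truth$spec
  with_seed(spec$seed + 1L, {
    transcripts <- list()
    for (g in seq_len(spec$n_genes)) {
      contig <- truth$primary_contigs[(g - 1) %% length(truth$primary_contigs) + 1]
      n_tr <- sample(spec$transcripts_per_gene[1]:spec$transcripts_per_gene[2], 1)
      trs <- place_gene(truth, contig, sprintf("gene%03d", g),
                        sprintf("GENE%03d", g), n_tr, spec$exons_per_transcript)
      transcripts <- c(transcripts, trs)
    }
    orphan_ids <- character(0)
    if (spec$orphan_transcripts > 0) {
      for (k in seq_len(spec$orphan_transcripts)) {
        id <- sprintf("orphan%02d.t1", k)
        st <- sample.int(1000, 1)
        transcripts[[length(transcripts) + 1L]] <- new_transcript(
          transcript_id = id, gene_id = sprintf("orphan%02d", k),
          gene_name = NA_character_, contig = "scaffold_unplaced_999",
          strand = "+", exons = matrix(c(st, st + 100), ncol = 2))
        orphan_ids <- c(orphan_ids, id)
      }
    }
    contig_order <- unique(vapply(transcripts, `[[`, character(1), "contig"))
    list(table = new_annotation_table(transcripts, "gtf", contig_order),
         orphan_ids = orphan_ids)
  })
}

#' Translate an annotation table into another naming scheme
#'
#' @param table An `annotation_table` in the genome's scheme.
#' @param truth Output of [generate_genome()].
#' @param scheme A scheme label from the fixture spec.
#' @return The renamed `annotation_table` (orphan contigs untouched).
#' @export
rename_annotation_scheme <- function(table, truth, scheme) {
  map <- stats::setNames(truth$scheme_names[, scheme],
                         rownames(truth$scheme_names))
  rename <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
  table$contig_order <- rename(table$contig_order)
  table$transcripts <- lapply(table$transcripts, function(t) {
    t$contig <- rename(t$contig); t
  })
  table
}

#' Write the fixture alias table
#'
#' One column per naming scheme plus an `identity` scheme equal to the
#' genome's own names, one row per primary contig.
#'
#' @param truth Output of [generate_genome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
generate_alias_table <- function(truth, path) {
  schemes <- colnames(truth$scheme_names)
  hdr <- c("identity", schemes)
  rows <- vapply(seq_len(nrow(truth$scheme_names)), function(i)
    paste(c(rownames(truth$scheme_names)[i], truth$scheme_names[i, ]),
          collapse = "\t"), character(1))
  # identity duplicates the genome scheme's names; drop the duplicate column
  if (identical(rownames(truth$scheme_names),
                unname(truth$scheme_names[, 1]))) {
    hdr <- schemes
    rows <- vapply(seq_len(nrow(truth$scheme_names)), function(i)
      paste(truth$scheme_names[i, ], collapse = "\t"), character(1))
  }
  writeLines(c(paste(hdr, collapse = "\t"), rows), path)
  invisible(path)
}

#' Generate a blacklist BED for a fixture genome
#'
#' @param truth Output of [generate_genome()].
#' @param path Output BED path.
#' @param n_intervals Number of intervals.
#' @param scheme Naming scheme for the interval contigs.
#' @return Data frame of the written intervals.
#' @export
generate_blacklist <- function(truth, path, n_intervals = 7L,
                               scheme = colnames(truth$scheme_names)[1]) {
  with_seed(truth$spec$seed + 2L, {
    ctgs <- truth$scheme_names[, scheme]
    rows <- lapply(seq_len(n_intervals), function(k) {
      i <- (k - 1) %% length(ctgs) + 1
      len <- truth$lengths[[rownames(truth$scheme_names)[i]]]
      st <- sample.int(max(len - 200, 1), 1) - 1
      data.frame(contig = ctgs[[i]], start = st, end = st + 150,
                 stringsAsFactors = FALSE)
    })
    bed <- do.call(rbind, rows)
    writeLines(sprintf("%s\t%.0f\t%.0f", bed$contig, bed$start, bed$end), path)
    bed
  })
}

#' Generate a filesystem-backed provider with metadata cache
#'
#' Lays out `<root>/<provider>/metadata.tsv` plus one directory per
#' assembly holding `genome.fa`, an annotation in the requested format,
#' `aliases.tsv` and optionally `blacklist.bed`, all generated from fixture
#' specs with known ground truth.
#'
#' @param root Provider root directory (created).
#' @param provider Provider name.
#' @param assemblies Named list: assembly name -> [fixture_spec()].
#' @param annotation_formats Formats to materialize per assembly.
#' @param taxonomy_ids Optional named integer vector per assembly.
#' @param species Optional named character vector per assembly.
#' @param blacklist Logical: also write a blacklist per assembly.
#' @return Named list of ground truths (one per assembly, with elements
#'   `genome`, `annotation`, `blacklist`).
#' @export
generate_provider <- function(root, provider, assemblies,
                              annotation_formats = c("gtf"),
                              taxonomy_ids = NULL, species = NULL,
                              blacklist = FALSE) {
  pdir <- file.path(root, provider)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  truths <- list()
  meta <- character(0)
  for (i in seq_along(assemblies)) {
    name <- names(assemblies)[i]
    spec <- assemblies[[i]]
    adir <- file.path(pdir, name)
    dir.create(adir, showWarnings = FALSE)
    truth <- generate_genome(spec, file.path(adir, "genome.fa"))
    ann <- generate_annotation(truth)
    for (fmt in annotation_formats)
      write_annotation(ann$table, file.path(adir, paste0("annotation.", fmt)),
                       format = fmt)
    generate_alias_table(truth, file.path(adir, "aliases.tsv"))
    bl <- NULL
    if (blacklist)
      bl <- generate_blacklist(truth, file.path(adir, "blacklist.bed"))
    tax <- if (!is.null(taxonomy_ids) && name %in% names(taxonomy_ids))
      taxonomy_ids[[name]] else 9000L + i
    sp <- if (!is.null(species) && name %in% names(species))
      species[[name]] else paste0("Synthetica specimen", i)
    flags <- paste(paste0(annotation_formats, ":1"), collapse = ",")
    acc <- sprintf("GCA_%09d.%d", 100000000L + spec$seed * 100L + i, 1L)
    meta <- c(meta, paste(name, acc, tax, sp,
                          paste0("synthetic fixture assembly|", name, " build"),
                          flags, sep = "\t"))
    truths[[name]] <- list(genome = truth, annotation = ann, blacklist = bl)
  }
  writeLines(c(paste(METADATA_COLUMNS, collapse = "\t"), meta),
             file.path(pdir, "metadata.tsv"))
  truths
}
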