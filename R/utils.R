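# Internal helpers shared across modules.

trimws2 <- function(x) trimws(x, which = "both")

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a condition class so the CLI
#' can map them onto exit codes deterministically.
#' @noRd
rs_stop <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(class, "refsmith_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

rs_warn <- function(...) warning(paste0(...), call. = FALSE)

is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Read all lines of a (possibly gzip-compressed) text file
#' @noRd
read_text_lines <- function(path) {
  if (!file.exists(path)) rs_stop("refsmith_not_found", "file not found: ", path)
  con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# IUPAC-complete complement, case preserved.
COMPLEMENT_FROM <- "ACGTURYSWKMBDHVNacgturyswkmbdhvn"
COMPLEMENT_TO   <- "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn"

#' Reverse complement of a nucleotide string
#'
#' Complements every IUPAC nucleotide code (case preserved; `N` maps to `N`)
#' and reverses the string.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("ACGTn")  # "nACGT"
#' @export
reverse_complement <- function(seq) {
  comp <- chartr(COMPLEMENT_FROM, COMPLEMENT_TO, seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Evaluate an expression with a private RNG stream
#'
#' Saves and restores `.Random.seed` so seeded sampling inside the package
#' never disturbs the caller's random-number stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Wrap a sequence string into fixed-width FASTA lines
#' @noRd
wrap_sequence <- function(seq, width = 80L) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = width)
  substring(seq, starts, pmin(starts + width - 1L, n))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector (names become headers).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Bases per line (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(wrap_sequence(seqs[[i]], width), con)
  }
  invisible(path)
}

#' Read a FASTA file into memory
#'
#' @param path FASTA path, optionally gzip-compressed.
#' @return Named character vector, one element per contig.  Names are the
#'   full header lines without the leading `>`.
#' @export
read_fasta <- function(path) {
  lines <- read_text_lines(path)
  hdr <- startsWith(lines, ">")
  if (length(lines) && !hdr[1])
    rs_stop("refsmith_format", "FASTA does not start with a header: ", path)
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(seq_along(headers), function(i) {
    paste(lines[rec == i & !hdr], collapse = "")
  }, character(1))
  names(seqs) <- headers
  seqs
}

#' First whitespace-delimited token of a FASTA header
#' @noRd
header_token <- function(header) sub("\\s.*$", "", header)

iso_time <- function() format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
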