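#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased on read. Gap characters (`-`) are only retained
#' when `alignment = TRUE`; otherwise they are an error, since plain protein
#' or CDS FASTA should not carry them.
#'
#' @param path Path to a FASTA file.
#' @param alignment Logical; if `TRUE` the file is treated as an aligned
#'   FASTA and gap characters are preserved.
#' @return Named character vector of sequences, names are record ids
#'   (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path, alignment = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  if (!alignment && any(grepl("-", seqs, fixed = TRUE))) {
    stop("gap characters found; use alignment = TRUE for aligned FASTA")
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read tabular (outfmt-6 style) sequence-search hits
#'
#' Parses the conventional 12-column tab-separated hit table
#' (query, subject, percent identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, e-value, bit score).
#' Query coverage is computed as `alignment_length / query length` when
#' `query_lengths` is supplied; otherwise it is left `NA` and downstream
#' filters that need it will refuse to run.
#'
#' @param path Path to the tab-separated hit file (no header).
#' @param query_lengths Optional named numeric vector of query lengths (aa).
#' @return data.frame with one row per hit: `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `query_coverage`, `e_value`,
#'   `bit_score`.
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, 1L) != 12L)
  if (length(bad) > 0L) {
    stop("malformed hit row (expected 12 columns) at line ", bad[1L])
  }
  m <- do.call(rbind, rows)
  num <- function(j) {
    x <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(x)) stop("non-numeric value in column ", j,
                       " at line ", which(is.na(x))[1L])
    x
  }
  hits <- data.frame(
    query_id = m[, 1L],
    subject_id = m[, 2L],
    percent_identity = num(3L),
    alignment_length = num(4L),
    query_coverage = NA_real_,
    e_value = num(11L),
    bit_score = num(12L),
    stringsAsFactors = FALSE
  )
  if (any(hits$e_value < 0)) stop("negative e-value in hit table")
  if (!is.null(query_lengths)) {
    qlen <- query_lengths[hits$query_id]
    if (anyNA(qlen)) {
      stop("query length missing for: ",
           paste(unique(hits$query_id[is.na(qlen)]), collapse = ", "))
    }
    hits$query_coverage <- pmin(1, hits$alignment_length / as.numeric(qlen))
  }
  hits
}
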