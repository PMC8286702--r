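# Candidate identification: homology screen against reference aquaporins
# plus structural sanity checks (transmembrane count, NPA motifs, length).

# Karlin-Altschul parameters for ungapped BLOSUM62 statistics, used to turn
# local alignment scores into approximate e-values in builtin mode.
KA_LAMBDA <- 0.318
KA_K <- 0.13

#' Structural sanity check for an MIP/aquaporin candidate
#'
#' @param protein_seq Amino-acid string, length >= 50.
#' @param length_range Acceptable protein length envelope (aa).
#' @return List with `tm_count`, `npa_count`, `length_ok`.
#' @export
mip_sanity_check <- function(protein_seq, length_range = c(200L, 400L)) {
  .check_protein(protein_seq)
  if (nchar(protein_seq) < 50L) {
    stop("protein shorter than 50 aa; not a credible channel protein")
  }
  list(
    tm_count = nrow(tm_segments(protein_seq)),
    npa_count = nrow(scan_npa(protein_seq)),
    length_ok = nchar(protein_seq) >= length_range[1L] &&
      nchar(protein_seq) <= length_range[2L]
  )
}

#' Screen a proteome for aquaporin candidates
#'
#' Each protein is compared against reference aquaporin queries and receives
#' at most one candidate call (best e-value; ties broken by higher bit/raw
#' score, then lexicographic reference id). A call is accepted when query
#' coverage exceeds `coverage_min`, the e-value is below `evalue_max`, the
#' protein carries at least `tm_min` predicted transmembrane segments and at
#' least one NPA-type motif.
#'
#' In `builtin` mode each reference is locally aligned (Smith-Waterman,
#' BLOSUM62, affine gaps) against each protein and the score is converted
#' to an approximate e-value with ungapped Karlin-Altschul statistics over
#' the effective search space. In `import` mode a pre-computed hit table
#' from [read_blast_tab()] is filtered instead; its `query_coverage` column
#' must be set.
#'
#' @param prot A [proteome()] or named character vector of proteins.
#' @param reference_queries Named character vector of reference aquaporins.
#' @param mode `"builtin"` or `"import"`.
#' @param hits Hit data.frame from [read_blast_tab()] (import mode).
#' @param coverage_min Query-coverage threshold (fraction of the reference).
#' @param evalue_max E-value threshold.
#' @param tm_min Minimum predicted transmembrane segments for acceptance.
#' @return data.frame of candidate calls: `gene_id`, `best_query`,
#'   `query_coverage`, `identity`, `e_value`, `tm_count`, `npa_count`,
#'   `accepted`, `rejection_reason`.
#' @export
homology_screen <- function(prot, reference_queries,
                            mode = c("builtin", "import"), hits = NULL,
                            coverage_min = 0.5, evalue_max = 0.01,
                            tm_min = 4L) {
  mode <- match.arg(mode)
  seqs <- if (inherits(prot, "Proteome")) proteome_seqs(prot, "protein") else prot
  if (length(seqs) == 0L) stop("empty proteome")
  if (length(reference_queries) == 0L) stop("no reference queries")

  if (mode == "builtin") {
    best <- .builtin_best_hits(seqs, reference_queries)
  } else {
    if (is.null(hits)) stop("import mode requires a hit table")
    if (anyNA(hits$query_coverage)) {
      stop("hit table has unset query_coverage; supply query_lengths to ",
           "read_blast_tab()")
    }
    best <- .import_best_hits(seqs, hits)
  }

  out <- lapply(names(seqs), function(id) {
    b <- best[[id]]
    if (is.null(b)) {
      return(data.frame(gene_id = id, best_query = NA_character_,
                        query_coverage = NA_real_, identity = NA_real_,
                        e_value = NA_real_, tm_count = NA_integer_,
                        npa_count = NA_integer_, accepted = FALSE,
                        rejection_reason = "no_hit",
                        stringsAsFactors = FALSE))
    }
    reason <- character(0)
    if (!(b$coverage > coverage_min)) reason <- c(reason, "coverage")
    if (!(b$e_value < evalue_max)) reason <- c(reason, "evalue")
    tm <- NA_integer_; npa <- NA_integer_
    if (length(reason) == 0L) {
      chk <- mip_sanity_check(seqs[[id]])
      tm <- chk$tm_count; npa <- chk$npa_count
      if (tm < tm_min) reason <- c(reason, "tm")
      if (npa < 1L) reason <- c(reason, "npa")
    }
    data.frame(gene_id = id, best_query = b$query,
               query_coverage = b$coverage, identity = b$identity,
               e_value = b$e_value, tm_count = tm, npa_count = npa,
               accepted = length(reason) == 0L,
               rejection_reason = paste(reason, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "filters") <- list(
    coverage_min = coverage_min, evalue_max = evalue_max, tm_min = tm_min,
    coverage_definition = "query coverage fraction (not identity)"
  )
  res
}

.builtin_best_hits <- function(seqs, refs) {
  search_space <- sum(nchar(refs)) * sum(nchar(seqs))
  best <- list()
  for (id in names(seqs)) {
    cand <- NULL
    for (q in names(refs)) {
      a <- align_local(refs[[q]], seqs[[id]])
      e <- KA_K * search_space * exp(-KA_LAMBDA * a$score)
      rec <- list(query = q, coverage = a$query_coverage,
                  identity = a$identity, e_value = e, score = a$score)
      if (is.null(cand) ||
          e < cand$e_value ||
          (e == cand$e_value && (rec$score > cand$score ||
            (rec$score == cand$score && q < cand$query)))) {
        cand <- rec
      }
    }
    best[[id]] <- cand
  }
  best
}

.import_best_hits <- function(seqs, hits) {
  best <- list()
  # "query" is the reference aquaporin; "subject" the proteome protein
  for (id in intersect(unique(hits$subject_id), names(seqs))) {
    h <- hits[hits$subject_id == id, , drop = FALSE]
    h <- h[order(h$e_value, -h$bit_score, h$query_id), , drop = FALSE]
    best[[id]] <- list(query = h$query_id[1L],
                       coverage = h$query_coverage[1L],
                       identity = h$percent_identity[1L],
                       e_value = h$e_value[1L], score = h$bit_score[1L])
  }
  best
}
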