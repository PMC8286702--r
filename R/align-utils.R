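# Thin wrappers around Biostrings pairwise alignment with the parameter set
# used throughout the pipeline (BLOSUM62, affine gaps 10/0.5).

.aln_params <- list(gapOpening = 10, gapExtension = 0.5)

.pairwise <- function(a, b, type = "global") {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = .aln_params$gapOpening,
    gapExtension = .aln_params$gapExtension,
    type = type
  )
}

#' Global alignment of two protein sequences
#'
#' Needleman-Wunsch with BLOSUM62 and affine gap penalties (open 10,
#' extend 0.5).
#'
#' @param a,b Amino-acid strings.
#' @return List with gapped strings `a`, `b`, the alignment `score`,
#'   `identity` (percent identical over all aligned columns, gaps included
#'   in the denominator) and `coverage` (fraction of the shorter sequence
#'   falling in gapless aligned columns).
#' @export
align_global <- function(a, b) {
  aln <- .pairwise(a, b, "global")
  ga <- as.character(Biostrings::pattern(aln))
  gb <- as.character(Biostrings::subject(aln))
  ca <- strsplit(ga, "")[[1L]]
  cb <- strsplit(gb, "")[[1L]]
  both <- ca != "-" & cb != "-"
  list(
    a = ga, b = gb, score = Biostrings::score(aln),
    identity = 100 * sum(ca == cb & both) / length(ca),
    coverage = sum(both) / min(nchar(a), nchar(b))
  )
}

#' Local alignment of two protein sequences
#'
#' Smith-Waterman with BLOSUM62 and affine gap penalties (open 10,
#' extend 0.5).
#'
#' @param query,subject Amino-acid strings.
#' @return List with `score`, `identity` (percent over aligned columns),
#'   `alignment_length`, and `query_coverage` (aligned query residues /
#'   query length).
#' @export
align_local <- function(query, subject) {
  aln <- .pairwise(query, subject, "local")
  gq <- as.character(Biostrings::pattern(aln))
  gs <- as.character(Biostrings::subject(aln))
  cq <- strsplit(gq, "")[[1L]]
  cs <- strsplit(gs, "")[[1L]]
  list(
    score = Biostrings::score(aln),
    identity = 100 * sum(cq == cs) / max(1L, length(cq)),
    alignment_length = length(cq),
    query_coverage = sum(cq != "-") / nchar(query)
  )
}

#' Percent identity of a global alignment
#' @param a,b Amino-acid strings.
#' @return Percent identity over aligned length (gapped columns count
#'   against identity).
#' @export
global_identity <- function(a, b) align_global(a, b)$identity

.check_protein <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("empty ", what)
  }
  bad <- setdiff(strsplit(seq, "")[[1L]], AA20)
  if (length(bad) > 0L) {
    stop("non-amino-acid character(s) in ", what, ": ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(seq)
}
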