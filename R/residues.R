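# Conserved-residue extraction: NPA motifs, ar/R selectivity filter and
# Froger's positions, mapped from curated reference anchors by global
# alignment.

NPA_THIRD <- c("A", "S", "T", "V", "G", "C", "L", "I", "M")

#' Scan a protein for NPA-type motifs
#'
#' Finds all occurrences of Asn-Pro-X where X is one of the small/aliphatic
#' residues seen in natural aquaporin variants (A, S, T, V, G, C, L, I, M).
#' The canonical motif has X = A; NIP-like members often carry NPS and some
#' SIPs carry NPT in their first motif.
#'
#' @param seq Amino-acid string.
#' @return data.frame with `position` (1-based index of the N), `triplet`,
#'   and `canonical` (X == "A").
#' @export
scan_npa <- function(seq) {
  .check_protein(seq)
  pat <- paste0("NP[", paste(NPA_THIRD, collapse = ""), "]")
  m <- gregexpr(pat, seq)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(position = integer(0), triplet = character(0),
                      canonical = logical(0)))
  }
  trip <- substring(seq, m, m + 2L)
  data.frame(position = as.integer(m), triplet = trip,
             canonical = substring(trip, 3L, 3L) == "A",
             stringsAsFactors = FALSE)
}

#' Reference anchor with curated residue positions
#'
#' @param id Reference identifier.
#' @param sequence Amino-acid string.
#' @param positions Named integer vector with elements `NPA_LB`, `NPA_LE`,
#'   `H2`, `H5`, `LE1`, `LE2`, `P1`..`P5` (1-based residue indices in
#'   `sequence`).
#' @return Object of class `ReferenceAnchor`.
#' @export
reference_anchor <- function(id, sequence, positions) {
  .check_protein(sequence)
  need <- c("NPA_LB", "NPA_LE", "H2", "H5", "LE1", "LE2",
            paste0("P", 1:5))
  missing <- setdiff(need, names(positions))
  if (length(missing) > 0L) {
    stop("anchor ", id, " missing position(s): ",
         paste(missing, collapse = ", "))
  }
  pos <- as.integer(positions[need])
  names(pos) <- need
  if (any(pos < 1L | pos > nchar(sequence))) {
    stop("anchor ", id, ": positions outside sequence bounds")
  }
  structure(list(id = id, sequence = sequence, positions = pos),
            class = "ReferenceAnchor")
}

#' Extract filter residues from a target by anchor-guided alignment
#'
#' Globally aligns the target to an annotated anchor (BLOSUM62, gap 10/0.5)
#' and reports the target residues opposite each curated anchor position.
#' A gap opposite an annotated position is reported as `"-"`.
#'
#' @param target_seq Amino-acid string.
#' @param anchor A [reference_anchor()].
#' @param min_identity Refuse extraction below this global identity (%).
#' @return List of class `ResidueAnnotation` with `npa_motifs` (data.frame
#'   of loop-B/loop-E triplets at the mapped positions), `arR` (named
#'   4-vector H2, H5, LE1, LE2), `froger` (named 5-vector P1..P5),
#'   `identity`, `anchor_id`.
#' @export
extract_filter_residues <- function(target_seq, anchor, min_identity = 20) {
  stopifnot(inherits(anchor, "ReferenceAnchor"))
  .check_protein(target_seq)
  aln <- align_global(anchor$sequence, target_seq)
  if (aln$identity < min_identity) {
    stop("anchor mismatch: identity ", round(aln$identity, 1),
         "% below ", min_identity, "%")
  }
  ca <- strsplit(aln$a, "")[[1L]]   # anchor row
  cb <- strsplit(aln$b, "")[[1L]]   # target row
  # map anchor residue index -> alignment column
  anchor_col <- which(ca != "-")
  target_pos <- cumsum(cb != "-")
  res_at <- function(p) {
    col <- anchor_col[p]
    if (cb[col] == "-") "-" else cb[col]
  }
  pos_at <- function(p) {
    col <- anchor_col[p]
    if (cb[col] == "-") NA_integer_ else target_pos[col]
  }
  triplet_at <- function(p) {
    tp <- pos_at(p)
    if (is.na(tp) || tp + 2L > nchar(target_seq)) return(NA_character_)
    substring(target_seq, tp, tp + 2L)
  }
  pos <- anchor$positions
  arR <- vapply(c("H2", "H5", "LE1", "LE2"), function(k) res_at(pos[[k]]), "")
  froger <- vapply(paste0("P", 1:5), function(k) res_at(pos[[k]]), "")
  npa <- data.frame(
    loop = c("LB", "LE"),
    position = c(pos_at(pos[["NPA_LB"]]), pos_at(pos[["NPA_LE"]])),
    triplet = c(triplet_at(pos[["NPA_LB"]]), triplet_at(pos[["NPA_LE"]])),
    stringsAsFactors = FALSE
  )
  structure(list(anchor_id = anchor$id, identity = aln$identity,
                 npa_motifs = npa, arR = arR, froger = froger),
            class = "ResidueAnnotation")
}

#' Pairwise global-identity matrix with subfamily means
#'
#' Identity is the percentage of identical residues over the full aligned
#' length of a global alignment (gapped columns count in the denominator).
#'
#' @param seqs Named character vector (>= 2 sequences).
#' @param subfamily Optional named (or parallel) character vector of
#'   subfamily labels; when given, mean within-subfamily off-diagonal
#'   identities are returned as well.
#' @return List with `matrix` (symmetric, percent, 100 on the diagonal) and
#'   `subfamily_mean` (named numeric, `NULL` when `subfamily` is missing).
#' @export
pairwise_identity_matrix <- function(seqs, subfamily = NULL) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- names(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- global_identity(seqs[[i]], seqs[[j]])
    }
  }
  sub_mean <- NULL
  if (!is.null(subfamily)) {
    if (!is.null(names(subfamily))) subfamily <- subfamily[ids]
    sub_mean <- vapply(split(seq_len(n), subfamily), function(idx) {
      if (length(idx) < 2L) return(NA_real_)
      sub <- m[idx, idx]
      mean(sub[upper.tri(sub)])
    }, 0)
  }
  list(matrix = m, subfamily_mean = sub_mean)
}
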