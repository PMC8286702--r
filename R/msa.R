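# Minimal deterministic progressive multiple alignment: k-mer guide tree
# (UPGMA) + profile-profile Needleman-Wunsch with BLOSUM62 and affine gaps
# (open 10, extend 0.5). Intended for modest numbers of homologous protein
# sequences, which is the regime of a gene-family analysis.

#' Progressive multiple alignment of protein sequences
#'
#' @param seqs Named character vector (>= 2 sequences).
#' @return Object of class `MultipleAlignment` (list): `ids`, `rows`
#'   (named character vector of equal-length gapped sequences), `source`.
#' @export
progressive_align <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  for (s in seqs) .check_protein(s)
  n <- length(seqs)
  if (n == 2L) {
    pa <- .profile_nw(.seq_profile(seqs[[1L]]), .seq_profile(seqs[[2L]]))
    rows <- c(.apply_gaps(seqs[[1L]], pa$gaps_a),
              .apply_gaps(seqs[[2L]], pa$gaps_b))
    names(rows) <- names(seqs)
    return(.msa(names(seqs), rows, "builtin", score = pa$score))
  }
  d <- .kmer_distance(seqs, k = 3L)
  hc <- hclust(stats::as.dist(d), method = "average")
  # progressive merge following the guide tree
  clusters <- lapply(seq_len(n), function(i) {
    list(ids = names(seqs)[i], rows = setNames(seqs[i], names(seqs)[i]))
  })
  merged <- vector("list", nrow(hc$merge))
  get_cluster <- function(idx) if (idx < 0) clusters[[-idx]] else merged[[idx]]
  for (m in seq_len(nrow(hc$merge))) {
    a <- get_cluster(hc$merge[m, 1L])
    b <- get_cluster(hc$merge[m, 2L])
    pa <- .profile_nw(.rows_profile(a$rows), .rows_profile(b$rows))
    rows <- c(vapply(a$rows, .apply_gaps, "", gaps = pa$gaps_a),
              vapply(b$rows, .apply_gaps, "", gaps = pa$gaps_b))
    merged[[m]] <- list(ids = c(a$ids, b$ids), rows = rows)
  }
  final <- merged[[nrow(hc$merge)]]
  # restore input order
  rows <- final$rows[names(seqs)]
  .msa(names(seqs), rows, "builtin")
}

#' Validate and wrap an externally produced alignment
#'
#' @param rows Named character vector of equal-length gapped sequences
#'   (e.g. from `read_fasta(..., alignment = TRUE)`).
#' @return A `MultipleAlignment` with `source = "imported"`.
#' @export
as_alignment <- function(rows) {
  .msa(names(rows), rows, "imported")
}

.msa <- function(ids, rows, source, score = NULL) {
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows differ in length")
  }
  structure(list(ids = ids, rows = rows, source = source, score = score),
            class = "MultipleAlignment")
}

#' @export
print.MultipleAlignment <- function(x, ...) {
  cat(sprintf("<MultipleAlignment> %d sequences x %d columns (%s)\n",
              length(x$rows), nchar(x$rows[[1L]]), x$source))
  invisible(x)
}

#' Drop gaps from one alignment row
#' @param aln A `MultipleAlignment`.
#' @param id Row id.
#' @return Ungapped sequence.
#' @export
ungap_row <- function(aln, id) gsub("-", "", aln$rows[[id]], fixed = TRUE)

.kmer_distance <- function(seqs, k = 3L) {
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(kmers[[i]], kmers[[j]]))
      denom <- max(1L, min(length(kmers[[i]]), length(kmers[[j]])))
      d[i, j] <- d[j, i] <- 1 - shared / denom
    }
  }
  d
}

# 20 x width frequency profile of an alignment (gaps contribute nothing)
.rows_profile <- function(rows) {
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  w <- ncol(mat)
  prof <- matrix(0, nrow = 20L, ncol = w, dimnames = list(AA20, NULL))
  for (j in seq_len(w)) {
    tab <- table(factor(mat[, j], levels = AA20))
    prof[, j] <- tab / nrow(mat)
  }
  prof
}

.seq_profile <- function(s) .rows_profile(setNames(s, "x"))

# Affine-gap global profile-profile alignment (Gotoh). Returns the merged
# column structure as logical gap masks for the two profiles.
.profile_nw <- function(pa, pb, gap_open = 10, gap_ext = 0.5) {
  B <- .blosum62_20()
  wa <- ncol(pa); wb <- ncol(pb)
  sub <- crossprod(pa, B %*% pb)       # wa x wb expected column scores
  NEG <- -1e9
  M <- matrix(NEG, wa + 1L, wb + 1L)
  X <- matrix(NEG, wa + 1L, wb + 1L)   # gap in b (consume a column)
  Y <- matrix(NEG, wa + 1L, wb + 1L)   # gap in a (consume b column)
  M[1L, 1L] <- 0
  for (i in 2L:(wa + 1L)) {
    X[i, 1L] <- -gap_open - gap_ext * (i - 1L)
  }
  for (j in 2L:(wb + 1L)) {
    Y[1L, j] <- -gap_open - gap_ext * (j - 1L)
  }
  for (i in 2L:(wa + 1L)) {
    for (j in 2L:(wb + 1L)) {
      s <- sub[i - 1L, j - 1L]
      M[i, j] <- s + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                         Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_ext,
                     X[i - 1L, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_ext,
                     Y[i, j - 1L] - gap_ext)
    }
  }
  # traceback (prefer M, then X, then Y on ties for determinism)
  i <- wa + 1L; j <- wb + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  gaps_a <- logical(0); gaps_b <- logical(0)  # TRUE = insert gap
  score <- c(M[i, j], X[i, j], Y[i, j])[state]
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      s <- sub[i - 1L, j - 1L]
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- which.max(prev)
      gaps_a <- c(FALSE, gaps_a); gaps_b <- c(FALSE, gaps_b)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      from_m <- M[i - 1L, j] - gap_open - gap_ext
      from_x <- X[i - 1L, j] - gap_ext
      state <- if (from_m >= from_x) 1L else 2L
      gaps_a <- c(FALSE, gaps_a); gaps_b <- c(TRUE, gaps_b)
      i <- i - 1L
    } else {
      from_m <- M[i, j - 1L] - gap_open - gap_ext
      from_y <- Y[i, j - 1L] - gap_ext
      state <- if (from_m >= from_y) 1L else 3L
      gaps_a <- c(TRUE, gaps_a); gaps_b <- c(FALSE, gaps_b)
      j <- j - 1L
    }
  }
  list(gaps_a = gaps_a, gaps_b = gaps_b, score = score)
}

.apply_gaps <- function(row, gaps) {
  chars <- strsplit(row, "")[[1L]]
  out <- character(length(gaps))
  out[gaps] <- "-"
  out[!gaps] <- chars
  paste(out, collapse = "")
}

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62_20 <- function() {
  if (is.null(.blosum62_cache$B)) {
    data("BLOSUM62", package = "Biostrings", envir = .blosum62_cache)
    .blosum62_cache$B <- .blosum62_cache$BLOSUM62[AA20, AA20]
  }
  .blosum62_cache$B
}
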