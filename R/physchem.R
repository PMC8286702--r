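# Physicochemical profiling: molecular weight, isoelectric point, GRAVY and
# hydropathy-based transmembrane segment prediction.

# Average (not monoisotopic) residue masses, Da.
AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Kyte-Doolittle hydropathy indices.
KD_INDEX <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Bjellqvist pKa values (Expasy-compatible): side chains plus termini.
# N-terminal pKa depends on the first residue.
PKA_SIDE <- c(D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0,
              K = 10.0, R = 12.0)
PKA_CTERM <- 3.55
PKA_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.7)
PKA_NTERM_DEFAULT <- 7.5

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water, as computed by standard
#' proteomics servers.
#'
#' @param seq Amino-acid string.
#' @return Molecular weight in kDa.
#' @export
molecular_weight <- function(seq) {
  .check_protein(seq)
  aa <- strsplit(seq, "")[[1L]]
  (sum(AA_MASS[aa]) + WATER_MASS) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R) with the Bjellqvist pKa set.
#'
#' @param seq Amino-acid string.
#' @param pH pH value.
#' @return Net charge (elementary charges).
#' @export
net_charge <- function(seq, pH) {
  .check_protein(seq)
  aa <- strsplit(seq, "")[[1L]]
  counts <- table(factor(aa, levels = AA20))
  pos <- 0
  neg <- 0
  pka_n <- PKA_NTERM[aa[1L]]
  if (is.na(pka_n)) pka_n <- PKA_NTERM_DEFAULT
  pos <- pos + 1 / (1 + 10^(pH - pka_n))                      # N-terminus
  neg <- neg + 1 / (1 + 10^(PKA_CTERM - pH))                  # C-terminus
  for (r in c("K", "R", "H")) {
    pos <- pos + counts[[r]] / (1 + 10^(pH - PKA_SIDE[[r]]))
  }
  for (r in c("D", "E", "C", "Y")) {
    neg <- neg + counts[[r]] / (1 + 10^(PKA_SIDE[[r]] - pH))
  }
  pos - neg
}

#' Isoelectric point by bisection on the net-charge curve
#'
#' @param seq Amino-acid string.
#' @param tol Bisection stops when `|net charge| < tol`.
#' @return pH at which the net charge is zero.
#' @export
isoelectric_point <- function(seq, tol = 1e-4) {
  .check_protein(seq)
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue Kyte-Doolittle indices; positive values
#' indicate a hydrophobic protein.
#'
#' @param seq Amino-acid string.
#' @return GRAVY value.
#' @export
gravy <- function(seq) {
  .check_protein(seq)
  mean(KD_INDEX[strsplit(seq, "")[[1L]]])
}

#' Predict transmembrane segments by hydropathy scanning
#'
#' Sliding Kyte-Doolittle window; a window centre qualifies when the mean
#' hydropathy of the window exceeds `threshold`. Runs of qualifying centres
#' are reported as segments; runs separated by fewer than `min_gap`
#' residues are merged and segments shorter than `min_len` are discarded.
#'
#' @param seq Amino-acid string, length >= `window`.
#' @param window Window size (aa).
#' @param threshold Mean-hydropathy cutoff marking membrane-spanning cores.
#' @param min_len Minimum reported segment length (aa).
#' @param min_gap Segments closer than this are merged.
#' @return Integer matrix with columns `start`, `end` (1-based inclusive),
#'   zero rows when no segment is found.
#' @export
tm_segments <- function(seq, window = 19L, threshold = 1.6,
                        min_len = 15L, min_gap = 5L) {
  .check_protein(seq)
  n <- nchar(seq)
  if (n < window) stop("sequence shorter than hydropathy window (", window, ")")
  h <- KD_INDEX[strsplit(seq, "")[[1L]]]
  cs <- cumsum(c(0, h))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(n - half)           # centre of each window
  marked <- means > threshold
  segs <- .runs_to_intervals(centers[marked])
  segs <- .merge_intervals(segs, min_gap)
  segs <- segs[segs[, 2L] - segs[, 1L] + 1L >= min_len, , drop = FALSE]
  colnames(segs) <- c("start", "end")
  segs
}

.runs_to_intervals <- function(pos) {
  if (length(pos) == 0L) return(matrix(integer(0), ncol = 2L))
  brk <- which(diff(pos) > 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))]
  cbind(starts, ends)
}

.merge_intervals <- function(iv, min_gap) {
  if (nrow(iv) <= 1L) return(iv)
  out <- iv[1L, , drop = FALSE]
  for (i in 2L:nrow(iv)) {
    if (iv[i, 1L] - out[nrow(out), 2L] < min_gap) {
      out[nrow(out), 2L] <- iv[i, 2L]
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

#' Physicochemical and structural profile of a protein set
#'
#' @param seqs Named character vector of protein sequences.
#' @return data.frame with `gene_id`, `length`, `mol_weight_kda`,
#'   `iso_point`, `gravy`, `tm_count`; the per-protein segment lists are
#'   attached as the `tm_segments` attribute.
#' @export
protein_profiles <- function(seqs) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  segs <- lapply(seqs, tm_segments)
  out <- data.frame(
    gene_id = names(seqs),
    length = nchar(seqs),
    mol_weight_kda = vapply(seqs, molecular_weight, 0),
    iso_point = vapply(seqs, isoelectric_point, 0),
    gravy = vapply(seqs, gravy, 0),
    tm_count = vapply(segs, nrow, 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "tm_segments") <- segs
  out
}
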