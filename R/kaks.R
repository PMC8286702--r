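# Nei-Gojobori (1986) synonymous/nonsynonymous substitution estimation with
# Jukes-Cantor correction, plus divergence-time dating and selection calls.
#
# Site counting: at each codon position the fraction of the 3 possible
# single-nucleotide changes that are synonymous defines the synonymous
# "site" content; changes producing a stop codon count as nonsynonymous.
# Differences: codon pairs differing at k positions are averaged over all
# k! single-step pathways, excluding pathways through stop codons (if every
# pathway passes through a stop, all are kept as a documented fallback).

NUC <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- gsub("U", "T", names(gc))
    .codon_env$code <- gc
  }
  .codon_env$code
}

.is_stop <- function(codon) .genetic_code()[[codon]] == "*"

# per-codon synonymous site count (sum over the 3 positions)
.syn_sites <- function(codon) {
  if (is.null(.codon_env$syn)) .codon_env$syn <- new.env(parent = emptyenv())
  cached <- .codon_env$syn[[codon]]
  if (!is.null(cached)) return(cached)
  code <- .genetic_code()
  aa <- code[[codon]]
  s <- 0
  chars <- strsplit(codon, "")[[1L]]
  for (p in 1:3) {
    for (alt in setdiff(NUC, chars[p])) {
      mut <- chars; mut[p] <- alt
      mcodon <- paste(mut, collapse = "")
      if (code[[mcodon]] == aa && code[[mcodon]] != "*") s <- s + 1 / 3
    }
  }
  assign(codon, s, envir = .codon_env$syn)
  s
}

# pathway-averaged (syn, nonsyn) differences between two codons
.codon_differences <- function(ca, cb) {
  a <- strsplit(ca, "")[[1L]]
  b <- strsplit(cb, "")[[1L]]
  diffpos <- which(a != b)
  k <- length(diffpos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  code <- .genetic_code()
  perms <- .permutations(diffpos)
  tally <- function(order, allow_stop) {
    cur <- a; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (!allow_stop && code[[c2]] == "*") return(NULL)
      if (code[[c1]] == code[[c2]] && code[[c2]] != "*") {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(syn = sd, nonsyn = nd)
  }
  res <- lapply(perms, tally, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L) res <- lapply(perms, tally, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(syn = mean(m[, "syn"]), nonsyn = mean(m[, "nonsyn"]))
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

.split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Map a protein-level alignment back to codons
#'
#' Globally aligns the translations of two CDS and returns the codon pairs
#' of columns where both proteins are ungapped (gapped codons dropped
#' pairwise), as two equal-length in-frame sequences.
#'
#' @param cds_a,cds_b In-frame coding sequences (may differ in length).
#' @return List with `cds_a`, `cds_b` (equal-length, gap-free).
#' @export
codon_align <- function(cds_a, cds_b) {
  pa <- translate_cds(cds_a); pb <- translate_cds(cds_b)
  aln <- align_global(pa, pb)
  ca <- .split_codons(substr(cds_a, 1L, 3L * nchar(pa)))
  cb <- .split_codons(substr(cds_b, 1L, 3L * nchar(pb)))
  ra <- strsplit(aln$a, "")[[1L]]
  rb <- strsplit(aln$b, "")[[1L]]
  ia <- cumsum(ra != "-"); ib <- cumsum(rb != "-")
  keep <- ra != "-" & rb != "-"
  list(cds_a = paste(ca[ia[keep]], collapse = ""),
       cds_b = paste(cb[ib[keep]], collapse = ""))
}

#' Nei-Gojobori Ka/Ks with Jukes-Cantor correction
#'
#' @param cds_a,cds_b Equal-length, gap-free, in-frame codon sequences
#'   (use [codon_align()] first for unaligned CDS).
#' @return Object of class `KaKsResult` (list): `S`, `N` (site counts,
#'   averaged over the two sequences), `Sd`, `Nd` (pathway-averaged
#'   differences), `pS`, `pN`, `Ks`, `Ka` (Jukes-Cantor corrected), `ratio`
#'   (`Ka/Ks`, `NA` when undefined), `valid` (FALSE when a proportion is
#'   at or beyond the 0.75 correction bound or `Ks` is 0).
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("CDS length mismatch")
  ca <- .split_codons(toupper(cds_a))
  cb <- .split_codons(toupper(cds_b))
  bad <- !grepl("^[ACGT]{3}$", ca) | !grepl("^[ACGT]{3}$", cb)
  if (any(bad)) stop("non-ACGT codon at codon index ", which(bad)[1L])
  if (any(vapply(ca, .is_stop, TRUE)) || any(vapply(cb, .is_stop, TRUE))) {
    stop("stop codon inside the aligned CDS")
  }
  Sa <- sum(vapply(ca, .syn_sites, 0))
  Sb <- sum(vapply(cb, .syn_sites, 0))
  S <- (Sa + Sb) / 2
  L <- length(ca)
  N <- 3 * L - S
  diffs <- mapply(function(x, y) .codon_differences(x, y), ca, cb)
  Sd <- sum(diffs["syn", ])
  Nd <- sum(diffs["nonsyn", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  valid <- !is.na(Ks) && !is.na(Ka) && Ks > 0
  ratio <- if (valid) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio, valid = valid,
                 codons = L),
            class = "KaKsResult")
}

#' @export
print.KaKsResult <- function(x, ...) {
  cat(sprintf(
    "<KaKsResult> %d codons  S=%.2f N=%.2f  Sd=%.2f Nd=%.2f  Ks=%s Ka=%s  Ka/Ks=%s\n",
    x$codons, x$S, x$N, x$Sd, x$Nd,
    format(x$Ks, digits = 4), format(x$Ka, digits = 4),
    if (x$valid) format(x$ratio, digits = 4) else "undefined"))
  invisible(x)
}

#' Ka/Ks ratio
#' @param Ka,Ks Corrected substitution rates.
#' @return `Ka/Ks`, or `NA` when `Ks` is 0 (undefined).
#' @export
kaks_ratio <- function(Ka, Ks) {
  if (is.na(Ks) || Ks <= 0) return(NA_real_)
  Ka / Ks
}

#' Divergence time from a synonymous rate
#'
#' `T = Ks / (2R)` with `R` the synonymous substitution rate per site per
#' year (default `1.5e-8`, a standard dicot value). `time_mya_alt` is the
#' alternative convention `Ks / 0.3` seen in some gene-family reports
#' (the `1e-8` scale dropped from `2R`); it is 10x smaller than the strict
#' value and reported alongside it for comparability.
#'
#' @param Ks Synonymous substitutions per site (>= 0).
#' @param rate Synonymous substitution rate per site per year.
#' @return List: `time_years`, `time_mya`, `time_mya_alt`, `rate`.
#' @export
divergence_time <- function(Ks, rate = 1.5e-8) {
  if (is.na(Ks) || Ks < 0) stop("Ks must be non-negative")
  years <- Ks / (2 * rate)
  list(time_years = years, time_mya = years / 1e6,
       time_mya_alt = Ks / 0.3, rate = rate)
}

#' Selection regime from a Ka/Ks ratio
#' @param ratio Ka/Ks value.
#' @param tol Half-width of the neutral band around 1.
#' @return `"purifying"`, `"neutral"` or `"positive"`.
#' @export
selection_call <- function(ratio, tol = 1e-9) {
  if (is.na(ratio)) stop("ratio undefined")
  if (abs(ratio - 1) <= tol) return("neutral")
  if (ratio < 1) "purifying" else "positive"
}
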