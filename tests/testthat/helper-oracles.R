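# Independent oracles and small fixture builders used across the suite.

random_protein <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q",
                                           "E", "G", "H", "I", "L", "K",
                                           "M", "F", "P", "S", "T", "W",
                                           "Y", "V")) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  paste(sample(names(code)[code != "*"], n_codons, TRUE), collapse = "")
}

# ---- Nei-Gojobori brute-force oracle -----------------------------------
# Plain, unoptimized re-derivation: explicit triple loops for site counts
# and full permutation enumeration for pathway-averaged differences.

.oracle_code <- local({
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  code
})

oracle_syn_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  aa <- .oracle_code[[codon]]
  s <- 0
  for (p in 1:3) {
    for (nt in nts) {
      if (substr(codon, p, p) == nt) next
      alt <- codon
      substr(alt, p, p) <- nt
      if (.oracle_code[[alt]] == aa && .oracle_code[[alt]] != "*") {
        s <- s + 1 / 3
      }
    }
  }
  s
}

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  res <- list()
  for (i in seq_along(v)) {
    for (p in oracle_perms(v[-i])) res[[length(res) + 1L]] <- c(v[i], p)
  }
  res
}

oracle_codon_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1L]] != strsplit(cb, "")[[1L]])
  if (length(pos) == 0L) return(c(0, 0))
  paths <- list()
  for (ord in oracle_perms(pos)) {
    cur <- ca; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (.oracle_code[[nxt]] == "*") { ok <- FALSE; break }
      if (.oracle_code[[nxt]] == .oracle_code[[cur]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) paths[[length(paths) + 1L]] <- c(sd, nd)
  }
  if (length(paths) == 0L) {
    # fallback: keep stop-crossing pathways, counting those steps nonsyn
    for (ord in oracle_perms(pos)) {
      cur <- ca; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (.oracle_code[[nxt]] != "*" &&
            .oracle_code[[nxt]] == .oracle_code[[cur]]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      paths[[length(paths) + 1L]] <- c(sd, nd)
    }
  }
  colMeans(do.call(rbind, paths))
}

oracle_ng86 <- function(cds_a, cds_b) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(cds_a); cb <- split3(cds_b)
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
          sum(vapply(cb, oracle_syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    d <- oracle_codon_diffs(ca[i], cb[i])
    sd <- sd + d[1L]; nd <- nd + d[2L]
  }
  pS <- sd / S; pN <- nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sd, Nd = nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

# random codon pair that differs at a handful of positions, stop-free
random_codon_pair <- function(max_codons = 6L) {
  n <- sample(2:max_codons, 1L)
  a <- random_cds(n)
  b <- a
  nmut <- sample(1:min(5L, 3L * n), 1L)
  for (k in seq_len(nmut)) {
    repeat {
      p <- sample(nchar(b), 1L)
      cand <- b
      substr(cand, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(b, p, p)), 1L)
      ci <- (p - 1L) %/% 3L + 1L
      codon <- substring(cand, 3L * ci - 2L, 3L * ci)
      if (.oracle_code[[codon]] != "*") { b <- cand; break }
    }
  }
  list(a = a, b = b)
}

# small hand-built proteome for coordinate-rule tests (no sequences)
toy_proteome <- function(coords) {
  loci <- lapply(seq_len(nrow(coords)), function(i) {
    r <- coords[i, ]
    gene_locus(r$gene_id, r$chromosome, r$start, r$end,
               strand = "+", exons = cbind(r$start, r$end))
  })
  proteome(loci, "toy")
}
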