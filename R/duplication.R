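# Duplicate-pair detection and tandem/segmental classification via
# collinearity chaining in gene-rank space.

#' Find duplicated gene pairs in a proteome
#'
#' All-vs-all global protein alignment; a pair is retained when identity
#' and coverage (fraction of the shorter protein in gapless aligned
#' columns) pass the thresholds.
#'
#' @param prot A [proteome()] whose loci carry protein sequences.
#' @param identity_min Percent-identity threshold.
#' @param coverage_min Coverage threshold (fraction).
#' @param ids Optional subset of gene ids to compare (default: all with a
#'   protein sequence).
#' @return data.frame: `gene_a`, `gene_b`, `identity`, `coverage`
#'   (gene_a < gene_b lexicographically).
#' @export
find_duplicate_pairs <- function(prot, identity_min = 40,
                                 coverage_min = 0.75, ids = NULL) {
  stopifnot(inherits(prot, "Proteome"))
  seqs <- proteome_seqs(prot, "protein")
  if (!is.null(ids)) seqs <- seqs[intersect(ids, names(seqs))]
  if (length(seqs) < 2L) stop("need at least 2 loci with protein sequences")
  nm <- sort(names(seqs))
  out <- list()
  for (i in seq_len(length(nm) - 1L)) {
    for (j in (i + 1L):length(nm)) {
      a <- align_global(seqs[[nm[i]]], seqs[[nm[j]]])
      if (a$identity >= identity_min && a$coverage >= coverage_min) {
        out[[length(out) + 1L]] <- data.frame(
          gene_a = nm[i], gene_b = nm[j],
          identity = a$identity, coverage = a$coverage,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), coverage = numeric(0)))
  }
  do.call(rbind, out)
}

# gene ranks (order along each chromosome) for all loci of a proteome
.gene_ranks <- function(prot) {
  info <- data.frame(
    gene_id = vapply(prot$loci, `[[`, "", "gene_id"),
    chromosome = vapply(prot$loci, `[[`, "", "chromosome"),
    start = vapply(prot$loci, function(l) l$start, 0L),
    stringsAsFactors = FALSE
  )
  info <- info[order(info$chromosome, info$start), ]
  info$rank <- stats::ave(info$start, info$chromosome,
                          FUN = seq_along)
  rownames(info) <- info$gene_id
  info
}

#' Detect collinear blocks by chaining homologous gene pairs
#'
#' Homologous pairs are plotted as dots in gene-rank space per chromosome
#' pair, and the longest chains with rank gaps of at most `max_gap` in both
#' genomes (same or inverted orientation) are recovered by dynamic
#' programming; chains with at least `min_anchors` anchors are reported.
#' When `prot_b` is `NULL` the comparison is a self-synteny scan of
#' `prot_a` (self-pairs excluded, each unordered pair used once).
#'
#' @param prot_a,prot_b Proteomes ([proteome()]); `prot_b = NULL` for
#'   self-synteny.
#' @param pairs data.frame with `gene_a`, `gene_b` homologous pairs (e.g.
#'   from [find_duplicate_pairs()]).
#' @param min_anchors Minimum anchors per reported block.
#' @param max_gap Maximum rank gap between consecutive anchors.
#' @return List of `CollinearBlock` lists: `chromosome_a`, `chromosome_b`,
#'   `orientation`, `anchors` (data.frame `gene_a`, `gene_b`),
#'   `anchor_count`.
#' @export
detect_collinear_blocks <- function(prot_a, pairs, prot_b = NULL,
                                    min_anchors = 5L, max_gap = 25L) {
  stopifnot(inherits(prot_a, "Proteome"))
  self <- is.null(prot_b)
  if (self) prot_b <- prot_a
  ra <- .gene_ranks(prot_a)
  rb <- .gene_ranks(prot_b)
  pairs <- pairs[pairs$gene_a %in% rownames(ra) &
                   pairs$gene_b %in% rownames(rb), , drop = FALSE]
  if (self) pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  if (nrow(pairs) == 0L) return(list())
  dots <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    chr_a = ra[pairs$gene_a, "chromosome"],
    chr_b = rb[pairs$gene_b, "chromosome"],
    rank_a = ra[pairs$gene_a, "rank"],
    rank_b = rb[pairs$gene_b, "rank"],
    stringsAsFactors = FALSE
  )
  if (self) {
    # orient each unordered pair so (chr, rank) of side a precedes side b
    flip <- with(dots, chr_a > chr_b | (chr_a == chr_b & rank_a > rank_b))
    dots[flip, c("gene_a", "gene_b", "chr_a", "chr_b", "rank_a", "rank_b")] <-
      dots[flip, c("gene_b", "gene_a", "chr_b", "chr_a", "rank_b", "rank_a")]
    dots <- unique(dots)
  }
  blocks <- list()
  for (key in unique(paste(dots$chr_a, dots$chr_b, sep = "\r"))) {
    chr <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- dots[dots$chr_a == chr[1L] & dots$chr_b == chr[2L], , drop = FALSE]
    for (orient in c("same", "inverted")) {
      chains <- .chain_dots(sub, orient, min_anchors, max_gap)
      for (ch in chains) {
        blocks[[length(blocks) + 1L]] <- list(
          chromosome_a = chr[1L], chromosome_b = chr[2L],
          orientation = orient,
          anchors = ch[, c("gene_a", "gene_b")],
          anchor_count = nrow(ch)
        )
      }
    }
  }
  blocks
}

.chain_dots <- function(sub, orient, min_anchors, max_gap) {
  if (nrow(sub) == 0L) return(list())
  sub <- sub[order(sub$rank_a, sub$rank_b), , drop = FALSE]
  n <- nrow(sub)
  found <- list()
  used <- rep(FALSE, n)
  repeat {
    idx <- which(!used)
    if (length(idx) < min_anchors) break
    L <- rep(1L, n); prev <- rep(NA_integer_, n)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      for (jj in seq_len(ii - 1L)) {
        j <- idx[jj]
        da <- sub$rank_a[i] - sub$rank_a[j]
        db <- if (orient == "same") sub$rank_b[i] - sub$rank_b[j] else
          sub$rank_b[j] - sub$rank_b[i]
        if (da > 0L && da <= max_gap && db > 0L && db <= max_gap &&
            L[j] + 1L > L[i]) {
          L[i] <- L[j] + 1L; prev[i] <- j
        }
      }
    }
    best <- which.max(replace(L, used, 0L))
    if (L[best] < min_anchors) break
    chain <- integer(0); k <- best
    while (!is.na(k)) { chain <- c(k, chain); k <- prev[k] }
    found[[length(found) + 1L]] <- sub[chain, , drop = FALSE]
    used[chain] <- TRUE
  }
  found
}

#' Classify a duplicate pair as tandem, segmental or dispersed
#'
#' Tandem: same chromosome, nearest-boundary separation at most
#' `tandem_window` bp and alignment coverage at least `tandem_coverage`.
#' Otherwise segmental when the pair is an anchor of a collinear block,
#' else dispersed.
#'
#' @param pair One-row data.frame (or list) with `gene_a`, `gene_b`,
#'   `coverage`.
#' @param prot The [proteome()] carrying the loci coordinates.
#' @param blocks Collinear blocks from [detect_collinear_blocks()].
#' @param tandem_window Maximum separation (bp) for tandem duplicates.
#' @param tandem_coverage Minimum coverage for tandem duplicates.
#' @return `"tandem"`, `"segmental"` or `"dispersed"`.
#' @export
classify_duplicate <- function(pair, prot, blocks = list(),
                               tandem_window = 1e5, tandem_coverage = 0.75) {
  la <- prot$loci[[pair$gene_a]]
  lb <- prot$loci[[pair$gene_b]]
  if (is.null(la) || is.null(lb)) stop("pair loci not found in proteome")
  if (la$chromosome == lb$chromosome) {
    sep <- max(0L, max(la$start, lb$start) - min(la$end, lb$end))
    cov <- pair$coverage %||% NA_real_
    if (sep <= tandem_window && !is.na(cov) && cov >= tandem_coverage) {
      return("tandem")
    }
  }
  key <- paste(sort(c(pair$gene_a, pair$gene_b)), collapse = "\r")
  for (b in blocks) {
    anchor_keys <- apply(b$anchors, 1L, function(r) {
      paste(sort(r), collapse = "\r")
    })
    if (key %in% anchor_keys) return("segmental")
  }
  "dispersed"
}

#' Full duplicate analysis of a proteome
#'
#' Convenience wrapper: finds duplicate pairs, detects self-synteny blocks,
#' classifies every pair and (when CDS are available) computes NG86 Ka/Ks,
#' the selection call and divergence times.
#'
#' @inheritParams find_duplicate_pairs
#' @inheritParams detect_collinear_blocks
#' @param rate Synonymous substitution rate per site per year.
#' @return List with `pairs` (data.frame including `dup_type`, `ka`, `ks`,
#'   `ka_ks`, `time_mya`, `selection`) and `blocks`.
#' @export
duplication_analysis <- function(prot, identity_min = 40,
                                 coverage_min = 0.75, min_anchors = 5L,
                                 max_gap = 25L, rate = 1.5e-8) {
  pairs <- find_duplicate_pairs(prot, identity_min, coverage_min)
  blocks <- detect_collinear_blocks(prot, pairs, min_anchors = min_anchors,
                                    max_gap = max_gap)
  if (nrow(pairs) == 0L) return(list(pairs = pairs, blocks = blocks))
  cds <- proteome_seqs(prot, "cds")
  pairs$dup_type <- NA_character_
  pairs$ka <- NA_real_; pairs$ks <- NA_real_; pairs$ka_ks <- NA_real_
  pairs$time_mya <- NA_real_; pairs$selection <- NA_character_
  for (i in seq_len(nrow(pairs))) {
    pairs$dup_type[i] <- classify_duplicate(pairs[i, ], prot, blocks)
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (ga %in% names(cds) && gb %in% names(cds)) {
      kk <- tryCatch(ng86_kaks(cds[[ga]], cds[[gb]]), error = function(e) NULL)
      if (!is.null(kk)) {
        pairs$ka[i] <- kk$Ka; pairs$ks[i] <- kk$Ks
        if (kk$valid) {
          pairs$ka_ks[i] <- kaks_ratio(kk$Ka, kk$Ks)
          pairs$selection[i] <- selection_call(pairs$ka_ks[i])
        }
        if (!is.na(kk$Ks) && kk$Ks >= 0) {
          pairs$time_mya[i] <- divergence_time(kk$Ks, rate)$time_mya
        }
      }
    }
  }
  list(pairs = pairs, blocks = blocks)
}
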