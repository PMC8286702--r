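#' Gene locus container
#'
#' A `GeneLocus` bundles a gene's genomic coordinates (1-based inclusive,
#' GFF3 convention), strand, exon structure and its representative protein
#' and CDS sequences. Exons are kept non-overlapping and sorted in genomic
#' order regardless of strand.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome/scaffold name.
#' @param start,end 1-based inclusive gene span (bp), `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param exons List or 2-column matrix of `(start, end)` exon intervals.
#' @param protein_seq Amino-acid sequence (optional, `NA` to omit).
#' @param cds_seq Coding nucleotide sequence (optional).
#' @param check_translation If `TRUE` and both sequences present, verify the
#'   translated CDS (standard code, terminal stop stripped) equals the
#'   protein; a mismatch or internal stop flags the locus invalid with a
#'   warning rather than an error.
#' @return Object of class `GeneLocus`.
#' @export
gene_locus <- function(gene_id, chromosome, start, end, strand, exons,
                       protein_seq = NA_character_, cds_seq = NA_character_,
                       check_translation = TRUE) {
  stopifnot(is.character(gene_id), nzchar(gene_id), nzchar(chromosome))
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop(gene_id, ": start > end")
  if (!strand %in% c("+", "-")) stop(gene_id, ": strand must be '+' or '-'")
  ex <- exons
  if (is.list(ex)) ex <- do.call(rbind, lapply(ex, as.integer))
  ex <- matrix(as.integer(ex), ncol = 2L)
  ex <- ex[order(ex[, 1L]), , drop = FALSE]
  if (any(ex[, 1L] > ex[, 2L])) stop(gene_id, ": exon start > end")
  if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L])) {
    stop(gene_id, ": overlapping exons")
  }
  valid <- TRUE
  if (!is.na(cds_seq)) {
    if (nchar(cds_seq) %% 3L != 0L) {
      warning(gene_id, ": CDS length not divisible by 3; locus flagged")
      valid <- FALSE
    } else if (check_translation && !is.na(protein_seq)) {
      tr <- translate_cds(cds_seq)
      if (grepl("*", tr, fixed = TRUE)) {
        warning(gene_id, ": internal stop codon; locus flagged")
        valid <- FALSE
      } else if (tr != protein_seq) {
        warning(gene_id, ": translated CDS does not match protein; flagged")
        valid <- FALSE
      }
    }
  }
  structure(
    list(gene_id = gene_id, chromosome = chromosome, start = start,
         end = end, strand = strand, exons = ex,
         protein_seq = protein_seq, cds_seq = cds_seq, valid = valid),
    class = "GeneLocus"
  )
}

#' @export
print.GeneLocus <- function(x, ...) {
  cat(sprintf("<GeneLocus> %s %s:%d-%d(%s) %d exon(s)%s\n",
              x$gene_id, x$chromosome, x$start, x$end, x$strand,
              nrow(x$exons), if (x$valid) "" else " [flagged]"))
  invisible(x)
}

#' Translate a CDS with the standard code, stripping one terminal stop
#' @param cds_seq In-frame coding sequence.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds_seq) {
  if (nchar(cds_seq) %% 3L != 0L) stop("CDS length not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                           no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

#' Number of introns of a gene model
#'
#' @param locus A `GeneLocus`.
#' @return `nrow(exons) - 1`.
#' @export
intron_count <- function(locus) {
  stopifnot(inherits(locus, "GeneLocus"))
  n <- nrow(locus$exons)
  if (n == 0L) stop(locus$gene_id, ": no exons recorded")
  n - 1L
}

#' Proteome container
#'
#' A keyed collection of [gene_locus()] objects for one genome.
#'
#' @param loci List of `GeneLocus` objects.
#' @param genome_label Free-text genome label.
#' @return Object of class `Proteome`.
#' @export
proteome <- function(loci, genome_label = "genome") {
  stopifnot(is.list(loci), length(loci) > 0L)
  ids <- vapply(loci, function(l) l$gene_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(loci) <- ids
  structure(list(loci = loci, genome_label = genome_label),
            class = "Proteome")
}

#' @export
print.Proteome <- function(x, ...) {
  cat(sprintf("<Proteome> %s: %d loci on %d chromosome(s)\n",
              x$genome_label, length(x$loci),
              length(unique(vapply(x$loci, function(l) l$chromosome, "")))))
  invisible(x)
}

#' Extract the protein (or CDS) sequences of a proteome
#' @param x A `Proteome`.
#' @param what `"protein"` or `"cds"`.
#' @return Named character vector (loci lacking the sequence are dropped).
#' @export
proteome_seqs <- function(x, what = c("protein", "cds")) {
  what <- match.arg(what)
  field <- if (what == "protein") "protein_seq" else "cds_seq"
  s <- vapply(x$loci, function(l) l[[field]], "")
  s[!is.na(s)]
}

#' Read a GFF3 gene annotation into a Proteome
#'
#' One `GeneLocus` is kept per gene: the mRNA isoform with the longest
#' annotated CDS. Exons are stored sorted in genomic order; for
#' minus-strand genes the supplied CDS FASTA is still the
#' already-spliced, reverse-complemented coding sequence, so translation
#' checks apply unchanged. Sequences are matched to loci by mRNA id first,
#' then by gene id.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features using ID/Parent.
#' @param fasta_proteome Named character vector (or path) of proteins.
#' @param fasta_cds Named character vector (or path) of CDS sequences.
#' @param genome_label Label stored on the returned `Proteome`.
#' @return A [proteome()].
#' @export
read_gff3 <- function(path, fasta_proteome = NULL, fasta_cds = NULL,
                      genome_label = basename(path)) {
  if (is.character(fasta_proteome) && length(fasta_proteome) == 1L &&
      file.exists(fasta_proteome)) fasta_proteome <- read_fasta(fasta_proteome)
  if (is.character(fasta_cds) && length(fasta_cds) == 1L &&
      file.exists(fasta_cds)) fasta_cds <- read_fasta(fasta_cds)
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  ids <- .gff_attr(g$attributes, "ID")
  parents <- .gff_attr(g$attributes, "Parent")

  genes <- which(g$type == "gene")
  mrnas <- which(g$type %in% c("mRNA", "transcript"))
  exons <- which(g$type == "exon")
  cdss <- which(g$type == "CDS")
  if (length(genes) == 0L) stop("no gene features in ", path)

  gene_of_mrna <- setNames(parents[mrnas], ids[mrnas])
  if (anyNA(gene_of_mrna)) stop("mRNA without Parent attribute in ", path)
  known_mrna <- ids[mrnas]
  bad_parent <- setdiff(unique(parents[c(exons, cdss)]), known_mrna)
  if (length(bad_parent) > 0L) {
    stop("exon/CDS Parent not found among mRNAs: ",
         paste(bad_parent, collapse = ", "))
  }

  cds_len <- tapply(g$end[cdss] - g$start[cdss] + 1L, parents[cdss], sum)
  loci <- list()
  for (gi in genes) {
    gid <- ids[gi]
    if (is.na(gid)) stop("gene feature without ID in ", path)
    mr <- names(gene_of_mrna)[gene_of_mrna == gid]
    if (length(mr) == 0L) next
    len <- cds_len[mr]
    len[is.na(len)] <- 0
    best <- mr[order(-len, mr)][1L]
    ex_rows <- exons[parents[exons] == best]
    if (length(ex_rows) == 0L) ex_rows <- cdss[parents[cdss] == best]
    ex <- cbind(g$start[ex_rows], g$end[ex_rows])
    pseq <- .seq_lookup(fasta_proteome, best, gid)
    cseq <- .seq_lookup(fasta_cds, best, gid)
    loci[[gid]] <- gene_locus(
      gene_id = gid, chromosome = as.character(g$seqid[gi]),
      start = g$start[gi], end = g$end[gi],
      strand = as.character(g$strand[gi]), exons = ex,
      protein_seq = pseq, cds_seq = cseq
    )
  }
  proteome(loci, genome_label = genome_label)
}

.gff_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m), function(x) {
    if (length(x) == 2L) x[2L] else NA_character_
  }, "")
}

.seq_lookup <- function(fasta, mrna_id, gene_id) {
  if (is.null(fasta)) return(NA_character_)
  if (mrna_id %in% names(fasta)) return(unname(fasta[[mrna_id]]))
  if (gene_id %in% names(fasta)) return(unname(fasta[[gene_id]]))
  NA_character_
}
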