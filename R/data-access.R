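# Bundled tabular data.

#' Published substitution rates of duplicated pomegranate aquaporin pairs
#'
#' The reported Ka and Ks values, duplicate types and divergence times of
#' the eight duplicated PgrAQP gene pairs of the pomegranate aquaporin
#' family, usable as input for ratio, dating and selection-call
#' computations.
#'
#' @return data.frame: `gene_a`, `gene_b`, `dup_type`, `ka`, `ks`,
#'   `time_mya_reported`.
#' @export
pgr_duplicate_pair_rates <- function() {
  path <- system.file("extdata", "pgr_duplicated_pair_rates.tsv",
                      package = "mipfam", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Export the bundled seed anchors as FASTA plus a position table
#'
#' Writes the synthetic subfamily anchor sequences and their annotated
#' NPA/ar-R/Froger positions to `anchors.faa` and `anchor_positions.tsv`
#' in `dir`.
#'
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
export_seed_anchors <- function(dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "anchors.faa")
  tsv <- file.path(dir, "anchor_positions.tsv")
  write_fasta(aqp_seed_proteins(), fa)
  pos <- do.call(rbind, lapply(names(.AQP_SEEDS), function(f) {
    data.frame(subfamily = f, t(.AQP_SEEDS[[f]]$positions))
  }))
  write.table(pos, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, tsv))
}
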