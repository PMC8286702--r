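test_that("FASTA parsing, round trips and error cases behave", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a", "MKV"), f)
  expect_identical(read_fasta(f), c(a = "MKV"))

  set.seed(11)
  seqs <- setNames(
    vapply(1:50, function(i) random_protein(sample(20:80, 1)), ""),
    paste0("s", 1:50))
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)

  writeLines(c(">a", "MKV", ">a", "MKL"), f)
  expect_error(read_fasta(f), "duplicate.*a")

  writeLines(c(">a", "MK-V"), f)
  expect_error(read_fasta(f), "gap")
  expect_identical(read_fasta(f, alignment = TRUE), c(a = "MK-V"))

  writeLines(c(">a", "mkv"), f)
  expect_identical(read_fasta(f), c(a = "MKV"))
})

test_that("tabular hit files parse with coverage and fail on bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  row <- paste(c("q1", "s1", "85.5", "200", "25", "3", "1", "200",
                 "5", "204", "1e-30", "350"), collapse = "\t")
  writeLines(row, f)
  h <- read_blast_tab(f)
  expect_equal(nrow(h), 1L)
  expect_equal(h$e_value, 1e-30)
  expect_true(is.na(h$query_coverage))

  h2 <- read_blast_tab(f, query_lengths = c(q1 = 250))
  expect_equal(h2$query_coverage, 200 / 250)

  writeLines(paste(rep("x", 11), collapse = "\t"), f)
  expect_error(read_blast_tab(f), "12 columns.*line 1")
})

test_that("gene loci enforce coordinate and translation invariants", {
  gl <- gene_locus("g1", "chr1", 100, 900, "+",
                   exons = list(c(500, 900), c(100, 200)))
  expect_equal(gl$exons[, 1], c(100, 500))   # sorted genomic order
  expect_error(gene_locus("g2", "chr1", 100, 900, "+",
                          exons = list(c(100, 300), c(250, 900))),
               "overlap")
  expect_error(gene_locus("g3", "chr1", 900, 100, "+",
                          exons = list(c(100, 900))), "start > end")

  # matching CDS/protein passes silently; mismatch flags the locus
  cds <- "ATGAAAGTT"
  ok <- gene_locus("g4", "chr1", 1, 9, "+", list(c(1, 9)),
                   protein_seq = "MKV", cds_seq = cds)
  expect_true(ok$valid)
  expect_warning(
    bad <- gene_locus("g5", "chr1", 1, 9, "+", list(c(1, 9)),
                      protein_seq = "MKL", cds_seq = cds),
    "does not match")
  expect_false(bad$valid)
  expect_warning(
    fr <- gene_locus("g6", "chr1", 1, 8, "+", list(c(1, 8)),
                     protein_seq = "MKV", cds_seq = "ATGAAAGT"),
    "divisible")
  expect_false(fr$valid)
})

test_that("intron count is exon count minus one", {
  mk <- function(n_ex) {
    starts <- seq(1, by = 200, length.out = n_ex)
    gene_locus("g", "chr1", 1, max(starts) + 100, "+",
               exons = cbind(starts, starts + 100))
  }
  expect_equal(intron_count(mk(3)), 2L)
  expect_equal(intron_count(mk(1)), 0L)    # intronless, as in SIP members
  expect_equal(intron_count(mk(5)), 4L)
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    expect_equal(intron_count(mk(n)), n - 1L)
  }
})

test_that("GFF3 import keeps the longest-CDS isoform and exon structure", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t2000\t.\t-\t.\tID=gA",
    "chr1\tsrc\tmRNA\t100\t2000\t.\t-\t.\tID=gA.1;Parent=gA",
    "chr1\tsrc\texon\t100\t399\t.\t-\t.\tID=e1;Parent=gA.1",
    "chr1\tsrc\tCDS\t100\t399\t.\t-\t.\tID=c1;Parent=gA.1",
    "chr1\tsrc\tmRNA\t100\t2000\t.\t-\t.\tID=gA.2;Parent=gA",
    "chr1\tsrc\texon\t1500\t1649\t.\t-\t.\tID=e2;Parent=gA.2",
    "chr1\tsrc\texon\t100\t399\t.\t-\t.\tID=e3;Parent=gA.2",
    "chr1\tsrc\texon\t600\t749\t.\t-\t.\tID=e4;Parent=gA.2",
    "chr1\tsrc\tCDS\t1500\t1649\t.\t-\t.\tID=c2;Parent=gA.2",
    "chr1\tsrc\tCDS\t100\t399\t.\t-\t.\tID=c3;Parent=gA.2",
    "chr1\tsrc\tCDS\t600\t749\t.\t-\t.\tID=c4;Parent=gA.2"
  ), gff)
  pr <- read_gff3(gff)
  # 600 bp isoform beats the 300 bp one; exons sorted in genomic order
  expect_equal(nrow(pr$loci$gA$exons), 3L)
  expect_equal(pr$loci$gA$exons[, 1], c(100, 600, 1500))
  expect_equal(pr$loci$gA$strand, "-")
  expect_equal(intron_count(pr$loci$gA), 2L)

  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g",
    "chr1\tsrc\tmRNA\t1\t10\t.\t+\t.\tID=g.1;Parent=g",
    "chr1\tsrc\texon\t1\t10\t.\t+\t.\tID=e;Parent=g.missing"
  ), gff)
  expect_error(read_gff3(gff), "Parent")
})

test_that("generator GFF3/FASTA output round-trips into a valid proteome", {
  dir <- withr::local_tempdir()
  spec <- genome_sim_spec(seed = 5, n_chromosomes = 2,
                          background_per_chromosome = 2,
                          n_aqp = c(TIP = 2, PIP = 2, NIP = 0, SIP = 0,
                                    XIP = 0),
                          segmental_pairs = 1, tandem_pairs = 1)
  sim <- simulate_genome(spec, out_dir = dir)
  pr <- read_gff3(sim$files$gff, sim$files$proteome, sim$files$cds)
  expect_setequal(names(pr$loci), names(sim$prot$loci))
  for (id in names(pr$loci)) {
    expect_equal(pr$loci[[id]]$start, sim$prot$loci[[id]]$start)
    expect_equal(nrow(pr$loci[[id]]$exons), nrow(sim$prot$loci[[id]]$exons))
    expect_true(pr$loci[[id]]$valid)
    expect_identical(translate_cds(pr$loci[[id]]$cds_seq),
                     pr$loci[[id]]$protein_seq)
  }
})
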