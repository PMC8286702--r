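test_that("duplicate pairs require identity and coverage", {
  set.seed(61)
  p1 <- random_protein(240)
  loci <- list(
    gene_locus("dupA", "chr1", 1000, 2000, "+", cbind(1000, 2000),
               protein_seq = p1, check_translation = FALSE),
    gene_locus("dupB", "chr2", 1000, 2000, "+", cbind(1000, 2000),
               protein_seq = p1, check_translation = FALSE),
    gene_locus("lone", "chr3", 1000, 2000, "+", cbind(1000, 2000),
               protein_seq = random_protein(240), check_translation = FALSE)
  )
  pr <- proteome(loci)
  pairs <- find_duplicate_pairs(pr)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$identity, 100)
  expect_equal(pairs$coverage, 1)
  expect_setequal(c(pairs$gene_a, pairs$gene_b), c("dupA", "dupB"))

  unrelated <- proteome(list(
    gene_locus("r1", "chr1", 1, 10, "+", cbind(1, 10),
               protein_seq = random_protein(200), check_translation = FALSE),
    gene_locus("r2", "chr1", 100, 110, "+", cbind(100, 110),
               protein_seq = random_protein(200), check_translation = FALSE)))
  expect_equal(nrow(find_duplicate_pairs(unrelated)), 0L)
})

test_that("tandem classification follows the window and coverage rule", {
  coords <- data.frame(
    gene_id = c("a", "b", "c"), chromosome = c("chr1", "chr1", "chr1"),
    start = c(10000, 70000, 300000), end = c(15000, 75000, 305000),
    stringsAsFactors = FALSE)
  pr <- toy_proteome(coords)
  # 55 kb apart, coverage 0.8 -> tandem
  expect_equal(classify_duplicate(list(gene_a = "a", gene_b = "b",
                                       coverage = 0.8), pr), "tandem")
  # 225 kb apart -> beyond the 100 kb window
  expect_equal(classify_duplicate(list(gene_a = "b", gene_b = "c",
                                       coverage = 0.9), pr), "dispersed")
  # inside the window but under 75% coverage -> not tandem
  expect_equal(classify_duplicate(list(gene_a = "a", gene_b = "b",
                                       coverage = 0.5), pr), "dispersed")
})

test_that("collinearity chaining finds planted blocks, not shuffled ones", {
  # two chromosomes, 8 genes each; genes 2..7 are homologous in order
  mk <- function(chr, n) data.frame(
    gene_id = paste0(chr, "_g", 1:n), chromosome = chr,
    start = seq(1e4, by = 2e5, length.out = n),
    end = seq(1e4, by = 2e5, length.out = n) + 5e3,
    stringsAsFactors = FALSE)
  pr <- toy_proteome(rbind(mk("chrA", 8), mk("chrB", 8)))
  pairs6 <- data.frame(gene_a = paste0("chrA_g", 2:7),
                       gene_b = paste0("chrB_g", 2:7),
                       stringsAsFactors = FALSE)
  blocks <- detect_collinear_blocks(pr, pairs6)
  expect_equal(length(blocks), 1L)
  expect_equal(blocks[[1]]$anchor_count, 6L)
  expect_equal(blocks[[1]]$orientation, "same")

  # inverted block orientation is also recovered
  pairs_inv <- data.frame(gene_a = paste0("chrA_g", 2:7),
                          gene_b = paste0("chrB_g", 7:2),
                          stringsAsFactors = FALSE)
  binv <- detect_collinear_blocks(pr, pairs_inv)
  expect_equal(length(binv), 1L)
  expect_equal(binv[[1]]$orientation, "inverted")

  # shuffled partner order has no chain
  set.seed(62)
  pairs_shuf <- pairs6
  pairs_shuf$gene_b <- paste0("chrB_g", sample(c(7, 3, 8, 2, 5, 1)))
  expect_equal(length(detect_collinear_blocks(pr, pairs_shuf)), 0L)

  # a 4-anchor run fails the 5-anchor minimum
  expect_equal(length(detect_collinear_blocks(pr, pairs6[1:4, ])), 0L)
  expect_equal(length(detect_collinear_blocks(pr, pairs6[1:4, ],
                                              min_anchors = 4L)), 1L)
})

test_that("simulated genomes are recovered pair-for-pair with true labels", {
  spec <- genome_sim_spec(seed = 63, n_chromosomes = 4,
                          background_per_chromosome = 3,
                          n_aqp = c(TIP = 4, PIP = 3, NIP = 0, SIP = 0,
                                    XIP = 0),
                          segmental_pairs = 2, tandem_pairs = 1)
  sim <- simulate_genome(spec)
  res <- duplication_analysis(sim$prot)
  truth <- sim$truth[!is.na(sim$truth$partner), ]
  truth_keys <- unique(apply(
    cbind(truth$gene_id, truth$partner), 1,
    function(r) paste(sort(r), collapse = "|")))
  found_keys <- apply(res$pairs[, c("gene_a", "gene_b")], 1,
                      function(r) paste(sort(r), collapse = "|"))
  expect_setequal(found_keys, truth_keys)
  # every planted label reproduced
  for (i in seq_len(nrow(res$pairs))) {
    tr <- truth$dup_type[truth$gene_id == res$pairs$gene_a[i]][1]
    expect_equal(res$pairs$dup_type[i], tr)
  }
  # planted purifying signal: all valid ratios below 1
  aqp <- grepl("^AQP", res$pairs$gene_a)
  expect_true(all(res$pairs$ka_ks[aqp] < 1))
  expect_true(all(res$pairs$selection[aqp] == "purifying"))
})

test_that("NG86 equals the exhaustive pathway oracle on random pairs", {
  expect_error(ng86_kaks("ATGAAA", "ATG"), "mismatch")
  same <- ng86_kaks("ATGAAACCC", "ATGAAACCC")
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_false(same$valid)
  expect_true(is.na(same$ratio))

  # single third-position synonymous change in a 9-codon pair
  a <- "ATGAAACCCGGGTTTCTTAGAGATCAT"
  b <- a; substr(b, 9, 9) <- "A"   # CCC -> CCA (Pro, synonymous)
  r <- ng86_kaks(a, b)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  o <- oracle_ng86(a, b)
  expect_equal(r$S, o$S); expect_equal(r$N, o$N)
  expect_equal(r$Ks, o$Ks); expect_equal(r$Ka, o$Ka)

  # random short pairs, exact agreement
  set.seed(64)
  for (i in 1:60) {
    pr <- random_codon_pair()
    r <- ng86_kaks(pr$a, pr$b)
    o <- oracle_ng86(pr$a, pr$b)
    expect_equal(r$S, o$S, tolerance = 1e-12)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
    expect_equal(r$pS, o$pS, tolerance = 1e-12)
    expect_equal(r$pN, o$pN, tolerance = 1e-12)
    # conservation identities
    expect_equal(r$S + r$N, 3 * r$codons)
    nd_total <- sum(strsplit(pr$a, "")[[1]] != strsplit(pr$b, "")[[1]])
    expect_equal(r$Sd + r$Nd, nd_total, tolerance = 1e-9)
  }

  # saturated synonymous proportion: flagged, not an exception
  sat <- ng86_kaks(strrep("CTT", 10), strrep("CTG", 10))
  expect_false(sat$valid)
  expect_true(is.na(sat$Ks))
})

test_that("codon-aware alignment drops gapped codons pairwise", {
  a <- "ATGAAACCCGGG"          # M K P G
  b <- "ATGCCCGGG"             # M P G
  al <- codon_align(a, b)
  expect_equal(nchar(al$cds_a), nchar(al$cds_b))
  expect_equal(translate_cds(al$cds_a), "MPG")
  r <- ng86_kaks(al$cds_a, al$cds_b)
  expect_equal(r$Sd + r$Nd, 0)
})

test_that("ratio, dating and selection calls do the printed arithmetic", {
  expect_equal(round(kaks_ratio(0.101, 0.52), 3), 0.194)
  expect_equal(round(kaks_ratio(0.074, 1.54), 3), 0.048)
  expect_equal(kaks_ratio(0, 1), 0)
  expect_true(is.na(kaks_ratio(0.1, 0)))

  expect_equal(divergence_time(0.3)$time_mya, 10)
  expect_equal(round(divergence_time(2.09)$time_mya_alt, 2), 6.97)
  expect_equal(divergence_time(0)$time_years, 0)
  expect_error(divergence_time(-1), "non-negative")

  expect_equal(selection_call(0.194), "purifying")
  expect_equal(selection_call(1), "neutral")
  expect_equal(selection_call(1.7), "positive")
})

test_that("planted substitution rates are recovered from simulated pairs", {
  set.seed(65)
  errs <- sapply(1:8, function(i) {
    sim <- simulate_cds_pair(evol_sim_spec(seed = i, codons = 300,
                                           target_dn = 0.1, target_ds = 0.5))
    r <- ng86_kaks(sim$cds_a, sim$cds_b)
    c(abs(r$Ka - sim$realized_dn) / sim$realized_dn,
      abs(r$Ks - sim$realized_ds) / sim$realized_ds)
  })
  expect_lt(mean(errs), 0.15)
})
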